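#' Declarative specification of the multi-branch CNN
#'
#' Describes the seven-class lesion classifier: four convolutional blocks
#' (the first a single conv layer; blocks 2-4 each with three parallel
#' branches of 1x1 / two 3x3 / two 3x3 + one 1x1 convolutions, channel-
#' concatenated), each block closed by batch normalization, 2x2 max pooling
#' and the NGNDG activation, then fully connected layers of 256 and 64
#' units (NGNDG + dropout after each) and a softmax classification layer.
#'
#' Per-conv filter counts are free parameters of the design; the defaults
#' are deliberately small so the network trains in seconds on a CPU.
#'
#' @param input_shape integer `(height, width, channels)`.
#' @param n_classes number of output classes (>= 2).
#' @param fc_sizes hidden fully-connected widths, in order.
#' @param dropout_rate dropout probability in `[0, 1)` after each hidden FC.
#' @param beta NGNDG slope parameter; must be nonzero for a usable model.
#' @param activation `"ngndg"`, `"relu"` or `"elu"`; swapping the activation
#'   never changes parameter counts (all are parameter-free).
#' @param filters list with `block1` (scalar) and `block2`..`block4`
#'   (length-3, one filter count per branch).
#' @return an object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = c(28L, 28L, 3L),
                     n_classes = 7L,
                     fc_sizes = c(256L, 64L),
                     dropout_rate = 0.3,
                     beta = 1,
                     activation = "ngndg",
                     filters = list(block1 = 16L,
                                    block2 = c(8L, 8L, 8L),
                                    block3 = c(16L, 16L, 16L),
                                    block4 = c(16L, 16L, 16L))) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (length(fc_sizes) == 0L) stop("fc_sizes must be nonempty")
  check_beta(beta)
  if (length(filters$block1) != 1L ||
      !all(vapply(filters[c("block2", "block3", "block4")], length, 0L) == 3L))
    stop("filters must give 1 count for block1 and 3 per branch for blocks 2-4")
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 fc_sizes = as.integer(fc_sizes),
                 dropout_rate = dropout_rate,
                 beta = beta,
                 activation = activation,
                 filters = lapply(filters, as.integer)),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat("Multi-branch CNN specification\n")
  cat("  input:", paste(x$input_shape, collapse = "x"),
      " classes:", x$n_classes, "\n")
  cat("  activation:", x$activation, "(beta =", x$beta, ")\n")
  cat("  filters:", paste(vapply(x$filters, function(f) paste(f, collapse = "+"),
                                 ""), collapse = " | "), "\n")
  cat("  fc:", paste(x$fc_sizes, collapse = " -> "), "->", x$n_classes,
      "softmax;  dropout", x$dropout_rate, "\n")
  invisible(x)
}

# branch kernel patterns: 1x1 | 3x3,3x3 | 3x3,3x3,1x1
branch_kernels <- function() list(c(1L), c(3L, 3L), c(3L, 3L, 1L))

#' Build the multi-branch CNN
#'
#' Instantiates a trainable network from a [cnn_spec()]: He-initialized
#' convolution and dense weights, unit-gamma batch norms. Branch outputs
#' within a block are concatenated along channels and must therefore agree
#' spatially, which the stride-1 same-padded convolutions guarantee.
#'
#' @param spec a [cnn_spec()].
#' @param seed optional integer seed for the weight initialization.
#' @return an object of class `ngndg_net` (an ordered list of named stages).
#' @export
build_cnn <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (spec$beta == 0) stop("beta = 0 collapses the activation; refusing to build")
  if (!is.null(seed)) set.seed(seed)
  stages <- list()
  add <- function(st) stages[[st$name]] <<- st
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; Cin <- spec$input_shape[3]

  block_defs <- list(
    block1 = list(kernels = list(c(3L)), filters = spec$filters$block1),
    block2 = list(kernels = branch_kernels(), filters = spec$filters$block2),
    block3 = list(kernels = branch_kernels(), filters = spec$filters$block3),
    block4 = list(kernels = branch_kernels(), filters = spec$filters$block4)
  )
  for (bn in names(block_defs)) {
    bd <- block_defs[[bn]]
    cb <- new_conv_block(paste0(bn, "_conv"), bd$kernels, bd$filters, Cin)
    add(cb)
    add(new_batchnorm(paste0(bn, "_bn"), cb$c_out))
    add(list(name = paste0(bn, "_pool"), type = "maxpool"))
    add(list(name = paste0(bn, "_act"), type = "activation"))
    Cin <- cb$c_out
    H <- H %/% 2L; W <- W %/% 2L
    if (H < 1L || W < 1L)
      stop("input collapses to zero spatial extent in ", bn,
           "; increase input_shape")
  }
  add(list(name = "flatten", type = "flatten"))
  nin <- H * W * Cin
  for (fi in seq_along(spec$fc_sizes)) {
    dl <- new_dense_layer(nin, spec$fc_sizes[fi])
    add(c(list(name = paste0("fc", fi), type = "dense"), dl))
    add(list(name = paste0("fc", fi, "_act"), type = "activation"))
    add(list(name = paste0("drop", fi), type = "dropout", rate = spec$dropout_rate))
    nin <- spec$fc_sizes[fi]
  }
  dl <- new_dense_layer(nin, spec$n_classes)
  add(c(list(name = paste0("fc", length(spec$fc_sizes) + 1L), type = "dense"), dl))
  add(list(name = "softmax", type = "softmax"))

  structure(list(stages = stages, spec = spec,
                 activation = spec$activation, beta = spec$beta,
                 input_shape = spec$input_shape, n_classes = spec$n_classes,
                 default_layer = "block4_conv"),
            class = "ngndg_net")
}

#' Class probabilities from a network
#'
#' Runs the network in evaluation mode (dropout off, batch-norm running
#' statistics) on a batch of images.
#'
#' @param model an `ngndg_net`.
#' @param images array `(N, H, W, C)` or a single image `(H, W, C)`.
#' @return matrix `(N, n_classes)` of class probabilities; rows sum to 1.
#' @export
net_predict <- function(model, images) {
  x <- to_internal(check_images(images, model$input_shape))
  net_forward(model, x, training = FALSE)$probs
}

check_images <- function(images, input_shape) {
  d <- dim(images)
  if (length(d) == 3L) { dim(images) <- c(1L, d); d <- dim(images) }
  if (length(d) != 4L || !all(d[2:4] == input_shape))
    stop("images must be (N, ", paste(input_shape, collapse = ", "),
         ") but got (", paste(d, collapse = ", "), ")")
  images
}

#' Layer census of a built network
#'
#' Deterministic enumeration of the network's layers under the package's
#' documented counting convention: convolution, batch normalization, max
#' pooling, flatten, dense, dropout and softmax each count as one layer;
#' activations are fused into the stage they rectify (the Keras
#' `activation=` idiom) and reported in the `activation` column rather
#' than as rows. Under this convention the default architecture has
#' exactly 34 layers.
#'
#' @param model an `ngndg_net`.
#' @return a data frame with one row per layer: `layer`, `kind`, `block`,
#'   `branch`, `detail`, `activation`, `output_shape`, `n_params`.
#' @export
layer_census <- function(model) {
  stopifnot(inherits(model, "ngndg_net"))
  rows <- list()
  H <- model$input_shape[1]; W <- model$input_shape[2]
  shp <- function(...) paste(c(...), collapse = "x")
  act <- model$activation
  nm <- names(model$stages)
  for (i in seq_along(nm)) {
    st <- model$stages[[i]]
    blk <- sub("_(conv|bn|pool|act)$", "", st$name)
    if (!grepl("^block", blk)) blk <- NA_character_
    if (st$type == "conv_block") {
      for (bi in seq_along(st$branches)) {
        cin <- st$c_in
        for (li in seq_along(st$branches[[bi]])) {
          cv <- st$branches[[bi]][[li]]
          co <- dim(cv$W)[4]
          rows[[length(rows) + 1L]] <- data.frame(
            layer = sprintf("%s.b%d.c%d", st$name, bi, li), kind = "conv",
            block = blk,
            branch = if (length(st$branches) > 1L) paste0("b", bi) else NA,
            detail = sprintf("%dx%d conv, %d filters", cv$k, cv$k, co),
            activation = NA_character_,
            output_shape = shp(H, W, co),
            n_params = length(cv$W) + length(cv$b))
          cin <- co
        }
      }
      Cc <- st$c_out
    } else if (st$type == "batchnorm") {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = st$name, kind = "batch_norm", block = blk, branch = NA,
        detail = sprintf("%d channels", st$C), activation = NA_character_,
        output_shape = shp(H, W, st$C), n_params = 2L * st$C)
    } else if (st$type == "maxpool") {
      H <- H %/% 2L; W <- W %/% 2L
      rows[[length(rows) + 1L]] <- data.frame(
        layer = st$name, kind = "max_pool", block = blk, branch = NA,
        detail = "2x2, stride 2",
        activation = if (identical(model$stages[[i + 1L]]$type, "activation"))
          act else NA_character_,
        output_shape = shp(H, W, Cc), n_params = 0L)
    } else if (st$type == "flatten") {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = st$name, kind = "flatten", block = NA, branch = NA,
        detail = "", activation = NA_character_,
        output_shape = shp(H * W * Cc), n_params = 0L)
    } else if (st$type == "dense") {
      fused <- i < length(nm) &&
        identical(model$stages[[i + 1L]]$type, "activation")
      rows[[length(rows) + 1L]] <- data.frame(
        layer = st$name, kind = "dense", block = NA, branch = NA,
        detail = sprintf("%d -> %d", nrow(st$W), ncol(st$W)),
        activation = if (fused) act else NA_character_,
        output_shape = shp(ncol(st$W)), n_params = length(st$W) + length(st$b))
    } else if (st$type == "dropout") {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = st$name, kind = "dropout", block = NA, branch = NA,
        detail = sprintf("rate %g", st$rate), activation = NA_character_,
        output_shape = rows[[length(rows)]]$output_shape, n_params = 0L)
    } else if (st$type == "softmax") {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = st$name, kind = "softmax", block = NA, branch = NA,
        detail = sprintf("%d classes", model$n_classes),
        activation = NA_character_,
        output_shape = shp(model$n_classes), n_params = 0L)
    }
    # activation stages are fused, not counted
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' A tiny two-conv network for gradient-oracle work
#'
#' Builds a deliberately small network (two 3x3 conv layers with the chosen
#' activation, 2x2 pooling, 4x4 final feature maps, then a single linear
#' layer and softmax) used to validate the saliency machinery: because the
#' head from the last activation to the logits is affine, the closed-form
#' higher-order class-score derivatives are exact there and can be gated
#' against nested finite differences.
#'
#' @param seed integer seed for the weight initialization.
#' @param n_classes number of classes (default 5 keeps it under 500
#'   parameters).
#' @param activation,beta activation family and NGNDG slope.
#' @param input_shape image shape, default `(8, 8, 3)`.
#' @return an `ngndg_net` whose default saliency layer is `"conv2_act"`.
#' @export
toy_conv_net <- function(seed = 1L, n_classes = 5L, activation = "ngndg",
                         beta = 1, input_shape = c(8L, 8L, 3L)) {
  set.seed(seed)
  stages <- list()
  add <- function(st) stages[[st$name]] <<- st
  cb1 <- new_conv_block("conv1", list(c(3L)), 3L, input_shape[3])
  add(cb1)
  add(list(name = "conv1_act", type = "activation"))
  add(list(name = "pool1", type = "maxpool"))
  cb2 <- new_conv_block("conv2", list(c(3L)), 3L, 3L)
  add(cb2)
  add(list(name = "conv2_act", type = "activation"))
  add(list(name = "flatten", type = "flatten"))
  nin <- (input_shape[1] %/% 2L) * (input_shape[2] %/% 2L) * 3L
  add(c(list(name = "fc", type = "dense"), new_dense_layer(nin, n_classes)))
  add(list(name = "softmax", type = "softmax"))
  structure(list(stages = stages, spec = NULL, activation = activation,
                 beta = beta, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 default_layer = "conv2_act"),
            class = "ngndg_net")
}

#' @export
print.ngndg_net <- function(x, ...) {
  cen <- layer_census(x)
  cat("ngndg_net:", nrow(cen), "layers,",
      sum(cen$n_params), "trainable parameters\n")
  cat("  input", paste(x$input_shape, collapse = "x"),
      "->", x$n_classes, "classes;",
      "activation", x$activation, "(beta =", x$beta, ")\n")
  invisible(x)
}
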