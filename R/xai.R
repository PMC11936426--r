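# Class-discriminative saliency. Feature maps A^k(i,j) are taken from a
# named stage of the network (default: the last convolutional block's
# output). Grad-CAM weights channels by spatially averaged class-score
# gradients; Grad-CAM++ builds pixel-wise weights from the 2nd and 3rd
# order derivatives of the softmax class score. In both variants the final
# rectification of the weighted feature-map sum uses the NGNDG activation
# (or any registered activation), which is the generalization of the
# classical ReLU rectification.

resolve_layer <- function(model, layer_id) {
  if (is.null(layer_id)) layer_id <- model$default_layer
  if (!layer_id %in% names(model$stages))
    stop("unknown layer: ", layer_id, " (available: ",
         paste(names(model$stages), collapse = ", "), ")")
  layer_id
}

# capture feature maps at a stage for a single image -> (H, W, C) array
feature_maps <- function(model, image, layer_id = NULL) {
  layer_id <- resolve_layer(model, layer_id)
  x <- to_internal(check_images(image, model$input_shape))
  if (dim(x)[3] != 1L) stop("saliency expects a single image")
  fw <- net_forward(model, x, training = FALSE, capture = layer_id)
  A <- fw$outs[[layer_id]]
  d <- dim(A)
  dim(A) <- d[c(1L, 2L, 4L)]
  attr(A, "layer_id") <- layer_id
  attr(A, "probs") <- fw$probs[1L, ]
  A
}

# score of the head restarted from feature maps A (internal single-image)
head_score <- function(model, layer_id, A) {
  a4 <- A; dim(a4) <- c(dim(A)[1], dim(A)[2], 1L, dim(A)[3])
  fw <- net_forward(model, a4, training = FALSE, start_after = layer_id)
  list(logits = fw$logits[1L, ], probs = fw$probs[1L, ])
}

# per-class Jacobians d logit_k / dA for all classes -> list of (H, W, C)
logit_jacobians <- function(model, layer_id, A) {
  a4 <- A; dim(a4) <- c(dim(A)[1], dim(A)[2], 1L, dim(A)[3])
  fw <- net_forward(model, a4, training = FALSE, start_after = layer_id)
  C <- model$n_classes
  g <- vector("list", C)
  for (k in seq_len(C)) {
    seed <- matrix(0, 1L, C); seed[1L, k] <- 1
    bw <- net_backward(model, fw$caches, seed, stop_at = layer_id)
    gk <- bw$dx
    dim(gk) <- dim(A)
    g[[k]] <- gk
  }
  list(g = g, probs = fw$probs[1L, ], logits = fw$logits[1L, ])
}

#' Gradients of a class score with respect to feature maps
#'
#' Computes `d^n Y^c / (dA_ij^k)^n` for `n` in 1..3, where `A` are the
#' feature maps of the stage `layer_id` and `Y^c` is either the
#' pre-softmax logit of the target class (`score = "logit"`, the
#' conventional Grad-CAM score) or its softmax probability
#' (`score = "softmax"`, the Grad-CAM++ score).
#'
#' Order 1 is exact backpropagation. Orders 2 and 3 use the closed
#' softmax-chain forms built from the per-class logit Jacobians `g_k`:
#' with `gbar = sum_k p_k g_k`, `V = sum_k p_k (g_k - gbar)^2`,
#' `mu3 = sum_k p_k (g_k - gbar)^3`, elementwise over positions,
#' \deqn{dY^c/dA = p_c (g_c - gbar)}
#' \deqn{d^2Y^c/dA^2 = p_c ((g_c - gbar)^2 - V)}
#' \deqn{d^3Y^c/dA^3 = p_c ((g_c - gbar)^3 - 3 V (g_c - gbar) - mu3)}
#' These are exact whenever the subnetwork from `layer_id` to the logits
#' is affine (the usual last-conv-layer setting) and otherwise are the
#' locally-affine approximation standard in Grad-CAM++ practice. For the
#' logit score the higher orders are 0 under the same premise.
#'
#' @param model an `ngndg_net` (or `ngndg_cnn` fit).
#' @param image a single `(H, W, C)` image.
#' @param target_class class index in `0..C-1`.
#' @param layer_id stage name; default the model's last conv block.
#' @param order derivative order, 1, 2 or 3.
#' @param score `"logit"` or `"softmax"`.
#' @return gradient array shaped like the feature maps `(H, W, C)`.
#' @export
class_gradients <- function(model, image, target_class, layer_id = NULL,
                            order = 1L, score = c("logit", "softmax")) {
  model <- as_net(model)
  score <- match.arg(score)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  layer_id <- resolve_layer(model, layer_id)
  cidx <- as.integer(target_class) + 1L
  if (cidx < 1L || cidx > model$n_classes)
    stop("target_class must be in [0, ", model$n_classes, ")")
  A <- feature_maps(model, image, layer_id)
  jac <- logit_jacobians(model, layer_id, A)
  g <- jac$g; p <- jac$probs
  if (score == "logit") {
    if (order == 1L) return(g[[cidx]])
    out <- g[[cidx]]; out[] <- 0
    return(out)
  }
  gbar <- Reduce(`+`, Map(function(gk, pk) gk * pk, g, p))
  dc <- g[[cidx]] - gbar
  if (order == 1L) return(p[cidx] * dc)
  V <- Reduce(`+`, Map(function(gk, pk) pk * (gk - gbar)^2, g, p))
  if (order == 2L) return(p[cidx] * (dc^2 - V))
  mu3 <- Reduce(`+`, Map(function(gk, pk) pk * (gk - gbar)^3, g, p))
  p[cidx] * (dc^3 - 3 * V * dc - mu3)
}

new_saliency_map <- function(raw, variant, target_class, layer_id) {
  rng <- range(raw)
  normalized <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
                else array(0, dim(raw))
  structure(list(raw = raw, normalized = normalized, variant = variant,
                 target_class = target_class, layer_id = layer_id),
            class = "saliency_map")
}

#' Grad-CAM saliency map from feature maps and gradients
#'
#' The relevance weight of channel `k` is the spatial mean of the
#' first-order class-score gradients,
#' `alpha_k = (1/Z) sum_ij dY^c/dA^k(i,j)` with `Z` the number of spatial
#' positions, and the raw map is the activation-rectified weighted sum
#' `f(sum_k alpha_k A^k(i,j); beta)`. With `activation = "relu"` this is
#' classical Grad-CAM.
#'
#' @param fmaps feature maps `(H, W, C)` (see [class_gradients()] for how
#'   to obtain them from a model, or pass any array).
#' @param grads first-order gradients shaped like `fmaps`.
#' @param beta NGNDG slope parameter for the final rectification.
#' @param activation `"ngndg"`, `"relu"` or `"elu"`.
#' @param target_class recorded in the result for provenance.
#' @return an object of class `saliency_map` with `raw` and min-max
#'   `normalized` maps.
#' @export
grad_cam <- function(fmaps, grads, beta = 1, activation = "ngndg",
                     target_class = NA_integer_) {
  if (!identical(dim(fmaps), dim(grads)))
    stop("feature maps and gradients must have identical shapes")
  d <- dim(fmaps)
  if (length(d) != 3L) stop("feature maps must be (H, W, C)")
  Z <- d[1] * d[2]
  gm <- grads; dim(gm) <- c(Z, d[3])
  alpha <- colSums(gm) / Z
  fm <- fmaps; dim(fm) <- c(Z, d[3])
  raw <- fm %*% alpha
  dim(raw) <- d[1:2]
  act <- activation_set(activation)
  new_saliency_map(act$f(raw, beta), "grad_cam", target_class,
                   attr(fmaps, "layer_id"))
}

#' Grad-CAM++ saliency map
#'
#' Builds pixel-wise weights from the 2nd/3rd-order derivatives of the
#' softmax class score: per position,
#' `alpha_ijk = d2 / (2 f'(d1) + (sum_ab A_abk) * (f''(d1) d2 + f'(d1) d3))`
#' with `d1, d2, d3` the order-1/2/3 class-score gradients and `f` the
#' chosen activation; positions with a vanishing denominator get
#' `alpha_ijk = 0`. Channel weights are
#' `omega_k = sum_ij alpha_ijk f(d1_ijk)` and the raw map is
#' `f(sum_k omega_k A^k)`. All-zero gradients produce an all-zero map with
#' a warning rather than an error.
#'
#' @inheritParams class_gradients
#' @param beta NGNDG slope parameter.
#' @param activation `"ngndg"`, `"relu"` or `"elu"`.
#' @return an object of class `saliency_map`.
#' @export
grad_cam_pp <- function(model, image, target_class, layer_id = NULL,
                        beta = 1, activation = "ngndg") {
  model <- as_net(model)
  layer_id <- resolve_layer(model, layer_id)
  A <- feature_maps(model, image, layer_id)
  d1 <- class_gradients(model, image, target_class, layer_id, 1L, "softmax")
  if (all(d1 == 0)) {
    warning("all class-score gradients are zero; returning a zero map")
    return(new_saliency_map(array(0, dim(A)[1:2]), "grad_cam_pp",
                            target_class, layer_id))
  }
  d2 <- class_gradients(model, image, target_class, layer_id, 2L, "softmax")
  d3 <- class_gradients(model, image, target_class, layer_id, 3L, "softmax")
  act <- activation_set(activation)
  dd <- dim(A)
  Asum <- colSums(matrix(A, dd[1] * dd[2], dd[3]))       # sum_ab A_abk
  Asum_full <- array(rep(Asum, each = dd[1] * dd[2]), dd)
  denom <- 2 * act$grad(d1, beta) +
    Asum_full * (act$hess(d1, beta) * d2 + act$grad(d1, beta) * d3)
  alpha <- array(0, dd)
  ok <- abs(denom) > 1e-12
  alpha[ok] <- d2[ok] / denom[ok]
  w <- alpha * act$f(d1, beta)
  omega <- colSums(matrix(w, dd[1] * dd[2], dd[3]))
  raw <- matrix(A, dd[1] * dd[2], dd[3]) %*% omega
  dim(raw) <- dd[1:2]
  new_saliency_map(act$f(raw, beta), "grad_cam_pp", target_class, layer_id)
}

#' High-level saliency interface
#'
#' Convenience wrapper producing either variant from a fitted model and an
#' image.
#'
#' @param object an `ngndg_cnn` fit or `ngndg_net`.
#' @param image a single `(H, W, C)` image.
#' @param target_class class index in `0..C-1`; default the predicted class.
#' @param variant `"gradcam"` or `"gradcampp"`.
#' @param layer_id stage name (default: last conv block).
#' @param beta NGNDG slope used for rectification; defaults to the model's.
#' @param score score convention for Grad-CAM order-1 gradients;
#'   Grad-CAM++ always differentiates the softmax score.
#' @return an object of class `saliency_map`.
#' @export
explain <- function(object, image, target_class = NULL,
                    variant = c("gradcam", "gradcampp"), layer_id = NULL,
                    beta = NULL, score = c("logit", "softmax")) {
  variant <- match.arg(variant)
  score <- match.arg(score)
  model <- as_net(object)
  if (is.null(beta)) beta <- model$beta
  if (is.null(target_class)) {
    probs <- net_predict(model, image)
    target_class <- which.max(probs[1L, ]) - 1L
  }
  if (variant == "gradcampp")
    return(grad_cam_pp(model, image, target_class, layer_id, beta,
                       model$activation))
  layer_id <- resolve_layer(model, layer_id)
  A <- feature_maps(model, image, layer_id)
  g <- class_gradients(model, image, target_class, layer_id, 1L, score)
  grad_cam(A, g, beta, model$activation, target_class)
}

as_net <- function(object) {
  if (inherits(object, "ngndg_cnn")) return(object$model)
  if (inherits(object, "ngndg_net")) return(object)
  stop("expected an ngndg_cnn fit or ngndg_net model")
}

#' Bilinear upsampling of a 2-D map
#'
#' `align_corners = FALSE` convention: output pixel centers are mapped to
#' input coordinates by `src = (dst + 0.5) * (n_in / n_out) - 0.5`, clamped
#' to the valid range, then interpolated bilinearly. Deterministic and
#' bit-exact for fixed inputs.
#'
#' @param m numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return an `out_h x out_w` matrix.
#' @export
bilinear_upsample <- function(m, out_h, out_w) {
  sy <- nrow(m) / out_h; sx <- ncol(m) / out_w
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), nrow(m) - 1)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), ncol(m) - 1)
  y0 <- pmin(floor(yc), nrow(m) - 1); y1 <- pmin(y0 + 1, nrow(m) - 1)
  x0 <- pmin(floor(xc), ncol(m) - 1); x1 <- pmin(x0 + 1, ncol(m) - 1)
  wy <- yc - y0; wx <- xc - x0
  a00 <- m[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
  a01 <- m[cbind(rep(y0 + 1, length(x1)), rep(x1 + 1, each = length(y0)))]
  a10 <- m[cbind(rep(y1 + 1, length(x0)), rep(x0 + 1, each = length(y1)))]
  a11 <- m[cbind(rep(y1 + 1, length(x1)), rep(x1 + 1, each = length(y1)))]
  WY <- rep(wy, times = out_w); WX <- rep(wx, each = out_h)
  out <- (1 - WY) * (1 - WX) * a00 + (1 - WY) * WX * a01 +
    WY * (1 - WX) * a10 + WY * WX * a11
  matrix(out, out_h, out_w)
}

heat_colormap <- function(name = c("jet", "inferno")) {
  name <- match.arg(name)
  cols <- switch(name,
    jet = c("#000080", "#0000FF", "#00FFFF", "#FFFF00", "#FF0000", "#800000"),
    inferno = c("#000004", "#56106E", "#BB3754", "#F98C0A", "#FCFFA4"))
  grDevices::colorRamp(cols)
}

#' Render a saliency overlay on an image
#'
#' Bilinearly upsamples the normalized map to the image size, maps it
#' through a colormap, and alpha-blends it over the image:
#' `(1 - alpha) * image + alpha * heat`.
#'
#' @param map a `saliency_map`.
#' @param image `(H, W, 3)` RGB image in `[0, 1]`.
#' @param colormap `"jet"` or `"inferno"`.
#' @param alpha blend weight in `[0, 1]`; 0 returns the image unchanged.
#' @return `(H, W, 3)` RGB array in `[0, 1]`, writable with
#'   [png::writePNG()].
#' @export
render_overlay <- function(map, image, colormap = "jet", alpha = 0.5) {
  stopifnot(inherits(map, "saliency_map"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be (H, W, 3)")
  up <- bilinear_upsample(map$normalized, d[1], d[2])
  cm <- heat_colormap(colormap)
  heat <- cm(as.vector(up)) / 255
  heat <- array(heat, c(d[1], d[2], 3L))
  (1 - alpha) * image + alpha * heat
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("Saliency map (", x$variant, ") for class ", x$target_class,
      " at layer ", x$layer_id %||% "?", "\n", sep = "")
  cat("  ", nrow(x$raw), "x", ncol(x$raw), " raw range [",
      signif(min(x$raw), 4), ", ", signif(max(x$raw), 4), "]\n", sep = "")
  invisible(x)
}

#' Plot a saliency map
#' @param x a `saliency_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.saliency_map <- function(x, ...) {
  graphics::image(t(x$normalized[nrow(x$normalized):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Inferno"), axes = FALSE,
                  main = paste0(x$variant, ", class ", x$target_class), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
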