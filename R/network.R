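# Network container: an ordered list of named stages, each one of
#   conv_block  - parallel branches of conv layers, channel-concatenated
#   batchnorm / maxpool / activation / flatten / dense / dropout / softmax
# Stage outputs before `flatten` use the internal (H, W, N, C) layout; after
# it they are (N, features) matrices. Saliency code addresses stages by
# name (`layer_id`), so every intermediate is capturable and the forward
# pass can be restarted from any stage boundary.

new_conv_layer <- function(k, c_in, c_out) {
  sd <- sqrt(2 / (k * k * c_in))
  list(W = array(stats::rnorm(k * k * c_in * c_out, sd = sd), c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

new_dense_layer <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

# branches: list of integer kernel-size vectors, e.g. list(c(3), c(3,3), c(3,3,1));
# filters: one filter count per branch (all convs in a branch share it)
new_conv_block <- function(name, kernels, filters, c_in) {
  branches <- vector("list", length(kernels))
  for (bi in seq_along(kernels)) {
    cin <- c_in
    convs <- vector("list", length(kernels[[bi]]))
    for (li in seq_along(kernels[[bi]])) {
      convs[[li]] <- new_conv_layer(kernels[[bi]][li], cin, filters[bi])
      convs[[li]]$k <- kernels[[bi]][li]
      cin <- filters[bi]
    }
    branches[[bi]] <- convs
  }
  list(name = name, type = "conv_block", branches = branches,
       kernels = kernels, filters = filters, c_in = c_in,
       c_out = sum(filters))
}

new_batchnorm <- function(name, C) {
  list(name = name, type = "batchnorm", gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C), momentum = 0.9, eps = 1e-5, C = C)
}

stage_forward <- function(stage, x, model, training) {
  switch(stage$type,
    conv_block = {
      bouts <- vector("list", length(stage$branches))
      bcaches <- vector("list", length(stage$branches))
      for (bi in seq_along(stage$branches)) {
        t <- x
        ccaches <- vector("list", length(stage$branches[[bi]]))
        for (li in seq_along(stage$branches[[bi]])) {
          cv <- stage$branches[[bi]][[li]]
          r <- conv2d_forward(t, cv$W, cv$b)
          ccaches[[li]] <- r$cache
          t <- r$out
        }
        bouts[[bi]] <- t
        bcaches[[bi]] <- ccaches
      }
      d <- dim(bouts[[1]])
      out <- array(unlist(bouts, use.names = FALSE),
                   c(d[1], d[2], d[3], stage$c_out))
      list(out = out,
           cache = list(bcaches = bcaches,
                        channels = vapply(bouts, function(o) dim(o)[4], 0L)))
    },
    batchnorm = {
      r <- batchnorm_forward(x, stage$gamma, stage$beta, stage$run_mean,
                             stage$run_var, training, stage$momentum, stage$eps)
      list(out = r$out, cache = r$cache,
           run_mean = r$run_mean, run_var = r$run_var)
    },
    maxpool = maxpool_forward(x),
    activation = {
      act <- activation_set(model$activation)
      list(out = act$f(x, model$beta), cache = list(x = x))
    },
    flatten = flatten_forward(x),
    dense = dense_forward(x, stage$W, stage$b),
    dropout = dropout_forward(x, stage$rate, training),
    softmax = list(out = softmax_rows(x), cache = NULL),
    stop("unknown stage type: ", stage$type)
  )
}

stage_backward <- function(stage, dout, cache, model) {
  switch(stage$type,
    conv_block = {
      ch <- cache$channels
      ends <- cumsum(ch); starts <- ends - ch + 1L
      dx <- NULL
      pgrads <- vector("list", length(stage$branches))
      for (bi in seq_along(stage$branches)) {
        d <- dout[, , , starts[bi]:ends[bi], drop = FALSE]
        cgrads <- vector("list", length(stage$branches[[bi]]))
        for (li in rev(seq_along(stage$branches[[bi]]))) {
          r <- conv2d_backward(d, cache$bcaches[[bi]][[li]])
          cgrads[[li]] <- list(W = r$dW, b = r$db)
          d <- r$dx
        }
        pgrads[[bi]] <- cgrads
        dx <- if (is.null(dx)) d else dx + d
      }
      list(dx = dx, pgrads = pgrads)
    },
    batchnorm = {
      r <- batchnorm_backward(dout, cache)
      list(dx = r$dx, pgrads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    maxpool = maxpool_backward(dout, cache),
    activation = {
      act <- activation_set(model$activation)
      list(dx = dout * act$grad(cache$x, model$beta))
    },
    flatten = flatten_backward(dout, cache),
    dense = {
      r <- dense_backward(dout, cache)
      list(dx = r$dx, pgrads = list(W = r$dW, b = r$db))
    },
    dropout = dropout_backward(dout, cache),
    stop("no backward for stage type: ", stage$type)
  )
}

# Forward pass over internal-layout input. `start_after` restarts the
# network feeding `x` as the output of that stage; `capture` names stages
# whose outputs are returned.
net_forward <- function(model, x, training = FALSE, start_after = NULL,
                        capture = NULL) {
  nm <- names(model$stages)
  i0 <- 1L
  if (!is.null(start_after)) {
    idx <- match(start_after, nm)
    if (is.na(idx)) stop("unknown layer: ", start_after)
    i0 <- idx + 1L
  }
  caches <- vector("list", length(nm)); names(caches) <- nm
  outs <- list()
  for (i in seq(i0, length(nm))) {
    r <- stage_forward(model$stages[[i]], x, model, training)
    caches[[i]] <- r$cache
    if (!is.null(r$run_mean)) {
      # running-stat updates are a side effect surfaced to the caller
      attr(caches, "bn_updates") <- c(attr(caches, "bn_updates"),
        stats::setNames(list(list(run_mean = r$run_mean, run_var = r$run_var)), nm[i]))
    }
    x <- r$out
    if (nm[i] %in% capture) outs[[nm[i]]] <- x
    if (identical(model$stages[[i]]$type, "dense") && i == length(nm) - 1L)
      logits <- x
  }
  if (!exists("logits", inherits = FALSE)) logits <- NULL
  list(probs = x, logits = logits, caches = caches, outs = outs,
       start_index = i0)
}

# Backward from a gradient on the logits (input of the final softmax).
# Returns parameter gradients named by stage, plus the gradient with
# respect to the output of `stop_at` (or the network input if NULL).
net_backward <- function(model, caches, dlogits, stop_at = NULL,
                         stop_index = 1L) {
  nm <- names(model$stages)
  M <- length(nm)
  stopifnot(identical(model$stages[[M]]$type, "softmax"))
  d <- dlogits
  pgrads <- list()
  for (i in seq(M - 1L, 1L)) {
    if (!is.null(stop_at) && nm[i] == stop_at)
      return(list(pgrads = pgrads, dx = d))
    if (i < stop_index) break
    r <- stage_backward(model$stages[[i]], d, caches[[i]], model)
    if (!is.null(r$pgrads)) pgrads[[nm[i]]] <- r$pgrads
    d <- r$dx
  }
  list(pgrads = pgrads, dx = d)
}

apply_bn_updates <- function(model, caches) {
  ups <- attr(caches, "bn_updates")
  for (nmi in names(ups)) {
    model$stages[[nmi]]$run_mean <- ups[[nmi]]$run_mean
    model$stages[[nmi]]$run_var <- ups[[nmi]]$run_var
  }
  model
}

# --- trainable parameter plumbing -------------------------------------------

# Deterministically named flat list of trainable arrays.
collect_params <- function(model) {
  out <- list()
  for (st in model$stages) {
    if (st$type == "conv_block") {
      for (bi in seq_along(st$branches))
        for (li in seq_along(st$branches[[bi]])) {
          key <- sprintf("%s.b%d.c%d", st$name, bi, li)
          out[[paste0(key, ".W")]] <- st$branches[[bi]][[li]]$W
          out[[paste0(key, ".b")]] <- st$branches[[bi]][[li]]$b
        }
    } else if (st$type == "batchnorm") {
      out[[paste0(st$name, ".gamma")]] <- st$gamma
      out[[paste0(st$name, ".beta")]] <- st$beta
    } else if (st$type == "dense") {
      out[[paste0(st$name, ".W")]] <- st$W
      out[[paste0(st$name, ".b")]] <- st$b
    }
  }
  out
}

set_params <- function(model, params) {
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    if (st$type == "conv_block") {
      for (bi in seq_along(st$branches))
        for (li in seq_along(st$branches[[bi]])) {
          key <- sprintf("%s.b%d.c%d", st$name, bi, li)
          model$stages[[i]]$branches[[bi]][[li]]$W <- params[[paste0(key, ".W")]]
          model$stages[[i]]$branches[[bi]][[li]]$b <- params[[paste0(key, ".b")]]
        }
    } else if (st$type == "batchnorm") {
      model$stages[[i]]$gamma <- params[[paste0(st$name, ".gamma")]]
      model$stages[[i]]$beta <- params[[paste0(st$name, ".beta")]]
    } else if (st$type == "dense") {
      model$stages[[i]]$W <- params[[paste0(st$name, ".W")]]
      model$stages[[i]]$b <- params[[paste0(st$name, ".b")]]
    }
  }
  model
}

# Flatten the nested per-stage gradients from net_backward into the same
# naming scheme as collect_params; stages absent from pgrads yield zeros.
collect_grads <- function(model, pgrads) {
  ref <- collect_params(model)
  out <- lapply(ref, function(a) { z <- a; z[] <- 0; z })
  for (nmi in names(pgrads)) {
    st <- model$stages[[nmi]]
    g <- pgrads[[nmi]]
    if (st$type == "conv_block") {
      for (bi in seq_along(g))
        for (li in seq_along(g[[bi]])) {
          key <- sprintf("%s.b%d.c%d", nmi, bi, li)
          out[[paste0(key, ".W")]] <- g[[bi]][[li]]$W
          out[[paste0(key, ".b")]] <- g[[bi]][[li]]$b
        }
    } else if (st$type == "batchnorm") {
      out[[paste0(nmi, ".gamma")]] <- g$gamma
      out[[paste0(nmi, ".beta")]] <- g$beta
    } else if (st$type == "dense") {
      out[[paste0(nmi, ".W")]] <- g$W
      out[[paste0(nmi, ".b")]] <- g$b
    }
  }
  out
}

# --- public batch layout conversion -----------------------------------------

# (N, H, W, C) -> (H, W, N, C)
to_internal <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  aperm(x, c(2L, 3L, 1L, 4L))
}

# (H, W, N, C) -> (N, H, W, C)
to_public <- function(x) aperm(x, c(3L, 1L, 2L, 4L))
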