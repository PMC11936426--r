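#' Sparse categorical cross-entropy
#'
#' `L = -(1/N) * sum_i log p[i, label_i]` for integer-coded labels. The log
#' argument is floored at `1e-12` for numerical safety. With `weights`
#' (one per sample) the loss is the weighted mean, which is how optional
#' inverse-frequency class weighting enters.
#'
#' @param probs `(N, C)` matrix of predicted class probabilities; each row
#'   must sum to 1 within `tol`.
#' @param labels integer class indices in `0..C-1` (or a factor).
#' @param weights optional nonnegative per-sample weights.
#' @param tol allowed deviation of a row sum from 1.
#' @return a single nonnegative number.
#' @export
sparse_ce_loss <- function(probs, labels, weights = NULL, tol = 1e-6) {
  probs <- as.matrix(probs)
  labels <- as_label_index(labels, ncol(probs))
  if (nrow(probs) != length(labels))
    stop("probs and labels disagree on the number of samples")
  if (any(abs(rowSums(probs) - 1) > tol))
    stop("probability rows must sum to 1 (within ", tol, ")")
  p <- pmax(probs[cbind(seq_len(nrow(probs)), labels + 1L)], 1e-12)
  if (is.null(weights)) mean(-log(p)) else
    sum(weights * -log(p)) / sum(weights)
}

as_label_index <- function(labels, n_classes) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= n_classes))
    stop("labels must be integer class indices in [0, ", n_classes, ")")
  labels
}

#' Hand-derived gradients for a dense NGNDG-softmax layer
#'
#' The reference setting for the loss-gradient chain: inputs `z` feed a
#' single dense layer `x = z %*% W + b`, the NGNDG activation `a = f(x)`
#' is applied, and class probabilities are `p = softmax(a)` scored by
#' sparse categorical cross-entropy. The gradients are assembled by the
#' chain rule loss -> probability -> activation derivative -> parameter:
#' `dL/da = (p - y)/N` (the softmax Jacobian contracted against the
#' cross-entropy term), `dL/dx = dL/da * f'(x)` with the analytic NGNDG
#' derivative, `dL/dW = t(z) %*% dL/dx`, `dL/db = colSums(dL/dx)`.
#'
#' @param W `(n_in, C)` weight matrix.
#' @param b length-`C` bias.
#' @param z `(N, n_in)` layer inputs.
#' @param labels integer class indices in `0..C-1`.
#' @param beta NGNDG slope parameter.
#' @return list with `dW`, `db`, `loss`, `probs`.
#' @export
manual_gradients <- function(W, b, z, labels, beta = 1) {
  z <- as.matrix(z)
  if (ncol(z) != nrow(W)) stop("z and W are not conformable")
  N <- nrow(z); C <- ncol(W)
  labels <- as_label_index(labels, C)
  x <- sweep(z %*% W, 2L, b, `+`)
  a <- ngndg(x, beta)
  p <- softmax_rows(a)
  y <- matrix(0, N, C); y[cbind(seq_len(N), labels + 1L)] <- 1
  da <- (p - y) / N
  dx <- da * ngndg_grad(x, beta)
  list(dW = crossprod(z, dx), db = colSums(dx),
       loss = sparse_ce_loss(p, labels), probs = p)
}

#' Adam optimizer state
#'
#' Standard Adam: exponential moving averages of the gradient (`m`) and the
#' squared gradient (`v`), bias-corrected, with the update
#' `theta <- theta - alpha * m_hat / (sqrt(v_hat) + epsilon)`.
#'
#' @param theta named list of parameter arrays (or a single array).
#' @param alpha learning rate.
#' @param beta1,beta2 moment decay rates in `[0, 1)`.
#' @param epsilon positive stabilizer.
#' @return an object of class `adam_state` carrying `theta`, the moments
#'   and the step counter `t`.
#' @export
adam_init <- function(theta, alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8) {
  theta <- as_param_list(theta)
  zero <- lapply(theta, function(a) { z <- a; z[] <- 0; z })
  structure(list(theta = theta, m = zero, v = zero, t = 0L,
                 alpha = alpha, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon),
            class = "adam_state")
}

#' One Adam update
#'
#' @param state an [adam_init()] state.
#' @param grads gradients shaped like `state$theta`.
#' @return the updated state; `state$theta` holds the new parameters.
#' @export
adam_step <- function(state, grads) {
  grads <- as_param_list(grads)
  check_conformable(state$theta, grads)
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (k in names(state$theta)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    mhat <- state$m[[k]] / c1
    vhat <- state$v[[k]] / c2
    state$theta[[k]] <- state$theta[[k]] -
      state$alpha * mhat / (sqrt(vhat) + state$epsilon)
  }
  state
}

#' RMSprop optimizer state
#'
#' Textbook RMSprop: `v <- rho * v + (1 - rho) * g^2`,
#' `theta <- theta - alpha * g / (sqrt(v) + epsilon)`.
#'
#' @inheritParams adam_init
#' @param rho squared-gradient decay rate.
#' @return an object of class `rmsprop_state`.
#' @export
rmsprop_init <- function(theta, alpha = 0.001, rho = 0.9, epsilon = 1e-8) {
  theta <- as_param_list(theta)
  structure(list(theta = theta,
                 v = lapply(theta, function(a) { z <- a; z[] <- 0; z }),
                 alpha = alpha, rho = rho, epsilon = epsilon, t = 0L),
            class = "rmsprop_state")
}

#' One RMSprop update
#' @param state an [rmsprop_init()] state.
#' @param grads gradients shaped like `state$theta`.
#' @return the updated state.
#' @export
rmsprop_step <- function(state, grads) {
  grads <- as_param_list(grads)
  check_conformable(state$theta, grads)
  state$t <- state$t + 1L
  for (k in names(state$theta)) {
    g <- grads[[k]]
    state$v[[k]] <- state$rho * state$v[[k]] + (1 - state$rho) * g * g
    state$theta[[k]] <- state$theta[[k]] -
      state$alpha * g / (sqrt(state$v[[k]]) + state$epsilon)
  }
  state
}

as_param_list <- function(theta) {
  if (!is.list(theta)) theta <- list(par = theta)
  if (is.null(names(theta)) || any(names(theta) == ""))
    names(theta) <- paste0("par", seq_along(theta))
  theta
}

check_conformable <- function(theta, grads) {
  if (!identical(names(theta), names(grads)) ||
      !all(mapply(function(a, g) length(a) == length(g), theta, grads)))
    stop("gradients are not shaped like the parameters")
  invisible(TRUE)
}
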