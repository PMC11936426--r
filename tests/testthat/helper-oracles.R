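# Shared oracles and fixtures. All finite-difference code here is
# deliberately independent of the analytic code paths it checks.

# central difference, O(h^2)
fd_central <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# 4th-order central difference, O(h^4): the high-precision derivative
# oracle used where 1e-6 absolute agreement is demanded
fd_central4 <- function(f, x, h = 1e-4) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}

# central second and third differences
fd_second <- function(f, x, h = 5e-4) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
fd_third <- function(f, x, h = 5e-3) {
  (f(x + 2 * h) - 2 * f(x + h) + 2 * f(x - h) - f(x - 2 * h)) / (2 * h^3)
}

# numeric gradient of a scalar function of an array, one coordinate at a time
fd_grad_array <- function(f, x, idx = seq_along(x), h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Independent transcription of the canonical Adam recurrence (scalar or
# vector parameter), used as the reference trajectory.
reference_adam_run <- function(theta0, grad_fn, steps, alpha = 0.001,
                               beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  theta <- theta0
  m <- v <- theta0 * 0
  path <- matrix(NA_real_, steps, length(theta0))
  for (t in seq_len(steps)) {
    g <- grad_fn(theta)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    theta <- theta - alpha * mhat / (sqrt(vhat) + eps)
    path[t, ] <- theta
  }
  path
}

# tiny toy fixture shared by the saliency tests
toy_fixture <- function(seed = 11L, beta = 1) {
  model <- toy_conv_net(seed = seed, beta = beta)
  set.seed(seed + 100L)
  image <- array(runif(8 * 8 * 3), c(8, 8, 3))
  list(model = model, image = image)
}

# softmax score of the toy head as a plain function of the feature maps,
# used to take nested finite differences against class_gradients
toy_head_score <- function(model, layer_id, A, class0, kind = "softmax") {
  r <- ngndgnet:::head_score(model, layer_id, A)
  if (kind == "softmax") r$probs[class0 + 1L] else r$logits[class0 + 1L]
}

# small deterministic image batch
random_images <- function(n, shape = c(28L, 28L, 3L), seed = 1L) {
  set.seed(seed)
  array(runif(n * prod(shape)), c(n, shape))
}
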