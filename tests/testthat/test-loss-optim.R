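test_that("sparse cross-entropy closed forms and guards", {
  expect_equal(sparse_ce_loss(matrix(c(0, 1, 0), 1), 1L), 0)
  expect_equal(sparse_ce_loss(matrix(rep(1 / 7, 7), 1), 3L), log(7),
               tolerance = 1e-12)
  p2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  expect_equal(sparse_ce_loss(p2, c(0L, 1L)), log(2))
  # nonnegative, zero iff all correct probabilities are 1
  expect_gt(sparse_ce_loss(matrix(c(0.9, 0.1), 1), 0L), 0)
  expect_error(sparse_ce_loss(matrix(c(0.6, 0.6), 1), 0L), "sum to 1")
  expect_error(sparse_ce_loss(matrix(c(0.5, 0.5), 1), 2L), "labels")
  # weighted form reduces to the weighted mean of per-sample terms
  w <- c(2, 1)
  expect_equal(sparse_ce_loss(p2, c(0L, 1L), weights = w),
               (2 * log(2) + log(2)) / 3)
})

test_that("hand-derived dense-layer gradients match high-order finite differences", {
  # bias gradient vanishes by symmetry on a balanced two-class toy with
  # zero weights (uniform probabilities, labels split evenly)
  W0 <- matrix(0, 3, 2); b0 <- c(0, 0)
  z0 <- matrix(rnorm(12), 4, 3)
  g0 <- manual_gradients(W0, b0, z0, c(0L, 1L, 0L, 1L), beta = 1)
  expect_equal(g0$db, c(0, 0), tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:20) {
    beta <- sample(c(0.5, 1, 2), 1)
    W <- matrix(rnorm(12, sd = 1.2), 4, 3)   # spreads x over both branches
    b <- rnorm(3)
    z <- matrix(rnorm(20), 5, 4)
    y <- sample(0:2, 5, replace = TRUE)
    g <- manual_gradients(W, b, z, y, beta)
    lf_W <- function(ww) manual_gradients(matrix(ww, 4, 3), b, z, y, beta)$loss
    lf_b <- function(bb) manual_gradients(W, bb, z, y, beta)$loss
    fdW <- fd_grad_array(lf_W, as.vector(W))
    fdb <- fd_grad_array(lf_b, b)
    # relative 1e-5 against plain central differences
    expect_lt(max(abs(fdW - as.vector(g$dW))) / max(abs(fdW)), 1e-5)
    expect_lt(max(abs(fdb - g$db)) / max(abs(fdb), 1), 1e-5)
    # 1e-6 absolute against the 4th-order oracle
    fdW4 <- vapply(seq_along(W), function(i)
      fd_central4(function(v) { w2 <- W; w2[i] <- v; lf_W(w2) }, W[i]),
      numeric(1))
    expect_lt(max(abs(fdW4 - as.vector(g$dW))), 1e-6)
  }
})

test_that("pre-activations in the gradient fixture actually span both branches", {
  set.seed(9)
  beta <- sample(c(0.5, 1, 2), 1)
  W <- matrix(rnorm(12, sd = 1.2), 4, 3); b <- rnorm(3)
  z <- matrix(rnorm(20), 5, 4)
  x <- sweep(z %*% W, 2, b, `+`)
  expect_gt(sum(x > 0), 0)
  expect_gt(sum(x < 0), 0)
})

test_that("adam: null update, unit first step, convergence on a quadratic", {
  st <- adam_init(c(w = 1.5), alpha = 0.1)
  st0 <- adam_step(st, c(par = 0))
  expect_equal(unname(st0$theta$par), 1.5)
  # first step with nonzero gradient moves by ~ -alpha * sign(g)
  st1 <- adam_step(st, c(w = 0.37))
  expect_equal(unname(st1$theta$par), 1.5 - 0.1 * 0.37 / (abs(0.37) + 1e-8),
               tolerance = 1e-12)
  expect_equal(unname(st1$theta$par), 1.5 - 0.1, tolerance = 1e-4)
  # 200 steps on (w - 3)^2 from w0 = 0 at alpha = 0.1
  st <- adam_init(c(w = 0), alpha = 0.1)
  for (i in 1:200) st <- adam_step(st, c(w = 2 * (st$theta$par - 3)))
  expect_lt(abs(st$theta$par - 3), 1e-2)
})

test_that("adam trajectory matches the reference recurrence to 1e-10", {
  set.seed(10)
  A <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  bb <- rnorm(3)
  grad_fn <- function(th) as.vector(A %*% th - bb)
  th0 <- rnorm(3)
  ref <- reference_adam_run(th0, grad_fn, steps = 100, alpha = 0.01)
  st <- adam_init(list(par = th0), alpha = 0.01)
  path <- matrix(NA_real_, 100, 3)
  for (t in 1:100) {
    st <- adam_step(st, list(par = grad_fn(st$theta$par)))
    path[t, ] <- st$theta$par
  }
  expect_lt(max(abs(path - ref)), 1e-10)
})

test_that("rmsprop follows its textbook recurrence and descends", {
  st <- rmsprop_init(c(w = 0), alpha = 0.05)
  g1 <- 2 * (0 - 3)
  st <- rmsprop_step(st, c(w = g1))
  v1 <- 0.1 * g1^2
  expect_equal(unname(st$theta$par), 0 - 0.05 * g1 / (sqrt(v1) + 1e-8))
  for (i in 1:300) st <- rmsprop_step(st, c(w = 2 * (st$theta$par - 3)))
  expect_lt(abs(st$theta$par - 3), 0.1)
})

test_that("optimizers reject malformed gradients", {
  st <- adam_init(list(a = matrix(0, 2, 2)))
  expect_error(adam_step(st, list(a = matrix(0, 3, 3))), "shaped")
  expect_error(adam_step(st, list(b = matrix(0, 2, 2))), "shaped")
})
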