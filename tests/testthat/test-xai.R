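# Saliency machinery checked against nested finite differences on a tiny
# network whose head (feature maps -> logits) is affine, the setting in
# which the closed-form higher-order class-score derivatives are exact.

test_that("order-1 logit gradients on an affine head are the dense weights", {
  fx <- toy_fixture(11)
  A <- ngndgnet:::feature_maps(fx$model, fx$image, "conv2_act")
  Wfc <- fx$model$stages$fc$W
  for (cls in c(0L, 2L, 4L)) {
    g <- class_gradients(fx$model, fx$image, cls, "conv2_act", 1L, "logit")
    expect_equal(as.vector(g), Wfc[, cls + 1L], tolerance = 1e-12)
  }
  # second derivative of an affine map is identically zero
  g2 <- class_gradients(fx$model, fx$image, 1L, "conv2_act", 2L, "logit")
  expect_true(all(g2 == 0))
})

test_that("softmax-score gradients of orders 1-3 match nested finite differences", {
  fx <- toy_fixture(11)
  A <- ngndgnet:::feature_maps(fx$model, fx$image, "conv2_act")
  cls <- 2L
  sc <- function(Amod) toy_head_score(fx$model, "conv2_act", Amod, cls)
  set.seed(21)
  idx <- sample(length(A), 6)
  tols <- c(1e-4, 1e-3, 1e-2)
  for (ord in 1:3) {
    d <- class_gradients(fx$model, fx$image, cls, "conv2_act", ord, "softmax")
    for (i in idx) {
      f1 <- function(v) { A2 <- A; A2[i] <- A2[i] + v; sc(A2) }
      fdv <- switch(ord,
        fd_central(f1, 0, h = 1e-5),
        fd_second(f1, 0, h = 5e-4),
        fd_third(f1, 0, h = 5e-3))
      expect_lt(abs(fdv - d[i]), tols[ord])
    }
  }
})

test_that("grad_cam implements mean-gradient channel weights and rectification", {
  set.seed(22)
  # one channel, unit gradients -> alpha = 1 -> map is f(A)
  A1 <- array(rnorm(16), c(4, 4, 1))
  sm <- grad_cam(A1, array(1, c(4, 4, 1)), beta = 1)
  expect_equal(sm$raw, ngndg(A1[, , 1], 1))
  # zero gradients -> zero map
  sm0 <- grad_cam(A1, array(0, c(4, 4, 1)), beta = 1)
  expect_true(all(sm0$raw == 0))
  expect_true(all(sm0$normalized == 0))
  # two channels 2x2 with hand-picked integers, brute-force arithmetic
  A <- array(c(1, 2, 3, 4, -1, 0, 2, -3), c(2, 2, 2))
  G <- array(c(4, 0, 0, 0, 0, 0, 0, -8), c(2, 2, 2))
  alpha <- c(sum(G[, , 1]) / 4, sum(G[, , 2]) / 4)   # (1, -2)
  expected <- ngndg(alpha[1] * A[, , 1] + alpha[2] * A[, , 2], 1.5)
  sm <- grad_cam(A, G, beta = 1.5)
  expect_equal(sm$raw, expected)
  expect_error(grad_cam(A, G[, , 1, drop = FALSE]), "identical shapes")
})

test_that("doubling gradients doubles channel weights; positive region scales exactly", {
  set.seed(23)
  A <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  G <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  s1 <- grad_cam(A, G, beta = 2)
  s2 <- grad_cam(A, 2 * G, beta = 2)
  pos <- s1$raw > 0
  expect_identical(s2$raw[pos], 2 * s1$raw[pos])
})

test_that("with ReLU rectification grad_cam reproduces classical Grad-CAM bit for bit", {
  fx <- toy_fixture(31)
  A <- ngndgnet:::feature_maps(fx$model, fx$image, "conv2_act")
  g <- class_gradients(fx$model, fx$image, 1L, "conv2_act", 1L, "logit")
  sm <- grad_cam(A, g, beta = 1, activation = "relu")
  # independent classical computation
  alpha <- apply(g, 3, mean)
  weighted <- matrix(A, 16, 3) %*% alpha
  classical <- pmax(matrix(weighted, 4, 4), 0)
  expect_identical(sm$raw, classical)
})

test_that("saliency normalization is in [0,1] and affine-invariant", {
  set.seed(24)
  A <- array(rnorm(32), c(4, 4, 2)); G <- array(rnorm(32), c(4, 4, 2))
  sm <- grad_cam(A, G)
  expect_true(all(sm$normalized >= 0 & sm$normalized <= 1))
  # positive affine rescaling of the raw map leaves the normalization fixed
  re <- ngndgnet:::new_saliency_map(3.2 * sm$raw + 0.7, "grad_cam", 0L, NULL)
  expect_equal(re$normalized, sm$normalized, tolerance = 1e-12)
})

test_that("grad_cam_pp matches an independent recomputation from FD derivatives", {
  fx <- toy_fixture(41)
  cls <- 3L
  A <- ngndgnet:::feature_maps(fx$model, fx$image, "conv2_act")
  sm <- grad_cam_pp(fx$model, fx$image, cls, "conv2_act", beta = 1)
  # recompute every derivative by nested finite differences and push them
  # through the pixel-weight formula written out independently here
  sc <- function(Amod) toy_head_score(fx$model, "conv2_act", Amod, cls)
  d1 <- d2 <- d3 <- array(0, dim(A))
  for (i in seq_along(A)) {
    f1 <- function(v) { A2 <- A; A2[i] <- A2[i] + v; sc(A2) }
    d1[i] <- fd_central(f1, 0, h = 1e-5)
    d2[i] <- fd_second(f1, 0, h = 5e-4)
    d3[i] <- fd_third(f1, 0, h = 5e-3)
  }
  dd <- dim(A)
  Asum <- rep(colSums(matrix(A, dd[1] * dd[2], dd[3])), each = dd[1] * dd[2])
  den <- 2 * ngndg_grad(d1, 1) +
    Asum * (ngndg_hess(d1, 1) * d2 + ngndg_grad(d1, 1) * d3)
  alpha <- ifelse(abs(den) > 1e-12, d2 / den, 0)
  omega <- colSums(matrix(alpha * ngndg(d1, 1), dd[1] * dd[2], dd[3]))
  raw <- ngndg(matrix(matrix(A, dd[1] * dd[2], dd[3]) %*% omega, dd[1], dd[2]), 1)
  expect_equal(sm$raw, raw, tolerance = 1e-3)
})

test_that("a head detached from the chosen layer yields a zero map with a warning", {
  fx <- toy_fixture(51)
  model <- fx$model
  model$stages$fc$W[] <- 0    # logits no longer depend on the feature maps
  expect_warning(sm <- grad_cam_pp(model, fx$image, 1L, "conv2_act"),
                 "zero map")
  expect_true(all(sm$raw == 0))
})

test_that("explain dispatches variants and validates classes and layers", {
  fx <- toy_fixture(61)
  s1 <- explain(fx$model, fx$image, 0L, variant = "gradcam")
  expect_s3_class(s1, "saliency_map")
  expect_equal(s1$variant, "grad_cam")
  s2 <- explain(fx$model, fx$image, 0L, variant = "gradcampp")
  expect_equal(s2$variant, "grad_cam_pp")
  # default target class is the argmax prediction
  s3 <- explain(fx$model, fx$image)
  pred <- which.max(net_predict(fx$model, fx$image)[1, ]) - 1L
  expect_equal(s3$target_class, pred)
  expect_error(explain(fx$model, fx$image, 0L, layer_id = "nope"), "unknown layer")
  expect_error(class_gradients(fx$model, fx$image, 99L, "conv2_act"), "target_class")
})

test_that("bilinear upsampling matches hand-computed weights (align_corners = FALSE)", {
  m <- matrix(c(0, 2, 1, 3), 2, 2)   # m[1,1]=0 m[2,1]=2 m[1,2]=1 m[2,2]=3
  up <- bilinear_upsample(m, 4, 4)
  # src coordinate for dst j: (j + 0.5)/2 - 0.5 -> 0 maps to -0.25 (clamped 0)
  # hand-computed corner and center values
  expect_equal(up[1, 1], 0)
  expect_equal(up[4, 4], 3)
  expect_equal(up[2, 2], 0 * 0.75 * 0.75 + 1 * 0.75 * 0.25 +
                 2 * 0.25 * 0.75 + 3 * 0.25 * 0.25)
  expect_equal(up[3, 3], 0 * 0.25 * 0.25 + 1 * 0.25 * 0.75 +
                 2 * 0.75 * 0.25 + 3 * 0.75 * 0.75)
  # identity when sizes match
  expect_equal(bilinear_upsample(m, 2, 2), m)
})

test_that("overlay blending follows (1-alpha) image + alpha heat", {
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  zero_map <- ngndgnet:::new_saliency_map(matrix(0, 2, 2), "grad_cam", 0L, NULL)
  # alpha = 0 is a no-op
  expect_equal(render_overlay(zero_map, img, alpha = 0), img)
  # all-zero map blends the colormap's zero color everywhere
  ov <- render_overlay(zero_map, img, alpha = 0.4)
  zero_col <- ngndgnet:::heat_colormap("jet")(0) / 255
  for (ch in 1:3)
    expect_equal(ov[, , ch], 0.6 * img[, , ch] + 0.4 * zero_col[ch])
  expect_error(render_overlay(zero_map, img, alpha = 1.5), "alpha")
})
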