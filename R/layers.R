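# Low-level differentiable layer primitives.
#
# Internal batch layout is (H, W, N, C): spatial dims first so that a
# kernel-offset slice of the padded input is a contiguous-enough array that
# reshapes straight into the GEMM operand, and channels last so that
# branch concatenation along channels is plain memory concatenation.
# Public image batches are (N, H, W, C) and converted at the boundary.
# Every forward returns list(out, cache); every backward takes (dout, cache)
# and returns list(dx, and parameter gradients where the layer has any).

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# 2-D convolution, stride 1, zero "same" padding, odd square kernel.
# x: (H, W, N, Cin); W: (k, k, Cin, Cout); b: length Cout.
# Computed as a sum of k*k shifted GEMMs rather than one im2col, which
# keeps peak memory small and the backward pass symmetric.
conv2d_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x, p)
  out <- matrix(rep(b, each = H * Wd * N), H * Wd * N, Cout)
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      S <- xp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , , drop = FALSE]
      dim(S) <- c(H * Wd * N, Cin)
      out <- out + S %*% matrix(W[dy, dx, , ], Cin, Cout)
    }
  }
  dim(out) <- c(H, Wd, N, Cout)
  list(out = out, cache = list(xp = xp, dims = d, W = W, k = k, p = p))
}

conv2d_backward <- function(dout, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  W <- cache$W; k <- cache$k; p <- cache$p
  Cout <- dim(W)[4]
  dmat <- dout
  dim(dmat) <- c(H * Wd * N, Cout)
  dW <- array(0, dim(W))
  # dx is the correlation of dout with the kernel flipped in both spatial
  # directions: same shifted-GEMM structure as the forward pass, which
  # avoids any read-modify-write on padded slices.
  doutp <- dout
  dim(doutp) <- c(H, Wd, N, Cout)
  doutp <- pad_hw(doutp, p)
  dxm <- matrix(0, H * Wd * N, Cin)
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      S <- cache$xp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , , drop = FALSE]
      dim(S) <- c(H * Wd * N, Cin)
      dW[dy, dx, , ] <- crossprod(S, dmat)
      D <- doutp[(k - dy + 1L):(k - dy + H), (k - dx + 1L):(k - dx + Wd), , ,
                 drop = FALSE]
      dim(D) <- c(H * Wd * N, Cout)
      dxm <- dxm + D %*% t(matrix(W[dy, dx, , ], Cin, Cout))
    }
  }
  dim(dxm) <- c(H, Wd, N, Cin)
  list(dx = dxm, dW = dW, db = colSums(dmat))
}

# 2x2 max pooling, stride 2; a trailing odd row/column is dropped.
# Ties route their gradient to the first maximal position in the fixed
# candidate order (top-left, bottom-left, top-right, bottom-right), so the
# backward pass is deterministic.
maxpool_forward <- function(x) {
  d <- dim(x); H2 <- 2L * (d[1] %/% 2L); W2 <- 2L * (d[2] %/% 2L)
  ri <- seq(1L, H2, by = 2L); ci <- seq(1L, W2, by = 2L)
  cand <- list(
    x[ri,      ci,      , , drop = FALSE],
    x[ri + 1L, ci,      , , drop = FALSE],
    x[ri,      ci + 1L, , , drop = FALSE],
    x[ri + 1L, ci + 1L, , , drop = FALSE]
  )
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  list(out = out, cache = list(cand = cand, out = out, dims = d, ri = ri, ci = ci))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  assigned <- array(FALSE, dim(cache$out))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (m in seq_along(cache$cand)) {
    mask <- (cache$cand[[m]] == cache$out) & !assigned
    assigned <- assigned | mask
    g <- dout * mask
    dx[cache$ri + offs[[m]][1], cache$ci + offs[[m]][2], , ] <-
      dx[cache$ri + offs[[m]][1], cache$ci + offs[[m]][2], , , drop = FALSE] + g
  }
  list(dx = dx)
}

# Batch normalization over (H, W, N) per channel; population variance for
# the batch statistics, exponential running averages for eval mode.
batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2] * d[3]; C <- d[4]
  xm <- x; dim(xm) <- c(m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- xm - rep(mu, each = m)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = m)
  out <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d,
                    training = training, m = m),
       run_mean = run_mean, run_var = run_var)
}

batchnorm_backward <- function(dout, cache) {
  d <- cache$dims; m <- cache$m; C <- d[4]
  dom <- dout; dim(dom) <- c(m, C)
  dgamma <- colSums(dom * cache$xhat)
  dbeta <- colSums(dom)
  dxhat <- dom * rep(cache$gamma, each = m)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- (m * dxhat - rep(s1, each = m) - cache$xhat * rep(s2, each = m)) *
      rep(cache$inv / m, each = m)
  } else {
    # eval mode is an affine map per channel
    dx <- dxhat * rep(cache$inv, each = m)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# (H, W, N, C) -> (N, H*W*C); feature order within a row is (H, W, C)
flatten_forward <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  list(out = t(xp), cache = list(dims = d))
}

flatten_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- t(dout)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1L, 2L, 4L, 3L)))
}

dense_forward <- function(z, W, b) {
  out <- z %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(z = z, W = W))
}

dense_backward <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$z, dout),
       db = colSums(dout))
}

# inverted dropout; identity in eval mode
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) return(list(dx = dout))
  list(dx = dout * cache$mask)
}

# numerically stable row softmax
softmax_rows <- function(a) {
  a <- a - apply(a, 1L, max)
  e <- exp(a)
  e / rowSums(e)
}
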