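#' The NGNDG activation function
#'
#' Piecewise algebraic activation: `beta * x` for `x >= 0` and
#' `beta * x / (1 + x^2)` for `x < 0`, applied elementwise. The negative
#' branch is a rational tail that vanishes as `x -> -Inf`, reaches its
#' extremum `-beta/2` at `x = -1` (for `beta > 0`), and meets the linear
#' branch continuously at 0 with value 0. `beta` scales both branches
#' linearly, so `ngndg(x, beta) == beta * ngndg(x, 1)`; a negative `beta`
#' flips the sign of both branches.
#'
#' @param x numeric vector or array of pre-activations; must be finite.
#' @param beta scalar slope/polarity parameter. `beta = 0` collapses the
#'   function to zero everywhere; it is allowed here (useful for probing)
#'   but rejected by the model builder.
#' @return numeric object of the same shape as `x`.
#' @seealso [ngndg_grad()] for the analytic derivative,
#'   [reference_activation()] for ReLU/ELU baselines.
#' @examples
#' ngndg(c(-3, -1, 0, 2), beta = 1)
#' @export
ngndg <- function(x, beta = 1) {
  check_finite(x, "x")
  check_beta(beta)
  neg <- x < 0
  out <- beta * x
  # beta multiplies last so that f(x, beta) == beta * f(x, 1) holds exactly
  out[neg] <- beta * (x[neg] / (1 + x[neg]^2))
  out
}

#' Analytic derivative of the NGNDG activation
#'
#' Returns `beta` for `x >= 0` and `beta * (1 - x^2) / (1 + x^2)^2` for
#' `x < 0`. Both one-sided derivatives at 0 equal `beta`, so the function is
#' differentiable there and no subgradient convention is needed; the value
#' at exactly 0 is `beta`.
#'
#' @inheritParams ngndg
#' @return numeric object of the same shape as `x`.
#' @export
ngndg_grad <- function(x, beta = 1) {
  check_finite(x, "x")
  check_beta(beta)
  neg <- x < 0
  out <- rep_like(beta, x)
  out[neg] <- beta * ((1 - x[neg]^2) / (1 + x[neg]^2)^2)
  out
}

#' Second derivative of the NGNDG activation
#'
#' Zero on the linear branch (`x > 0`) and
#' `-2 beta x (3 - x^2) / (1 + x^2)^3` for `x < 0`. At 0 the convention
#' value is 0 (the right second derivative). Needed by the Grad-CAM++
#' pixel-weight denominator, where the activation's curvature enters.
#'
#' @inheritParams ngndg
#' @return numeric object of the same shape as `x`.
#' @export
ngndg_hess <- function(x, beta = 1) {
  check_finite(x, "x")
  check_beta(beta)
  neg <- x < 0
  out <- rep_like(0, x)
  out[neg] <- beta * (-2 * x[neg] * (3 - x[neg]^2) / (1 + x[neg]^2)^3)
  out
}

#' Reference activations for comparison harnesses
#'
#' Standard ReLU (`max(0, x)`) and ELU (`x` for `x >= 0`,
#' `param * (exp(x) - 1)` for `x < 0`) used as benchmark rectifiers next to
#' [ngndg()].
#'
#' @param name `"relu"` or `"elu"`.
#' @param x numeric vector or array; must be finite.
#' @param param ELU scale parameter (ignored for ReLU).
#' @return numeric object of the same shape as `x`.
#' @export
reference_activation <- function(name, x, param = 1) {
  check_finite(x, "x")
  switch(match_activation_name(name),
    relu = pmax(x, 0),
    elu  = ifelse(x >= 0, x, param * (expm1(x)))
  )
}

match_activation_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% c("relu", "elu")))
    stop("unknown reference activation: ", paste(name, collapse = ", "),
         " (expected 'relu' or 'elu')")
  name
}

#' Activation registry
#'
#' Resolves an activation by name to its forward map, first derivative and
#' (where defined) second derivative, for use by the model builder and the
#' saliency formulas. `"ngndg"` takes `beta` from the caller at evaluation
#' time; `"relu"` and `"elu"` ignore it.
#'
#' @param name one of `"ngndg"`, `"relu"`, `"elu"`.
#' @return a list with functions `f(x, beta)`, `grad(x, beta)` and
#'   `hess(x, beta)`.
#' @export
activation_set <- function(name = c("ngndg", "relu", "elu")) {
  name <- match.arg(name)
  switch(name,
    ngndg = list(
      name = "ngndg",
      f    = function(x, beta = 1) ngndg(x, beta),
      grad = function(x, beta = 1) ngndg_grad(x, beta),
      hess = function(x, beta = 1) ngndg_hess(x, beta)
    ),
    relu = list(
      name = "relu",
      f    = function(x, beta = 1) pmax(x, 0),
      grad = function(x, beta = 1) { o <- rep_like(0, x); o[x >= 0] <- 1; o }, # right-derivative 1 at 0
      hess = function(x, beta = 1) rep_like(0, x)
    ),
    elu = list(
      name = "elu",
      f    = function(x, beta = 1) ifelse(x >= 0, x, expm1(x)),
      grad = function(x, beta = 1) ifelse(x >= 0, rep_like(1, x), exp(x)),
      hess = function(x, beta = 1) ifelse(x >= 0, rep_like(0, x), exp(x))
    )
  )
}

check_finite <- function(x, label) {
  if (!is.numeric(x) || length(x) == 0L)
    stop(label, " must be a nonempty numeric vector or array")
  if (!all(is.finite(x)))
    stop(label, " contains non-finite values")
  invisible(x)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("beta must be a single finite number")
  invisible(beta)
}

# constant broadcast that preserves dim()
rep_like <- function(value, x) {
  out <- rep(value, length(x))
  dim(out) <- dim(x)
  out
}
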