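#' Sinh-arcsinh (SHASH) warp parameters
#'
#' Parameters of the monotone warp
#' \deqn{\phi(y) = \sinh(\delta \cdot \mathrm{arcsinh}((y - c)/d) - \epsilon)}
#' used as a likelihood warp: a Gaussian model on \eqn{\phi(y)} induces a
#' skewed, heavy- or light-tailed distribution on \eqn{y}. \code{epsilon}
#' controls skew (positive values skew the induced density of y to the
#' right), \code{delta} controls tailweight (\code{delta < 1} heavy,
#' \code{delta > 1} light), and \code{c}, \code{d} are an affine
#' location/scale applied before the map. \code{epsilon = 0},
#' \code{delta = 1}, \code{c = 0}, \code{d = 1} give the identity warp.
#'
#' @param epsilon skew parameter (real, unitless).
#' @param delta tailweight parameter (must be > 0).
#' @param c location applied before the map (measurement units).
#' @param d scale applied before the map (measurement units, > 0).
#' @return An object of class \code{warp_params}.
#' @export
#' @examples
#' wp <- warp_params(epsilon = 0, delta = 2)
#' warp(1, wp) # 2 * sqrt(2)
warp_params <- function(epsilon = 0, delta = 1, c = 0, d = 1) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("warp_params: 'delta' must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("warp_params: 'd' must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon))
    stop("warp_params: 'epsilon' must be a finite scalar", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c))
    stop("warp_params: 'c' must be a finite scalar", call. = FALSE)
  structure(list(epsilon = epsilon, delta = delta, c = c, d = d),
            class = "warp_params")
}

#' @export
print.warp_params <- function(x, ...) {
  cat(sprintf("SHASH warp: epsilon = %.4g, delta = %.4g, c = %.4g, d = %.4g\n",
              x$epsilon, x$delta, x$c, x$d))
  invisible(x)
}

#' Apply the sinh-arcsinh warp
#'
#' Computes \eqn{\phi(y) = \sinh(\delta\,\mathrm{arcsinh}((y-c)/d) - \epsilon)}.
#' Strictly increasing in \code{y} for any valid parameters.
#'
#' @param y numeric vector (measurement units).
#' @param params a [warp_params] object.
#' @return numeric vector of warped values (unitless).
#' @seealso [warp_inverse()], [warp_log_deriv()]
#' @export
warp <- function(y, params) {
  stopifnot(inherits(params, "warp_params"))
  sinh(params$delta * asinh((y - params$c) / params$d) - params$epsilon)
}

#' Invert the sinh-arcsinh warp
#'
#' Returns \eqn{y} such that \code{warp(y, params) == z}:
#' \eqn{y = c + d\,\sinh((\mathrm{arcsinh}(z) + \epsilon)/\delta)}.
#'
#' @param z numeric vector in warped space.
#' @inheritParams warp
#' @return numeric vector in measurement units.
#' @export
warp_inverse <- function(z, params) {
  stopifnot(inherits(params, "warp_params"))
  params$c + params$d * sinh((asinh(z) + params$epsilon) / params$delta)
}

#' Log-derivative of the sinh-arcsinh warp
#'
#' \eqn{\log \phi'(y)}, the Jacobian term of the warped-Gaussian
#' log-likelihood:
#' \eqn{\log\phi'(y) = \log\delta - \log d + \log\cosh(\delta\,\mathrm{arcsinh}(u) - \epsilon)
#'  - \tfrac12\log(1 + u^2)} with \eqn{u = (y - c)/d}.
#'
#' @inheritParams warp
#' @return numeric vector of \eqn{\log \phi'(y)}.
#' @export
warp_log_deriv <- function(y, params) {
  stopifnot(inherits(params, "warp_params"))
  u <- (y - params$c) / params$d
  t <- params$delta * asinh(u) - params$epsilon
  # log cosh with overflow guard: log cosh(t) = |t| + log1p(exp(-2|t|)) - log 2
  logcosh <- abs(t) + log1p(exp(-2 * abs(t))) - log(2)
  log(params$delta) - log(params$d) + logcosh - 0.5 * log1p(u^2)
}

#' Sample sinh-arcsinh distributed residuals
#'
#' Draws \code{n} values of \eqn{S^{-1}(\eta)} with \eqn{\eta \sim N(0,1)},
#' i.e. residuals whose warp under \code{params} is standard normal. Used by
#' the cohort simulator so that the normative warp family is correctly
#' specified by construction. With \code{epsilon = 0, delta = 1} this is a
#' standard normal draw.
#'
#' @param n number of draws.
#' @inheritParams warp
#' @return numeric vector of length \code{n}.
#' @export
rshash <- function(n, params = warp_params()) {
  warp_inverse(stats::rnorm(n), params)
}
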