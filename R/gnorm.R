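#' The generalized normal (exponential power) density
#'
#' Density of the generalized normal distribution parameterized by its mean
#' `mu`, its standard deviation `sigma` and a shape exponent `beta` that
#' controls tail heaviness: `beta = 2` is the normal distribution, `beta < 2`
#' gives heavier tails, `beta -> Inf` approaches a uniform on
#' `mu +/- sqrt(3) sigma`.  The internal scale `alpha` is derived from
#' `sigma` so that the variance equals `sigma^2`:
#' `alpha = sigma * sqrt(gamma(1/beta) / gamma(3/beta))`.
#'
#' @param x vector of quantiles (feature units).
#' @param mu location (mean), feature units.
#' @param sigma standard deviation, `> 0`.
#' @param beta shape exponent, `> 0`.
#' @param log logical; return the log density?
#' @return numeric vector of densities.
#' @examples
#' dgnorm(0)                      # 1/sqrt(2*pi), the standard normal mode
#' dgnorm(1, beta = 0.5)          # heavy-tailed member
#' integrate(dgnorm, -50, 50, beta = 1.5)
#' @export
dgnorm <- function(x, mu = 0, sigma = 1, beta = 2, log = FALSE) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (any(beta <= 0)) stop("'beta' must be positive")
  alpha <- gnorm_alpha(sigma, beta)
  ld <- base::log(beta) - base::log(2 * alpha) - lgamma(1 / beta) -
    abs((x - mu) / alpha)^beta
  if (log) ld else exp(ld)
}

#' Scale parameter of the generalized normal for a given standard deviation
#'
#' @param sigma standard deviation, `> 0`.
#' @param beta shape exponent, `> 0`.
#' @return the scale `alpha` such that the distribution's variance is `sigma^2`.
#' @export
gnorm_alpha <- function(sigma, beta) {
  sigma * exp(0.5 * (lgamma(1 / beta) - lgamma(3 / beta)))
}

#' Generalized-normal shape descriptor
#'
#' Bundles the shared class width `sigma` and shape exponent `beta` used by
#' every class of a [mixture_state()], together with the derived scale
#' `alpha`.
#'
#' @param sigma standard deviation of each class (feature units, `> 0`).
#' @param beta shape exponent (dimensionless, `> 0`); `2` is Gaussian.
#' @return an object of class `"gn_shape"` with fields `sigma`, `beta`,
#'   `alpha`.
#' @export
gn_shape <- function(sigma = 1, beta = 2) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (sigma <= 0) stop("'sigma' must be positive")
  if (beta <= 0) stop("'beta' must be positive")
  structure(list(sigma = sigma, beta = beta,
                 alpha = gnorm_alpha(sigma, beta)),
            class = "gn_shape")
}

#' @export
#' @method print gn_shape
print.gn_shape <- function(x, ...) {
  cat(sprintf("generalized normal shape: sigma = %g, beta = %g (alpha = %g)\n",
              x$sigma, x$beta, x$alpha))
  invisible(x)
}
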