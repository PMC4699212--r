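#' Mixture belief state
#'
#' The model's belief about the auditory scene: one class per candidate
#' stream, each class a generalized normal with centroid `mu[k]`, shared
#' width/shape, and mixing probability `pi[k]` (the accumulated evidence for
#' that stream's existence).  Mixing probabilities sum to 1.
#'
#' @param mu numeric vector of class centroids (feature units).
#' @param pi numeric vector of mixing probabilities; must be positive and
#'   sum to 1 (within 1e-9).
#' @param shape a [gn_shape()], or `sigma`/`beta` to build one.
#' @param sigma,beta used when `shape` is missing.
#' @return an object of class `"mixture_state"`.
#' @examples
#' st <- mixture_state(mu = c(0, 5), pi = c(0.95, 0.05), sigma = 1, beta = 2)
#' posterior_probs(st, 3)
#' @export
mixture_state <- function(mu, pi, shape = NULL, sigma = 1, beta = 2) {
  if (is.null(shape)) shape <- gn_shape(sigma, beta)
  stopifnot(inherits(shape, "gn_shape"))
  mu <- as.numeric(mu)
  pi <- as.numeric(pi)
  if (length(mu) != length(pi) || length(mu) < 1L)
    stop("'mu' and 'pi' must be non-empty vectors of equal length")
  if (any(pi <= 0)) stop("all mixing probabilities must be positive")
  if (abs(sum(pi) - 1) > 1e-9)
    stop("mixing probabilities must sum to 1 (got ", format(sum(pi)), ")")
  structure(list(mu = mu, pi = pi, shape = shape), class = "mixture_state")
}

#' @export
#' @method print mixture_state
print.mixture_state <- function(x, ...) {
  cat(sprintf("mixture state: %d class(es), sigma = %g, beta = %g\n",
              length(x$mu), x$shape$sigma, x$shape$beta))
  print(data.frame(class = seq_along(x$mu), mu = x$mu, pi = x$pi),
        row.names = FALSE)
  invisible(x)
}

#' @export
n_classes <- function(state) UseMethod("n_classes")

#' @export
n_classes.mixture_state <- function(state) length(state$mu)

#' Mixture density of an input element
#'
#' `p(x) = sum_k pi_k p(x | c = k)`, the marginal likelihood of an incoming
#' element under the current belief state.
#'
#' @param state a [mixture_state()].
#' @param x numeric vector of feature values.
#' @return numeric vector of densities.
#' @export
mixture_density <- function(state, x) {
  stopifnot(inherits(state, "mixture_state"))
  vapply(x, function(xi) {
    d <- dgnorm(xi, state$mu, state$shape$sigma, state$shape$beta)
    # left-to-right pairwise sum matches the sequential engine exactly
    Reduce(`+`, state$pi * d)
  }, numeric(1))
}

#' A-posteriori class probabilities of an input element
#'
#' `p(c = k | x) = pi_k p(x | c = k) / p(x)`.  Computed in log space; a total
#' density below `1e-300` raises a degenerate-input error rather than
#' returning NaN.
#'
#' @param state a [mixture_state()].
#' @param x a single feature value.
#' @return numeric vector summing to 1, one entry per class.
#' @export
posterior_probs <- function(state, x) {
  stopifnot(inherits(state, "mixture_state"), length(x) == 1L)
  d <- dgnorm(x, state$mu, state$shape$sigma, state$shape$beta)
  px <- Reduce(`+`, state$pi * d)
  if (!is.finite(px) || px < 1e-300) {
    lw <- base::log(state$pi) +
      dgnorm(x, state$mu, state$shape$sigma, state$shape$beta, log = TRUE)
    m <- max(lw)
    if (!is.finite(m))
      stop("degenerate input: total mixture density underflowed at x = ", x)
    stop("degenerate input: total mixture density below 1e-300 at x = ", x)
  }
  state$pi * d / px
}

#' Classify an input element
#'
#' Deterministic mode returns the class with maximal a-posteriori
#' probability (ties broken toward the lowest class index); stochastic mode
#' draws the class from the a-posteriori distribution via the inverse CDF of
#' one uniform variate.
#'
#' @param state a [mixture_state()].
#' @param x a single feature value.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return integer class index `k*`.
#' @export
classify_element <- function(state, x, mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  q <- posterior_probs(state, x)
  if (mode == "deterministic") return(which.max(q))
  u <- stats::runif(1)
  cum <- 0
  for (k in seq_along(q)) {
    cum <- cum + q[k]
    if (u <= cum) return(k)
  }
  length(q)
}

#' Centroid update of the selected class
#'
#' Shifts `mu[k_star]` towards the element by an amount proportional to the
#' a-posteriori probability of the class and the distance to the element:
#' `mu <- mu + gamma * p(c = k* | x) * (x - mu)`.  Mixing probabilities are
#' untouched.
#'
#' @param state a [mixture_state()].
#' @param k_star index of the class the element was classified to.
#' @param x the element's feature value.
#' @param gamma centroid update rate (dimensionless, `>= 0`).
#' @return the updated `mixture_state`.
#' @export
update_centroid <- function(state, k_star, x, gamma) {
  stopifnot(inherits(state, "mixture_state"),
            k_star >= 1L, k_star <= length(state$mu), gamma >= 0)
  q <- posterior_probs(state, x)
  state$mu[k_star] <- state$mu[k_star] +
    gamma * q[k_star] * (x - state$mu[k_star])
  state
}

#' Mixing-probability update
#'
#' Applies `pi_k <- pi_k * (1 + eta * (p(x | c = k) - p(x)))` to every class:
#' evidence flows towards classes whose conditional likelihood of the
#' element exceeds the mixture likelihood, at the expense of the rest.  The
#' sum of mixing probabilities is algebraically conserved.  Factors are
#' clamped at a floor of 1e-12 (with a warning and renormalization) to keep
#' every `pi_k` positive under extreme `eta` or heavy-tailed density peaks.
#'
#' @param state a [mixture_state()].
#' @param x the element's feature value.
#' @param eta mixing update rate (feature units, `>= 0`).
#' @return the updated `mixture_state`.
#' @export
update_mixing <- function(state, x, eta) {
  stopifnot(inherits(state, "mixture_state"), eta >= 0)
  d <- dgnorm(x, state$mu, state$shape$sigma, state$shape$beta)
  px <- Reduce(`+`, state$pi * d)
  f <- 1 + eta * (d - px)
  if (any(f < 1e-12)) {
    warning("mixing update factor clamped at 1e-12; pi renormalized")
    f <- pmax(f, 1e-12)
    state$pi <- state$pi * f
    state$pi <- state$pi / sum(state$pi)
  } else {
    state$pi <- state$pi * f
  }
  state$pi <- pmax(state$pi, 1e-300)
  state
}

#' Create a class around a surprising element
#'
#' Unconditional creation rule: a new class is centered at the element with
#' initial mixing probability `p_init`, existing mixing probabilities are
#' rescaled by `1 - p_init`.
#'
#' @param state a [mixture_state()].
#' @param x the element's feature value; becomes the new centroid.
#' @param p_init initial mixing probability of the new class, in (0, 1).
#' @return the enlarged `mixture_state`.
#' @export
add_class <- function(state, x, p_init) {
  stopifnot(inherits(state, "mixture_state"), p_init > 0, p_init < 1)
  state$mu <- c(state$mu, x)
  state$pi <- c(state$pi * (1 - p_init), p_init)
  state
}

#' Threshold-gated class creation
#'
#' If the mixture likelihood of the element falls below `theta`, a new class
#' is generated around it via [add_class()]; otherwise the state is returned
#' unchanged.
#'
#' @inheritParams add_class
#' @param theta likelihood threshold (density units, `>= 0`); `0` disables
#'   creation.
#' @return a `mixture_state`, possibly with one more class.
#' @export
maybe_add_class <- function(state, x, theta, p_init) {
  stopifnot(theta >= 0)
  if (theta > 0 && mixture_density(state, x) < theta)
    add_class(state, x, p_init)
  else state
}

#' One full update step for a single element
#'
#' Composition of the model's rules in order: threshold-gated class
#' creation, classification, centroid update, mixing update.  By default
#' both updates use the conditional likelihoods evaluated when the element
#' arrived (`mixing_update = "shared"`); `"recompute"` makes the mixing
#' update re-evaluate the selected class's likelihood at the already-updated
#' centroid.
#'
#' This is the plain-R reference path; [simulate.streaming_model()] runs the
#' same arithmetic in compiled code.
#'
#' @param state a [mixture_state()].
#' @param x the element's feature value.
#' @param gamma,eta,theta,p_init model rates (see [streaming_model()]).
#' @param mode classification mode.
#' @param mixing_update `"shared"` or `"recompute"`.
#' @return list with `state` (updated), `k_star`, `posterior` (pre-update),
#'   `created` (logical).
#' @export
step_element <- function(state, x, gamma, eta, theta = 0, p_init = 1e-3,
                         mode = c("deterministic", "stochastic"),
                         mixing_update = c("shared", "recompute")) {
  mode <- match.arg(mode)
  mixing_update <- match.arg(mixing_update)
  created <- FALSE
  if (theta > 0 && mixture_density(state, x) < theta) {
    state <- add_class(state, x, p_init)
    created <- TRUE
  }
  q <- posterior_probs(state, x)
  k_star <- if (mode == "deterministic") which.max(q) else
    classify_element(state, x, mode = "stochastic")
  if (mixing_update == "shared")
    d_shared <- dgnorm(x, state$mu, state$shape$sigma, state$shape$beta)
  state$mu[k_star] <- state$mu[k_star] + gamma * q[k_star] * (x - state$mu[k_star])
  if (mixing_update == "recompute") {
    state <- update_mixing(state, x, eta)
  } else {
    px <- Reduce(`+`, state$pi * d_shared)
    f <- pmax(1 + eta * (d_shared - px), 1e-12)
    state$pi <- state$pi * f
    if (any(f == 1e-12)) state$pi <- state$pi / sum(state$pi)
  }
  list(state = state, k_star = k_star, posterior = q, created = created)
}

#' Serialize / restore a mixture state as JSON
#'
#' @param state a [mixture_state()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `state_to_json`: the JSON string (invisibly if written to file);
#'   `state_from_json`: a `mixture_state`.
#' @export
state_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "mixture_state"))
  js <- jsonlite::toJSON(list(mu = state$mu, pi = state$pi,
                              sigma = state$shape$sigma,
                              beta = state$shape$beta),
                         digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname state_to_json
#' @param json a JSON string or file path produced by [state_to_json()].
#' @export
state_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  mixture_state(mu = o$mu, pi = o$pi, sigma = o$sigma, beta = o$beta)
}
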