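#' Streaming model specification
#'
#' Defines the online-classification model of auditory streaming for an
#' alternating two-tone sequence.  Tones A (feature 0) and B (feature
#' `delta`) arrive one element at a time; each is classified to a class of a
#' two-class generalized-normal mixture and the mixture is updated by
#' competing rules: the selected class's centroid moves towards the element
#' (rate `gamma`, driven by the a-posteriori probability) while mixing
#' probabilities accumulate evidence for the class whose conditional
#' likelihood best matches the element (rate `eta`).  Classifying B to
#' class 1 (A's class) is the integration percept; to class 2, segregation.
#'
#' In `"deterministic"` mode each element goes to the a-posteriori argmax
#' and the percept tracks the most recent B classification, producing
#' periodic switching.  In `"stochastic"` mode classes are drawn from the
#' a-posteriori distribution and the percept flips only after `K` B-elements
#' have been classified opposite to the current percept within the current
#' phase (the K-counter rule), producing variable phase durations.
#'
#' @param gamma centroid update rate (dimensionless, `>= 0`).
#' @param eta mixing-probability update rate (feature units, `>= 0`).
#' @param sigma shared class standard deviation (feature units, `> 0`).
#' @param beta generalized-normal shape exponent (`> 0`; 2 = Gaussian).
#' @param delta feature separation between A and B (`>= 0`).
#' @param pattern `"ABA-"` (triplet plus silence; silence contributes no
#'   element) or `"ABAB"`.
#' @param mode `"deterministic"` or `"stochastic"` classification.
#' @param K switch count of the K-counter rule (stochastic mode, `>= 1`).
#' @param theta new-class likelihood threshold (density units, `>= 0`);
#'   the default 0 disables class creation — simulations start with both
#'   classes present.
#' @param p_init initial mixing probability of a newly created class.
#' @param pi2_init initial mixing probability of class 2 (the B-centered
#'   class) at simulation start.
#' @param mixing_update `"shared"` (default): both update rules use the
#'   conditional likelihoods evaluated when the element arrived;
#'   `"recompute"`: the mixing update re-evaluates the selected class's
#'   likelihood at its just-updated centroid.
#' @param update_class stochastic mode only.  `"drawn"` (default): the
#'   drawn class is the element's classification and feeds the parameter
#'   updates as well as the K-counter.  `"percept"`: the updates classify
#'   each element according to the current perceptual interpretation (B to
#'   the percept's class, A to class 1) while the posterior draws feed only
#'   the K-counter; this couples the mixture dynamics to the percept and
#'   strengthens the memory carried across switches.
#' @param counter `"cumulative"` (default): the K-counter accumulates
#'   opposite-percept B classifications within the phase and resets only at
#'   switches; `"consecutive"`: any percept-consistent B resets it.
#' @return an object of class `"streaming_model"`.
#' @seealso [simulate.streaming_model()] to run it.
#' @examples
#' m <- streaming_model(gamma = 0.1, eta = 0.5, delta = 5, beta = 1.5)
#' m
#' coef(m)
#' @export
streaming_model <- function(gamma = 0.1, eta = 0.5, sigma = 1, beta = 2,
                            delta = 1, pattern = c("ABA-", "ABAB"),
                            mode = c("deterministic", "stochastic"),
                            K = 6, theta = 0, p_init = 1e-3, pi2_init = 1e-4,
                            mixing_update = c("shared", "recompute"),
                            counter = c("cumulative", "consecutive"),
                            update_class = c("drawn", "percept")) {
  pattern <- match.arg(pattern)
  mode <- match.arg(mode)
  mixing_update <- match.arg(mixing_update)
  counter <- match.arg(counter)
  update_class <- match.arg(update_class)
  stopifnot(gamma >= 0, eta >= 0, theta >= 0, delta >= 0,
            p_init > 0, p_init < 1, pi2_init > 0, pi2_init < 1,
            K >= 1, K == as.integer(K))
  m <- list(gamma = gamma, eta = eta, sigma = sigma, beta = beta,
            delta = delta, pattern = pattern, mode = mode, K = as.integer(K),
            theta = theta, p_init = p_init, pi2_init = pi2_init,
            mixing_update = mixing_update, counter = counter,
            update_class = update_class,
            shape = gn_shape(sigma, beta))
  class(m) <- "streaming_model"
  m
}

#' @export
#' @method print streaming_model
print.streaming_model <- function(x, ...) {
  cat("Streaming model (online generalized-normal mixture classification)\n")
  cat(sprintf("  stimulus: %s, delta = %g (delta/sigma = %g)\n",
              x$pattern, x$delta, delta_tilde(x)))
  cat(sprintf("  classes:  sigma = %g, beta = %g; initial pi2 = %g\n",
              x$sigma, x$beta, x$pi2_init))
  cat(sprintf("  dynamics: gamma = %g, eta = %g (eta/sigma = %g), theta = %g\n",
              x$gamma, x$eta, eta_tilde(x), x$theta))
  if (x$mode == "stochastic")
    cat(sprintf("  mode:     stochastic, K = %d (%s counter)\n", x$K, x$counter))
  else
    cat("  mode:     deterministic (argmax classification)\n")
  invisible(x)
}

#' @export
#' @method coef streaming_model
coef.streaming_model <- function(object, ...) {
  c(gamma = object$gamma, eta = object$eta, sigma = object$sigma,
    beta = object$beta, delta = object$delta, K = object$K,
    theta = object$theta, p_init = object$p_init, pi2_init = object$pi2_init)
}

#' Normalized stimulus separation and mixing rate
#'
#' `delta_tilde = delta / sigma` and `eta_tilde = eta / sigma`.  All update
#' equations depend on `(delta, sigma, eta)` only through these two ratios,
#' so simulations with `(delta, sigma, eta)` and `(delta/s, sigma/s, eta/s)`
#' produce identical classification sequences.
#'
#' @param model a [streaming_model()].
#' @return a single number.
#' @export
delta_tilde <- function(model) model$delta / model$sigma

#' @rdname delta_tilde
#' @export
eta_tilde <- function(model) model$eta / model$sigma

#' Initial two-class mixture for an alternating sequence
#'
#' Two classes centered at the A and B features (0 and `delta`), with the
#' B-class given a small initial mixing probability `pi2_init` so the
#' simulation starts in integration.
#'
#' @param delta feature separation.
#' @param pi2_init initial mixing probability of class 2, in (0, 1).
#' @param shape a [gn_shape()], or `sigma`/`beta`.
#' @param sigma,beta used when `shape` is missing.
#' @return a [mixture_state()] with two classes.
#' @export
init_mixture <- function(delta, pi2_init = 1e-4, shape = NULL,
                         sigma = 1, beta = 2) {
  stopifnot(pi2_init > 0, pi2_init < 1)
  mixture_state(mu = c(0, delta), pi = c(1 - pi2_init, pi2_init),
                shape = shape, sigma = sigma, beta = beta)
}

#' Alternating two-tone stimulus sequence
#'
#' `"ABA-"` emits elements A, B, A per triplet (the silent gap contributes
#' no element); `"ABAB"` emits alternating A, B pairs.  A sits at feature 0
#' and B at feature `delta`.
#'
#' @param pattern `"ABA-"` or `"ABAB"`.
#' @param delta feature separation (`>= 0`).
#' @param n_triplets number of pattern repetitions (`>= 1`).
#' @return a data frame with columns `element`, `label` (`"A"`/`"B"`) and
#'   `feature`.
#' @examples
#' make_sequence("ABA-", delta = 5, n_triplets = 2)
#' @export
make_sequence <- function(pattern = c("ABA-", "ABAB"), delta, n_triplets) {
  pattern <- match.arg(pattern)
  stopifnot(delta >= 0, n_triplets >= 1)
  lab <- if (pattern == "ABA-") rep(c("A", "B", "A"), n_triplets)
         else rep(c("A", "B"), n_triplets)
  data.frame(element = seq_along(lab), label = lab,
             feature = ifelse(lab == "B", delta, 0))
}

#' Element labels of a stimulus position
#' @noRd
element_labels <- function(pattern, n) {
  i <- seq_len(n) - 1L
  if (pattern == "ABA-") ifelse(i %% 3L == 1L, "B", "A")
  else ifelse(i %% 2L == 1L, "B", "A")
}
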