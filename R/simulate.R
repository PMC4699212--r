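#' Simulate a streaming model
#'
#' Runs the online classification loop on an alternating stimulus sequence
#' and records the percept stream, switches, and (optionally) the
#' per-element mixture trajectory.  The loop itself runs in compiled code;
#' it performs exactly the arithmetic of [step_element()] applied
#' sequentially.
#'
#' The run length is set by exactly one of `n_elements`, `n_triplets` or
#' `target_phases`.  With `target_phases`, elements are presented until
#' `target_phases + 1` perceptual switches have occurred (which yields
#' `target_phases` complete, analyzable phases) or `max_elements` is
#' reached, whichever comes first.
#'
#' @param object a [streaming_model()].
#' @param nsim number of independent runs; if `> 1` a list of traces is
#'   returned.
#' @param seed optional integer passed to [set.seed()] before simulating.
#' @param n_elements run length in elements.
#' @param n_triplets run length in pattern repetitions.
#' @param target_phases stop once this many complete phases are available.
#' @param max_elements hard cap on run length (default 1e6).
#' @param record_trace keep the per-element record (classification, mixing
#'   probability, centroids, evidence)?  Turn off for large sweeps.
#' @param init optional [mixture_state()] overriding the default
#'   [init_mixture()] two-class start.
#' @param ... unused.
#' @return an object of class `"streaming_trace"`: a list with `model`,
#'   `n_elements`, `switches` (data frame of switch element indices and the
#'   percept switched to, 1 = integration, 2 = segregation), `phases` (see
#'   [extract_phases()]), `elements` (per-element data frame or `NULL`),
#'   `final_state`, `clamped`, `created`.
#' @examples
#' m <- streaming_model(gamma = 0.03, eta = 0.1, beta = 0.5, delta = 0.6,
#'                      mode = "stochastic", K = 6)
#' tr <- simulate(m, seed = 1, target_phases = 50)
#' summary(tr)
#' @export
simulate.streaming_model <- function(object, nsim = 1, seed = NULL,
                                     n_elements = NULL, n_triplets = NULL,
                                     target_phases = NULL,
                                     max_elements = 1e6,
                                     record_trace = TRUE, init = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim > 1) {
    return(lapply(seq_len(nsim), function(i)
      simulate.streaming_model(object, nsim = 1,
                               n_elements = n_elements,
                               n_triplets = n_triplets,
                               target_phases = target_phases,
                               max_elements = max_elements,
                               record_trace = record_trace, init = init)))
  }
  per <- if (object$pattern == "ABA-") 3L else 2L
  target_switches <- 0L
  if (!is.null(n_elements)) {
    n_max <- as.integer(n_elements)
  } else if (!is.null(n_triplets)) {
    n_max <- as.integer(n_triplets) * per
  } else if (!is.null(target_phases)) {
    n_max <- as.integer(max_elements)
    target_switches <- as.integer(target_phases) + 1L
  } else {
    stop("give one of 'n_elements', 'n_triplets' or 'target_phases'")
  }
  if (is.null(init))
    init <- init_mixture(object$delta, object$pi2_init, shape = object$shape)
  stopifnot(inherits(init, "mixture_state"))

  res <- engine_run(n_max = n_max,
                    pattern = if (object$pattern == "ABA-") 0L else 1L,
                    delta = object$delta,
                    mu0 = init$mu, pi0 = init$pi,
                    sigma = object$sigma, beta = object$beta,
                    gamma = object$gamma, eta = object$eta,
                    theta = object$theta, p_init = object$p_init,
                    stochastic = object$mode == "stochastic", K = object$K,
                    recompute_mixing = object$mixing_update == "recompute",
                    consecutive_counter = object$counter == "consecutive",
                    percept_updates = identical(object$update_class, "percept"),
                    target_switches = target_switches,
                    record_trace = record_trace)

  n <- res$n_elements
  switches <- data.frame(element = res$switch_element, to = res$switch_to)
  elements <- NULL
  if (record_trace) {
    elements <- data.frame(
      element = seq_len(n),
      label = element_labels(object$pattern, n),
      k_star = res$k_star,
      pi2 = res$pi2, mu1 = res$mu1, mu2 = res$mu2,
      p_c2 = res$post2,
      percept = res$percept)
  }
  out <- structure(list(
    model = object, n_elements = n, switches = switches,
    elements = elements,
    final_state = mixture_state(res$mu, res$pi, shape = object$shape),
    clamped = res$clamped, created = res$created), class = "streaming_trace")
  out$phases <- extract_phases(out)
  out
}

#' Segment a simulation trace into percept phases
#'
#' Phases tile the trace without gaps: an opening phase from element 1 to
#' the first switch, one phase per inter-switch interval, and a trailing
#' (truncated) phase after the last switch.  The opening and trailing
#' phases are flagged `boundary = TRUE`; downstream statistics exclude
#' them.  `evidence_at_start` is the a-posteriori probability `P(c = 2 | B)`
#' of the first B element of the phase (the switch-triggering element
#' itself, for non-boundary phases), or `NA` when the per-element trace was
#' not recorded.
#'
#' @param trace a `"streaming_trace"` from [simulate.streaming_model()].
#' @return data frame with columns `percept` (1 = integration,
#'   2 = segregation), `start`, `duration` (element counts), `boundary`,
#'   `evidence_at_start`.
#' @export
extract_phases <- function(trace) {
  stopifnot(inherits(trace, "streaming_trace"))
  n <- trace$n_elements
  s <- trace$switches$element
  to <- trace$switches$to
  ev <- function(start) {
    if (is.null(trace$elements)) return(NA_real_)
    lab <- trace$elements$label
    b <- which(lab == "B" & trace$elements$element >= start)[1]
    if (is.na(b)) NA_real_ else trace$elements$p_c2[b]
  }
  if (length(s) == 0L) {
    return(data.frame(percept = 1L, start = 1L, duration = n,
                      boundary = TRUE, evidence_at_start = ev(1L)))
  }
  starts <- c(1L, s)
  ends <- c(s - 1L, n)
  percept <- c(if (to[1] == 2L) 1L else 2L, to)
  m <- length(starts)
  data.frame(percept = percept, start = starts,
             duration = ends - starts + 1L,
             boundary = seq_len(m) %in% c(1L, m),
             evidence_at_start = vapply(starts, ev, numeric(1)))
}

#' Interior (analyzable) phases of a trace
#' @param trace a `"streaming_trace"`.
#' @return the non-boundary rows of `trace$phases`.
#' @export
interior_phases <- function(trace) {
  ph <- trace$phases
  ph[!ph$boundary, , drop = FALSE]
}

#' Fraction of time spent in segregation
#'
#' Share of elements under the segregation percept, measured over the
#' complete (non-boundary) phases of the trace.  `NA` (with attribute
#' `flagged`) when fewer than two complete phases exist.
#'
#' @param trace a `"streaming_trace"`.
#' @return a single number in \[0, 1\], or flagged `NA`.
#' @export
segregation_fraction <- function(trace) {
  ph <- interior_phases(trace)
  if (nrow(ph) < 2L)
    return(structure(NA_real_, flagged = "no complete switching cycle"))
  sum(ph$duration[ph$percept == 2L]) / sum(ph$duration)
}

#' Duration of the initial integration percept
#'
#' Number of elements presented before the first switch to segregation.
#' Returns 0 when the very first B element already yields segregation
#' (immediate segregation), and `Inf` (flagged) when no switch to
#' segregation occurred within the run.
#'
#' @param trace a `"streaming_trace"`.
#' @return element count (possibly 0 or flagged `Inf`).
#' @export
initial_integration_duration <- function(trace) {
  s <- trace$switches
  first_b <- if (trace$model$pattern == "ABA-") 2L else 2L
  i <- which(s$to == 2L)[1]
  if (is.na(i))
    return(structure(Inf, flagged = "no switch to segregation within horizon"))
  el <- s$element[i]
  if (el <= first_b) 0 else el - 1
}

#' @export
#' @method print streaming_trace
print.streaming_trace <- function(x, ...) {
  cat(sprintf("streaming_trace: %d elements (%s), %d switches, %d complete phases\n",
              x$n_elements, x$model$pattern, nrow(x$switches),
              sum(!x$phases$boundary)))
  invisible(x)
}

#' @export
#' @method summary streaming_trace
summary.streaming_trace <- function(object, ...) {
  ph <- interior_phases(object)
  mk <- function(p) {
    d <- ph$duration[ph$percept == p]
    c(n = length(d), mean = mean(d), sd = stats::sd(d))
  }
  out <- list(n_elements = object$n_elements,
              n_switches = nrow(object$switches),
              integration = mk(1L), segregation = mk(2L),
              segregation_fraction = segregation_fraction(object),
              clamped = object$clamped)
  class(out) <- "summary.streaming_trace"
  out
}

#' @export
#' @method print summary.streaming_trace
print.summary.streaming_trace <- function(x, ...) {
  cat(sprintf("%d elements, %d switches\n", x$n_elements, x$n_switches))
  cat(sprintf("integration: %d phases, mean duration %.1f elements (sd %.1f)\n",
              x$integration["n"], x$integration["mean"], x$integration["sd"]))
  cat(sprintf("segregation: %d phases, mean duration %.1f elements (sd %.1f)\n",
              x$segregation["n"], x$segregation["mean"], x$segregation["sd"]))
  cat(sprintf("fraction of time in segregation: %.3f\n",
              x$segregation_fraction))
  if (x$clamped > 0)
    cat(sprintf("note: mixing-update factor clamped %d times\n", x$clamped))
  invisible(x)
}

#' Plot a simulation trace
#'
#' Three stacked panels: mixing probability of class 2 (log scale),
#' centroids, and the evidence variable `P(c = 2 | B)`, with switch times
#' marked.
#'
#' @param x a `"streaming_trace"` simulated with `record_trace = TRUE`.
#' @param ... passed to [plot.default()].
#' @export
plot.streaming_trace <- function(x, ...) {
  if (is.null(x$elements))
    stop("trace was simulated with record_trace = FALSE")
  el <- x$elements
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  sw <- x$switches$element
  panel <- function(y, ylab, log = "") {
    graphics::plot(el$element, y, type = "l", xlab = "", ylab = ylab,
                   log = log, ...)
    graphics::abline(v = sw, col = "grey70", lty = 3)
  }
  panel(el$pi2, expression(pi[2]), log = "y")
  graphics::matplot(el$element, cbind(el$mu1, el$mu2), type = "l",
                    lty = 1, col = c("blue", "red"), xlab = "",
                    ylab = expression(mu))
  graphics::abline(v = sw, col = "grey70", lty = 3)
  b <- el$label == "B"
  graphics::plot(el$element[b], el$p_c2[b], type = "l",
                 xlab = "element", ylab = "P(c = 2 | B)")
  graphics::abline(v = sw, col = "grey70", lty = 3)
  graphics::abline(h = 0.5, col = "grey50", lty = 2)
  invisible(x)
}

#' Export a per-element trace as tidy CSV
#'
#' Columns: `element`, `label`, `k_star`, `pi2`, `mu1`, `mu2`,
#' `p_c2_given_B` (evidence, `NA` for A elements), `percept`.  Run metadata
#' (model parameters) is written alongside as JSON when `meta_path` is
#' given.
#'
#' @param trace a `"streaming_trace"` with a recorded per-element trace.
#' @param path CSV output path.
#' @param meta_path optional JSON metadata output path.
#' @export
write_trace <- function(trace, path, meta_path = NULL) {
  stopifnot(inherits(trace, "streaming_trace"), !is.null(trace$elements))
  el <- trace$elements
  el$p_c2_given_B <- ifelse(el$label == "B", el$p_c2, NA_real_)
  utils::write.csv(
    el[, c("element", "label", "k_star", "pi2", "mu1", "mu2",
           "p_c2_given_B", "percept")],
    path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- c(as.list(coef(trace$model)),
              list(pattern = trace$model$pattern, mode = trace$model$mode,
                   mixing_update = trace$model$mixing_update,
                   counter = trace$model$counter,
                   n_elements = trace$n_elements,
                   package_version = as.character(utils::packageVersion("streamclass")),
                   r_version = R.version.string))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), meta_path)
  }
  invisible(path)
}
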