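#' Phase durations of a single reported trial
#'
#' Converts a trial's ordered switch events (time of each report and the
#' percept switched to) into percept phases.  The interval before the first
#' report is unobserved and the phase begun by the last report is truncated
#' by the end of the trial, so the first and last phases of the event
#' sequence are excluded from analysis.  Consecutive identical percept
#' labels are merged (the later event is dropped) with a warning.
#'
#' @param times numeric vector of switch times, strictly increasing
#'   (seconds, or element counts for simulation-derived reports).
#' @param percepts integer vector of the percepts switched to
#'   (1 = integration, 2 = segregation), same length as `times`.
#' @return data frame with columns `percept`, `start`, `duration` — the
#'   analyzable (interior) phases, possibly zero rows when fewer than 3
#'   switch events remain.
#' @examples
#' trial_phases(c(10, 14, 20, 21), c(1, 2, 1, 2))   # one interior phase
#' @export
trial_phases <- function(times, percepts) {
  stopifnot(length(times) == length(percepts))
  if (length(times) == 0L)
    return(data.frame(percept = integer(), start = numeric(),
                      duration = numeric()))
  if (any(diff(times) <= 0)) stop("switch times must be strictly increasing")
  if (!all(percepts %in% c(1L, 2L)))
    stop("percept labels must be 1 (integration) or 2 (segregation)")
  dup <- c(FALSE, diff(percepts) == 0L)
  if (any(dup)) {
    warning(sum(dup), " non-alternating percept report(s) merged")
    times <- times[!dup]
    percepts <- percepts[!dup]
  }
  n <- length(times)
  if (n < 4L)
    return(data.frame(percept = integer(), start = numeric(),
                      duration = numeric()))
  # phase i runs from event i to event i+1; drop the first and last
  keep <- 2:(n - 2L)
  data.frame(percept = as.integer(percepts[keep]), start = times[keep],
             duration = times[keep + 1L] - times[keep])
}

#' Interior phase table of a report set
#'
#' Applies [trial_phases()] to every trial of a [report_data()] object and
#' stacks the results.
#'
#' @param reports a [report_data()] object.
#' @return data frame with columns `subject`, `trial`, `phase` (index within
#'   trial), `percept`, `duration`.
#' @export
report_phases <- function(reports) {
  stopifnot(inherits(reports, "report_data"))
  out <- lapply(split(reports$events, reports$events[c("subject", "trial")],
                      drop = TRUE), function(tr) {
    ph <- trial_phases(tr$time, tr$percept)
    if (nrow(ph) == 0L) return(NULL)
    data.frame(subject = tr$subject[1], trial = tr$trial[1],
               phase = seq_len(nrow(ph)), percept = ph$percept,
               duration = ph$duration)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject = integer(), trial = integer(),
                      phase = integer(), percept = integer(),
                      duration = numeric())
  rownames(out) <- NULL
  out
}

#' Normalize phase durations within trial and percept type
#'
#' Each duration is divided by the mean duration of its percept type within
#' its own trial, so every trial's points concentrate around 1 regardless
#' of the subject's switching rate.  This removes the spurious positive
#' pooled correlation that between-subject rate differences would otherwise
#' create.  Idempotent: normalizing twice equals normalizing once.
#'
#' @param phases a phase table from [report_phases()] (columns `subject`,
#'   `trial`, `percept`, `duration`).
#' @return the same table with a `norm_duration` column (replaced if
#'   present).
#' @export
normalize_durations <- function(phases) {
  key <- interaction(phases$subject, phases$trial, phases$percept,
                     drop = TRUE)
  m <- stats::ave(phases$duration, key, FUN = mean)
  phases$norm_duration <- phases$duration / m
  phases
}

transition_ends <- function(transition) {
  map <- list("I->S" = c(1L, 2L), "S->I" = c(2L, 1L),
              "I->I" = c(1L, 1L), "S->S" = c(2L, 2L))
  ends <- map[[transition]]
  if (is.null(ends)) stop("unknown transition type: ", transition)
  ends
}

#' Lagged phase-duration pairs by transition type
#'
#' Builds, within each trial, the pairs (duration of phase i, duration of
#' phase i + lag) restricted to a transition type.  With strictly
#' alternating percepts, lag 1 pairs are `I->S` or `S->I`, lag 2 pairs
#' `I->I` or `S->S`, and lag 3 pairs again cross-type — each interior pair
#' belongs to exactly one transition per lag.
#'
#' @param phases a (normalized) phase table.
#' @param lag phase separation, a positive integer (1, 2 or 3 in practice).
#' @param transition one of `"I->S"`, `"S->I"`, `"I->I"`, `"S->S"`.
#' @param value column to pair, `"norm_duration"` (default) or
#'   `"duration"`.
#' @return data frame with columns `subject`, `trial`, `x`, `y`.
#' @export
lag_pairs <- function(phases, lag, transition, value = "norm_duration") {
  ends <- transition_ends(transition)
  if (!value %in% names(phases))
    stop("column '", value, "' not found; run normalize_durations() first")
  res <- lapply(split(phases, phases[c("subject", "trial")], drop = TRUE),
                function(tr) {
    tr <- tr[order(tr$phase), ]
    n <- nrow(tr)
    if (n <= lag) return(NULL)
    i <- seq_len(n - lag)
    sel <- tr$percept[i] == ends[1] & tr$percept[i + lag] == ends[2]
    if (!any(sel)) return(NULL)
    data.frame(subject = tr$subject[1], trial = tr$trial[1],
               x = tr[[value]][i][sel], y = tr[[value]][i + lag][sel])
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(subject = integer(), trial = integer(),
                      x = numeric(), y = numeric())
  rownames(res) <- NULL
  res
}

#' Pooled lagged correlation of normalized phase durations
#'
#' Pools lagged duration pairs of one transition type across all trials and
#' subjects and computes the Pearson correlation with the standard
#' two-sided test (asymptotically valid here given the large number of
#' pairs).
#'
#' @inheritParams lag_pairs
#' @param normalize divide durations by the per-trial, per-type mean first?
#' @return a one-row data frame of class `"correlation_result"`: columns
#'   `transition`, `lag`, `rho`, `p`, `n`.  `p` is `NA` when `n < 3`.
#' @export
pooled_lag_correlation <- function(phases, lag, transition,
                                   normalize = TRUE) {
  if (normalize) phases <- normalize_durations(phases)
  value <- if (normalize) "norm_duration" else "duration"
  pr <- lag_pairs(phases, lag, transition, value = value)
  n <- nrow(pr)
  if (n < 3L) {
    rho <- if (n == 2L) suppressWarnings(stats::cor(pr$x, pr$y)) else NA_real_
    out <- data.frame(transition = transition, lag = lag, rho = rho,
                      p = NA_real_, n = n)
  } else {
    ct <- stats::cor.test(pr$x, pr$y)
    out <- data.frame(transition = transition, lag = lag,
                      rho = unname(ct$estimate), p = ct$p.value, n = n)
  }
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Per-trial lagged correlations
#'
#' Computes the Pearson correlation of lagged duration pairs separately for
#' each trial (no normalization needed, as each trial is its own scale).
#' Trials with fewer than `min_pairs` pairs are skipped and counted.
#'
#' @inheritParams lag_pairs
#' @param min_pairs minimum number of pairs for a trial to contribute.
#' @return data frame with columns `subject`, `trial`, `rho`, `n`; the
#'   number of skipped trials is attached as attribute `n_skipped`.
#' @export
per_trial_correlations <- function(phases, lag, transition, min_pairs = 3L) {
  pr <- lag_pairs(phases, lag, transition, value = "duration")
  skipped <- 0L
  res <- lapply(split(pr, pr[c("subject", "trial")], drop = TRUE),
                function(tr) {
    if (nrow(tr) < min_pairs || stats::sd(tr$x) == 0 || stats::sd(tr$y) == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    data.frame(subject = tr$subject[1], trial = tr$trial[1],
               rho = stats::cor(tr$x, tr$y), n = nrow(tr))
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(subject = integer(), trial = integer(),
                      rho = numeric(), n = integer())
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}

#' Random-intercept test of the mean per-trial correlation
#'
#' Fits `rho ~ 1 + (1 | subject)` by REML and tests the fixed intercept
#' against zero with Satterthwaite degrees of freedom, allowing per-trial
#' correlation coefficients to cluster within subjects.  The random effect
#' is tested by a restricted likelihood-ratio test against the
#' no-random-effect model.  When the fit is singular (estimated subject
#' variance zero) the intercept test falls back to a one-sample t-test and
#' the result is flagged.
#'
#' @param rhos data frame with columns `subject` and `rho`, e.g. from
#'   [per_trial_correlations()].
#' @return an object of class `"mixed_model_result"`: a list with `mu_hat`,
#'   `t_stat`, `df`, `p_fixed`, `subject_variance`, `p_random`,
#'   `singular`, `n_trials`, `n_subjects`.
#' @export
mixed_model_test <- function(rhos) {
  stopifnot(all(c("subject", "rho") %in% names(rhos)))
  if (length(unique(rhos$subject)) < 2L || nrow(rhos) < 2L)
    stop("need at least 2 subjects and 2 trials")
  rhos$subject <- factor(rhos$subject)
  if (stats::sd(rhos$rho) == 0) {
    # all correlations identical: zero residual variance, nothing to test
    return(structure(list(mu_hat = rhos$rho[1], t_stat = NA_real_,
                          df = NA_real_, p_fixed = NA_real_,
                          subject_variance = 0, p_random = NA_real_,
                          singular = TRUE, n_trials = nrow(rhos),
                          n_subjects = length(unique(rhos$subject))),
                     class = "mixed_model_result"))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(rho ~ 1 + (1 | subject), data = rhos,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_subj <- vc$vcov[vc$grp == "subject"]
  singular <- lme4::isSingular(fit)
  if (singular) {
    tt <- stats::t.test(rhos$rho)
    mu <- unname(tt$estimate); tstat <- unname(tt$statistic)
    df <- unname(tt$parameter); p_fixed <- tt$p.value
  } else {
    co <- stats::coef(summary(fit))
    mu <- co[1, "Estimate"]; tstat <- co[1, "t value"]
    df <- co[1, "df"]; p_fixed <- co[1, "Pr(>|t|)"]
  }
  # restricted LRT for the random intercept
  p_random <- tryCatch({
    rt <- suppressMessages(lmerTest::ranova(fit))
    rt[["Pr(>Chisq)"]][2]
  }, error = function(e) NA_real_)
  structure(list(mu_hat = mu, t_stat = tstat, df = df, p_fixed = p_fixed,
                 subject_variance = if (singular) 0 else s2_subj,
                 p_random = p_random, singular = singular,
                 n_trials = nrow(rhos),
                 n_subjects = length(unique(rhos$subject))),
            class = "mixed_model_result")
}

#' @export
#' @method print mixed_model_result
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("random-intercept test of mean correlation (%d trials, %d subjects)\n",
              x$n_trials, x$n_subjects))
  cat(sprintf("  mu = %.4f, t(%.1f) = %.2f, p = %.3g%s\n",
              x$mu_hat, x$df, x$t_stat, x$p_fixed,
              if (x$singular) "  [singular fit; one-sample t-test]" else ""))
  cat(sprintf("  subject variance = %.5f (LRT p = %.3g)\n",
              x$subject_variance, x$p_random))
  invisible(x)
}

#' Full lag-correlation table of a report set
#'
#' Pooled lag 1-3 correlations for every transition type defined at each
#' lag, mirroring the conventional grouping: lag 1 crosses percept types
#' (`I->S`, `S->I`), lag 2 stays within type (`I->I`, `S->S`), lag 3
#' crosses again.
#'
#' @param reports a [report_data()] object, or a phase table from
#'   [report_phases()].
#' @param min_switches optional exclusion: drop trials with fewer switch
#'   events than this before analysis (default 0 = keep all).
#' @return data frame of class `"correlation_result"` rows.
#' @export
lag_correlation_table <- function(reports, min_switches = 0L) {
  phases <- if (inherits(reports, "report_data")) {
    if (min_switches > 0L) reports <- filter_min_switches(reports, min_switches)
    report_phases(reports)
  } else reports
  combos <- list(c(1L, "I->S"), c(1L, "S->I"), c(2L, "I->I"), c(2L, "S->S"),
                 c(3L, "I->S"), c(3L, "S->I"))
  out <- do.call(rbind, lapply(combos, function(cm)
    pooled_lag_correlation(phases, as.integer(cm[1]), cm[2])))
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Drop trials with few switch events
#'
#' @param reports a [report_data()] object.
#' @param min_switches minimum number of switch events a trial must have.
#' @return the filtered `report_data`.
#' @export
filter_min_switches <- function(reports, min_switches) {
  stopifnot(inherits(reports, "report_data"))
  ev <- reports$events
  key <- interaction(ev$subject, ev$trial, drop = TRUE)
  cnt <- stats::ave(ev$time, key, FUN = length)
  reports$events <- ev[cnt >= min_switches, , drop = FALSE]
  reports
}
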