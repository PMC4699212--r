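#' Subject report data
#'
#' Container for perceptual switch reports: for each subject and trial, an
#' ordered sequence of switch times and the percept switched to
#' (1 = integration, 2 = segregation).  Times are strictly increasing
#' within a trial; non-alternating percepts are tolerated here and merged
#' (with a warning) when phases are extracted.
#'
#' @param events data frame with columns `subject`, `trial`, `time`,
#'   `percept`.
#' @param unit `"seconds"` (experimental or synthetic reports) or
#'   `"elements"` (simulation-derived); never mixed in one object.
#' @param source free-form origin tag (`"experimental"`, `"synthetic"`,
#'   `"simulation"`).
#' @return an object of class `"report_data"`.
#' @export
report_data <- function(events, unit = c("seconds", "elements"),
                        source = "experimental") {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(events),
            all(c("subject", "trial", "time", "percept") %in% names(events)))
  if (!all(events$percept %in% c(1L, 2L)))
    stop("percept labels must be 1 (integration) or 2 (segregation)")
  key <- interaction(events$subject, events$trial, drop = TRUE)
  bad <- tapply(events$time, key, function(t) any(diff(t) <= 0))
  if (any(unlist(bad)))
    stop("switch times must be strictly increasing within every trial")
  structure(list(events = events, unit = unit, source = source),
            class = "report_data")
}

#' @export
#' @method print report_data
print.report_data <- function(x, ...) {
  ev <- x$events
  cat(sprintf("report_data (%s, %s): %d subjects, %d trials, %d switch events\n",
              x$source, x$unit, length(unique(ev$subject)),
              nrow(unique(ev[c("subject", "trial")])), nrow(ev)))
  invisible(x)
}

#' Synthetic subject reports with tunable lag-1 correlation
#'
#' Generates alternating percept phases per trial from a log-normal chain:
#' a latent standardized Gaussian AR(1) process `z` with lag-1 coefficient
#' `r` supplies `duration = rate_j * exp(mu_type + sdlog * z)`, where
#' `mu_type` sets the mean duration of each percept type and `rate_j` is a
#' per-subject log-normal rate factor with geometric standard deviation
#' `subject_spread` (1 = homogeneous subjects).  The latent AR(1) gives a
#' tunable lag-1 association between successive phase durations with
#' geometrically vanishing higher-lag partial structure.  Switch events are
#' emitted until the trial length is exhausted; the truncated first/last
#' phases are emitted as-is since downstream analysis excludes them.
#'
#' The induced correlation between successive *durations* is smaller than
#' `r` (log-normal attenuation); compute it by Monte Carlo over bivariate
#' normal pairs when an exact reference is needed.
#'
#' @param n_subjects,n_trials design size (defaults mirror a typical
#'   ABA- experiment: 21 subjects, 6 trials).
#' @param trial_length trial duration in seconds.
#' @param mean_integration,mean_segregation mean phase durations (seconds).
#' @param subject_spread geometric SD of the per-subject rate factor
#'   (`>= 1`; 1 disables heterogeneity).
#' @param r latent lag-1 correlation, in (-1, 1).
#' @param sdlog log-scale SD of phase durations.
#' @return a [report_data()] with `source = "synthetic"`.
#' @examples
#' set.seed(1)
#' rep <- generate_reports(n_subjects = 4, n_trials = 2, r = 0.3)
#' rep
#' @export
generate_reports <- function(n_subjects = 21, n_trials = 6,
                             trial_length = 240,
                             mean_integration = 6.0,
                             mean_segregation = 8.1,
                             subject_spread = 1, r = 0, sdlog = 0.5) {
  stopifnot(trial_length > 0, mean_integration > 0, mean_segregation > 0,
            subject_spread >= 1, abs(r) < 1, sdlog > 0)
  mu_type <- c(log(mean_integration), log(mean_segregation)) - sdlog^2 / 2
  ssd <- log(subject_spread)
  out <- vector("list", n_subjects * n_trials)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    rate <- exp(stats::rnorm(1, 0, ssd))
    for (tr in seq_len(n_trials)) {
      first <- sample(1:2, 1)
      times <- numeric(0); percepts <- integer(0)
      z <- stats::rnorm(1)
      # initial (pre-first-report) phase, opposite type, not recorded
      t <- rate * exp(mu_type[3L - first] + sdlog * z)
      typ <- first
      while (t <= trial_length) {
        times <- c(times, t); percepts <- c(percepts, typ)
        z <- r * z + sqrt(1 - r^2) * stats::rnorm(1)
        t <- t + rate * exp(mu_type[typ] + sdlog * z)
        typ <- 3L - typ
      }
      idx <- idx + 1L
      if (length(times))
        out[[idx]] <- data.frame(subject = s, trial = tr, time = times,
                                 percept = percepts)
    }
  }
  report_data(do.call(rbind, out), unit = "seconds", source = "synthetic")
}

#' Write / read subject reports
#'
#' Two lossless plain-text formats: a nested JSON layout (per-trial arrays
#' `switch_times_s` and `percepts`, plus `unit`/`source` metadata) and a
#' flat CSV (`subject`, `trial`, `time_s`, `percept`).  The format is
#' chosen from the file extension.
#'
#' @param reports a [report_data()].
#' @param path output (or input) file path ending in `.json` or `.csv`.
#' @return `write_reports` returns `path` invisibly; `read_reports` a
#'   [report_data()].
#' @export
write_reports <- function(reports, path) {
  stopifnot(inherits(reports, "report_data"))
  ext <- tolower(tools::file_ext(path))
  ev <- reports$events
  if (ext == "json") {
    subj <- lapply(split(ev, ev$subject), function(se) {
      list(subject = se$subject[1],
           trials = unname(lapply(split(se, se$trial), function(tr)
             list(trial = tr$trial[1],
                  switch_times_s = tr$time,
                  percepts = tr$percept))))
    })
    obj <- list(unit = reports$unit, source = reports$source,
                subjects = unname(subj))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  } else if (ext == "csv") {
    utils::write.csv(
      data.frame(subject = ev$subject, trial = ev$trial, time_s = ev$time,
                 percept = ev$percept),
      path, row.names = FALSE)
  } else stop("unsupported report format: .", ext)
  invisible(path)
}

#' @rdname write_reports
#' @param unit,source used for CSV input (the JSON format stores its own).
#' @export
read_reports <- function(path, unit = "seconds", source = "experimental") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed report file '", path, "': ",
                           conditionMessage(e)))
    if (is.null(obj$subjects)) stop("malformed report file '", path,
                                    "': missing 'subjects'")
    rows <- list()
    for (se in obj$subjects) {
      for (tr in se$trials) {
        if (is.null(tr$switch_times_s) || is.null(tr$percepts) ||
            length(tr$switch_times_s) != length(tr$percepts))
          stop("malformed report file '", path, "': subject ", se$subject,
               " trial ", tr$trial,
               " needs matching 'switch_times_s' and 'percepts'")
        if (length(tr$switch_times_s) == 0) next
        rows[[length(rows) + 1L]] <-
          data.frame(subject = se$subject, trial = tr$trial,
                     time = as.numeric(unlist(tr$switch_times_s)),
                     percept = as.integer(unlist(tr$percepts)))
      }
    }
    ev <- do.call(rbind, rows)
    unit <- if (!is.null(obj$unit)) obj$unit else unit
    source <- if (!is.null(obj$source)) obj$source else source
  } else if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("subject", "trial", "time_s", "percept")
    if (!all(need %in% names(df)))
      stop("malformed report file '", path, "': need columns ",
           paste(need, collapse = ", "))
    ev <- data.frame(subject = df$subject, trial = df$trial,
                     time = df$time_s, percept = as.integer(df$percept))
  } else stop("unsupported report format: .", ext)
  ev <- ev[order(ev$subject, ev$trial, ev$time), ]
  rownames(ev) <- NULL
  report_data(ev, unit = unit, source = source)
}

#' Reports from simulated traces
#'
#' Packages the switch sequences of one or more simulation runs as a
#' [report_data()] (unit = elements), one trial per run, so that
#' simulation output feeds the same phase-statistics pipeline as
#' experimental reports.
#'
#' @param traces a `"streaming_trace"` or list of them.
#' @param subject subject id to assign (simulations have no subjects).
#' @return a [report_data()] with `source = "simulation"`.
#' @export
traces_as_reports <- function(traces, subject = 1L) {
  if (inherits(traces, "streaming_trace")) traces <- list(traces)
  ev <- do.call(rbind, lapply(seq_along(traces), function(i) {
    sw <- traces[[i]]$switches
    if (nrow(sw) == 0L) return(NULL)
    data.frame(subject = subject, trial = i, time = as.numeric(sw$element),
               percept = sw$to)
  }))
  report_data(ev, unit = "elements", source = "simulation")
}
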