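#' Lag correlations of a single stochastic run
#'
#' Interior-phase lag-1 (cross-type) and lag-2 (within-type) Pearson
#' correlations of one simulated trace, by transition type.
#'
#' @param trace a `"streaming_trace"`.
#' @param min_pairs minimum pairs for a defined correlation.
#' @return one-row data frame: `n_switches`, `n_phases`, `lag1_IS`,
#'   `lag1_SI`, `lag2_II`, `lag2_SS`.
#' @export
trace_lag_correlations <- function(trace, min_pairs = 3L) {
  ph <- interior_phases(trace)
  d <- ph$duration; p <- ph$percept; n <- nrow(ph)
  lagc <- function(lag, from) {
    if (n < lag + min_pairs) return(NA_real_)
    i <- seq_len(n - lag)
    sel <- p[i] == from
    if (sum(sel) < min_pairs) return(NA_real_)
    x <- d[i][sel]; y <- d[i + lag][sel]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  data.frame(n_switches = nrow(trace$switches), n_phases = n,
             lag1_IS = lagc(1L, 1L), lag1_SI = lagc(1L, 2L),
             lag2_II = lagc(2L, 1L), lag2_SS = lagc(2L, 2L))
}

#' Parameter sweep over the update rates
#'
#' Runs one stochastic simulation per (gamma, eta) grid cell with all other
#' parameters fixed, and records whether on-going switching occurred
#' (at least `min_switches` switches within the horizon) together with the
#' within-run lag-1 and lag-2 phase-duration correlations.
#'
#' Each cell gets the seed `base_seed + cell_index`, so the sweep is
#' reproducible and cells are independent.
#'
#' @param gammas,etas numeric grids of the centroid and mixing update
#'   rates (defaults: 30 linearly spaced values on \[0.001, 0.3\] each,
#'   a 900-cell sweep).
#' @param model template [streaming_model()] supplying all other
#'   parameters; its `gamma`/`eta` are overridden cell by cell.
#' @param target_phases stop a run after this many complete phases.
#' @param max_elements per-run element cap.
#' @param min_switches switching criterion.
#' @param base_seed seed offset.
#' @return data frame, one row per cell: `gamma`, `eta`, the columns of
#'   [trace_lag_correlations()], and `switching`.
#' @seealso [aggregate_sweep()] for the across-run summary.
#' @export
sweep_gamma_eta <- function(gammas = seq(0.001, 0.3, length.out = 30),
                            etas = seq(0.001, 0.3, length.out = 30),
                            model = streaming_model(
                              delta = 0.6, sigma = 1, beta = 0.5,
                              mode = "stochastic", K = 6, pi2_init = 1e-4),
                            target_phases = 500, max_elements = 1e6,
                            min_switches = 10L, base_seed = 1L) {
  stopifnot(length(gammas) >= 1, length(etas) >= 1)
  grid <- expand.grid(eta = etas, gamma = gammas)[, c("gamma", "eta")]
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- model
    m$gamma <- grid$gamma[i]
    m$eta <- grid$eta[i]
    tr <- simulate(m, seed = base_seed + i,
                   target_phases = target_phases,
                   max_elements = max_elements, record_trace = FALSE)
    res[[i]] <- cbind(grid[i, , drop = FALSE], trace_lag_correlations(tr))
  }
  out <- do.call(rbind, res)
  out$switching <- out$n_switches >= min_switches
  rownames(out) <- NULL
  out
}

#' Aggregate a gamma-eta sweep
#'
#' Across switching runs: mean, SD, range, number of positive values and
#' number of defined values for each lag-correlation column.
#'
#' @param sweep the data frame from [sweep_gamma_eta()].
#' @return data frame, one row per measure, plus attribute `n_switching`.
#' @export
aggregate_sweep <- function(sweep) {
  sw <- sweep[sweep$switching, , drop = FALSE]
  cols <- c("lag1_IS", "lag1_SI", "lag2_II", "lag2_SS")
  out <- do.call(rbind, lapply(cols, function(cl) {
    v <- sw[[cl]]
    data.frame(measure = cl, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)),
               n_positive = sum(v > 0, na.rm = TRUE),
               n_defined = sum(!is.na(v)))
  }))
  attr(out, "n_switching") <- nrow(sw)
  attr(out, "n_runs") <- nrow(sweep)
  out
}

#' Deterministic sweep over stimulus separation and class width
#'
#' For each (delta, sigma) cell, runs the deterministic model and records
#' the long-run fraction of time in segregation, the duration of the
#' initial integration percept, and whether on-going switching occurred.
#' All quantities depend on (delta, sigma) only through `delta / sigma`.
#'
#' The mixing rate is specified as `eta_tilde = eta / sigma`, held constant
#' across cells as `eta = eta_tilde * sigma`.
#'
#' @param deltas,sigmas numeric grids (feature units).
#' @param gamma centroid update rate.
#' @param eta_tilde normalized mixing update rate.
#' @param beta shape exponent.
#' @param pi2_init initial mixing probability of the B class.
#' @param n_elements deterministic run horizon per cell.
#' @param min_switches switching criterion.
#' @return data frame: `delta`, `sigma`, `delta_tilde`, `seg_fraction`,
#'   `initial_integration`, `n_switches`, `switching`.
#' @export
sweep_delta_sigma <- function(deltas = seq(1, 8, by = 1),
                              sigmas = c(1, 2, 4, 8),
                              gamma = 0.1, eta_tilde = 0.05, beta = 0.5,
                              pi2_init = 0.001, n_elements = 30000,
                              min_switches = 10L) {
  grid <- expand.grid(sigma = sigmas, delta = deltas)[, c("delta", "sigma")]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- streaming_model(gamma = gamma, eta = eta_tilde * grid$sigma[i],
                         sigma = grid$sigma[i], beta = beta,
                         delta = grid$delta[i], pattern = "ABA-",
                         mode = "deterministic", pi2_init = pi2_init)
    tr <- simulate(m, n_elements = n_elements, record_trace = FALSE)
    data.frame(delta = grid$delta[i], sigma = grid$sigma[i],
               delta_tilde = grid$delta[i] / grid$sigma[i],
               seg_fraction = as.numeric(segregation_fraction(tr)),
               initial_integration =
                 as.numeric(initial_integration_duration(tr)),
               n_switches = nrow(tr$switches))
  })
  out <- do.call(rbind, res)
  out$switching <- out$n_switches >= min_switches
  rownames(out) <- NULL
  out
}

#' Build-up curves of the segregation percept
#'
#' For each stimulus separation, runs `n_runs` stochastic simulations and
#' tracks the probability of the segregation percept as a function of
#' element index (mean across runs, with the standard error of the mean),
#' quantifying the build-up from the default initial integration percept
#' toward the steady state.
#'
#' @param deltas stimulus separations to profile.
#' @param sigma class width shared by all runs.
#' @param n_runs stochastic runs per separation.
#' @param horizon elements per run.
#' @param gamma,eta_tilde,beta,pi2_init,K model settings.
#' @param base_seed seed offset; run j of separation i uses
#'   `base_seed + 1000 * i + j`.
#' @return data frame: `delta`, `element`, `p_seg`, `sem`.
#' @export
buildup_curves <- function(deltas = c(2, 4, 6, 8), sigma = 4,
                           n_runs = 100, horizon = 600,
                           gamma = 0.1, eta_tilde = 0.05, beta = 0.5,
                           pi2_init = 0.001, K = 6, base_seed = 1L) {
  res <- lapply(seq_along(deltas), function(i) {
    m <- streaming_model(gamma = gamma, eta = eta_tilde * sigma,
                         sigma = sigma, beta = beta, delta = deltas[i],
                         pattern = "ABA-", mode = "stochastic", K = K,
                         pi2_init = pi2_init)
    seg <- matrix(0L, nrow = n_runs, ncol = horizon)
    for (j in seq_len(n_runs)) {
      tr <- simulate(m, seed = base_seed + 1000L * i + j,
                     n_elements = horizon)
      seg[j, ] <- as.integer(tr$elements$percept == 2L)
    }
    p <- colMeans(seg)
    data.frame(delta = deltas[i], element = seq_len(horizon), p_seg = p,
               sem = sqrt(p * (1 - p) / n_runs))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
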