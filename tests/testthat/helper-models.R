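# Model configurations used across tests.

# Long-run stochastic reference: heavily overlapping classes, K-counter
# switching; produces variable phase durations around 36 elements.
stochastic_reference_model <- function(K = 6, ...) {
  streaming_model(gamma = 0.03, eta = 0.1, sigma = 1, beta = 0.5,
                  delta = 0.6, pattern = "ABA-", mode = "stochastic",
                  K = K, pi2_init = 1e-4, ...)
}

# Deterministic reference: well-separated classes, argmax classification;
# settles into periodic switching after a transient.
periodic_reference_model <- function(...) {
  streaming_model(gamma = 0.1, eta = 0.5, sigma = 1, beta = 1.5,
                  delta = 5, pattern = "ABA-", mode = "deterministic",
                  pi2_init = 1e-4, ...)
}

# Random valid mixture state with n classes.
random_state <- function(n, sigma = 1, beta = 2) {
  w <- stats::runif(n, 0.05, 1)
  mixture_state(mu = stats::rnorm(n, 0, 3), pi = w / sum(w),
                sigma = sigma, beta = beta)
}

# Plain-R reference run: repeatedly applies step_element() to the ABA-/ABAB
# element stream.  Independent of the compiled engine code path.
reference_run <- function(model, init, n_elements) {
  lab <- rep(if (model$pattern == "ABA-") c("A", "B", "A") else c("A", "B"),
             length.out = n_elements)
  st <- init
  k <- integer(n_elements)
  for (i in seq_len(n_elements)) {
    x <- if (lab[i] == "B") model$delta else 0
    stp <- step_element(st, x, gamma = model$gamma, eta = model$eta,
                        theta = model$theta, p_init = model$p_init,
                        mode = model$mode,
                        mixing_update = model$mixing_update)
    st <- stp$state
    k[i] <- stp$k_star
  }
  list(state = st, k_star = k)
}
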