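test_that("compiled loop matches the step-by-step reference on a 3-class mixture", {
  set.seed(61)
  init <- mixture_state(mu = c(-0.5, 0.4, 1.1), pi = c(0.5, 0.3, 0.2),
                        sigma = 1, beta = 1.5)
  for (mode in c("deterministic", "stochastic")) {
    for (mixing in c("shared", "recompute")) {
      m <- streaming_model(gamma = 0.08, eta = 0.25, sigma = 1, beta = 1.5,
                           delta = 0.9, pattern = "ABA-", mode = mode,
                           K = 3, mixing_update = mixing)
      tr <- simulate(m, seed = 7, n_elements = 100, init = init)
      set.seed(7)
      ref <- reference_run(m, init, 100)
      expect_equal(tr$elements$k_star, ref$k_star,
                   info = paste(mode, mixing))
      expect_equal(tr$final_state$mu, ref$state$mu, tolerance = 1e-12)
      expect_equal(tr$final_state$pi, ref$state$pi, tolerance = 1e-12)
    }
  }
})

test_that("class creation in the compiled loop matches the reference rule", {
  init <- mixture_state(0, 1, sigma = 0.3, beta = 2)
  m <- streaming_model(gamma = 0.05, eta = 0.1, sigma = 0.3, beta = 2,
                       delta = 6, theta = 1e-4, p_init = 0.01)
  tr <- simulate(m, n_elements = 30, init = init)
  expect_identical(tr$created, 1L)          # one class formed at B, once
  expect_identical(length(tr$final_state$mu), 2L)
  expect_equal(tr$final_state$mu[2], 6, tolerance = 1e-9)
  ref <- reference_run(m, init, 30)
  expect_equal(tr$final_state$mu, ref$state$mu, tolerance = 1e-12)
  expect_equal(tr$final_state$pi, ref$state$pi, tolerance = 1e-12)
})

test_that("identical configuration and seed give bit-identical traces", {
  m <- stochastic_reference_model()
  a <- simulate(m, seed = 3, n_elements = 3000)
  b <- simulate(m, seed = 3, n_elements = 3000)
  expect_identical(a$elements, b$elements)
  expect_identical(a$switches, b$switches)
  c <- simulate(m, seed = 4, n_elements = 3000)
  expect_false(identical(a$switches, c$switches))
})

test_that("dynamics are invariant under joint rescaling of delta, sigma, eta", {
  for (s in c(0.25, 4)) {
    m1 <- stochastic_reference_model()
    m2 <- streaming_model(gamma = 0.03, eta = 0.1 / s, sigma = 1 / s,
                          beta = 0.5, delta = 0.6 / s, pattern = "ABA-",
                          mode = "stochastic", K = 6, pi2_init = 1e-4)
    t1 <- simulate(m1, seed = 11, n_elements = 5000)
    t2 <- simulate(m2, seed = 11, n_elements = 5000)
    expect_identical(t1$elements$k_star, t2$elements$k_star)
    expect_identical(t1$switches, t2$switches)
    expect_equal(t1$elements$p_c2, t2$elements$p_c2, tolerance = 1e-9)
  }
})

test_that("percept bookkeeping: switches, tiling, evidence bounds", {
  m <- stochastic_reference_model()
  tr <- simulate(m, seed = 2, target_phases = 60)
  el <- tr$elements
  # percept changes exactly at the recorded switch elements
  chg <- which(diff(el$percept) != 0) + 1L
  expect_identical(chg, tr$switches$element)
  # phases tile the trace
  expect_identical(sum(tr$phases$duration), tr$n_elements)
  expect_true(all(tr$phases$duration >= 1))
  # evidence is a probability
  b <- el$label == "B"
  expect_true(all(el$p_c2[b] >= 0 & el$p_c2[b] <= 1))
  # two-class run: pi1 = 1 - pi2 by construction, mu2 pinned at B when
  # no A element was ever classified to class 2
  if (!any(el$k_star[!b] == 2L)) {
    expect_equal(unique(el$mu2), m$delta)
  }
  # boundary phases are exactly the first and last
  expect_identical(which(tr$phases$boundary),
                   c(1L, nrow(tr$phases)))
})

test_that("deterministic run becomes periodic and switches near even evidence", {
  m <- periodic_reference_model()
  tr <- simulate(m, n_elements = 6000)
  ph <- interior_phases(tr)
  # discard the transient, then durations per percept are constant +- 1
  late <- ph[-seq_len(min(6L, nrow(ph) - 4L)), ]
  for (p in 1:2) {
    d <- late$duration[late$percept == p]
    expect_gte(length(d), 3)
    expect_lte(diff(range(d)), 1)
  }
  # at a switch element the evidence has just crossed 0.5: it is within
  # one B-to-B step of 0.5
  el <- tr$elements
  b_idx <- which(el$label == "B")
  p2 <- el$p_c2[b_idx]
  for (s in tr$switches$element[-1]) {
    j <- which(b_idx == s)
    step_size <- abs(p2[j] - p2[j - 1])
    expect_lt(abs(el$p_c2[s] - 0.5), step_size + 1e-12)
  }
})

test_that("zero separation never segregates", {
  m <- streaming_model(gamma = 0.1, eta = 0.5, sigma = 1, beta = 1.5,
                       delta = 0, mode = "deterministic", pi2_init = 1e-4)
  tr <- simulate(m, n_elements = 3000)
  expect_identical(nrow(tr$switches), 0L)
  expect_true(all(tr$elements$percept == 1L))
})

test_that("large normalized separation gives immediate segregation", {
  m <- streaming_model(gamma = 0.1, eta = 0.05, sigma = 1, beta = 0.5,
                       delta = 9, mode = "deterministic", pi2_init = 0.001)
  tr <- simulate(m, n_elements = 3000)
  expect_identical(initial_integration_duration(tr), 0)
})

test_that("with K = 1 the percept follows the last drawn B classification", {
  m <- stochastic_reference_model(K = 1)
  tr <- simulate(m, seed = 9, n_elements = 2000)
  el <- tr$elements
  b <- el$label == "B"
  expect_identical(el$percept[b], ifelse(el$k_star[b] == 2L, 2L, 1L))
})

test_that("saturated posteriors make the stochastic run deterministic", {
  # widely separated classes: posteriors are numerically 0/1, so posterior
  # draws equal the argmax and (with K = 1) the stochastic trace reproduces
  # the deterministic one exactly
  det <- streaming_model(gamma = 0.1, eta = 0.3, sigma = 1, beta = 2,
                         delta = 30, mode = "deterministic",
                         pi2_init = 0.3)
  sto <- streaming_model(gamma = 0.1, eta = 0.3, sigma = 1, beta = 2,
                         delta = 30, mode = "stochastic", K = 1,
                         pi2_init = 0.3)
  t1 <- simulate(det, n_elements = 500)
  t2 <- simulate(sto, seed = 1, n_elements = 500)
  expect_identical(t1$elements$k_star, t2$elements$k_star)
  expect_identical(t1$elements$percept, t2$elements$percept)
})

test_that("phase extraction handles switchless and short traces", {
  m <- streaming_model(delta = 0, mode = "deterministic")
  tr <- simulate(m, n_elements = 50)
  expect_identical(nrow(tr$phases), 1L)
  expect_true(tr$phases$boundary)
  expect_identical(nrow(interior_phases(tr)), 0L)
  expect_true(is.na(segregation_fraction(tr)))
  expect_equal(initial_integration_duration(tr), Inf, ignore_attr = TRUE)
})

test_that("trace export writes the tidy per-element table", {
  m <- stochastic_reference_model()
  tr <- simulate(m, seed = 5, n_elements = 300)
  f <- tempfile(fileext = ".csv"); j <- tempfile(fileext = ".json")
  write_trace(tr, f, meta_path = j)
  df <- read.csv(f)
  expect_identical(nrow(df), 300L)
  expect_true(all(c("element", "label", "k_star", "pi2", "mu1", "mu2",
                    "p_c2_given_B", "percept") %in% names(df)))
  expect_true(all(is.na(df$p_c2_given_B[df$label == "A"])))
  meta <- jsonlite::fromJSON(j)
  expect_equal(meta$gamma, 0.03)
  expect_equal(meta$K, 6)
})
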