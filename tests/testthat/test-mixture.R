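# The two-class scenario in which the posterior favors the dominant class
# while the conditional likelihood favors the other: classes at 0 and 5,
# unit width, pi = (0.95, 0.05), input at 3.
competing_state <- function() {
  mixture_state(mu = c(0, 5), pi = c(0.95, 0.05), sigma = 1, beta = 2)
}

test_that("mixture density is the pi-weighted sum of class densities", {
  one <- mixture_state(0, 1, sigma = 1, beta = 2)
  expect_equal(mixture_density(one, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)
  two <- mixture_state(c(-1, 1), c(0.5, 0.5), sigma = 1, beta = 2)
  expect_equal(mixture_density(two, 0), dnorm(1), tolerance = 1e-12)
  expect_equal(mixture_density(two, 0), 0.2419707, tolerance = 1e-6)
  # convex combination bound
  set.seed(11)
  st <- random_state(4)
  for (x in rnorm(20, 0, 4)) {
    expect_lte(mixture_density(st, x),
               max(dgnorm(x, st$mu, st$shape$sigma, st$shape$beta)))
  }
})

test_that("posterior normalizes, honors symmetry, and matches Bayes' rule", {
  two <- mixture_state(c(-1, 1), c(0.5, 0.5), sigma = 1, beta = 2)
  expect_equal(posterior_probs(two, 0), c(0.5, 0.5), tolerance = 1e-12)
  one <- mixture_state(0, 1, sigma = 1, beta = 2)
  expect_equal(posterior_probs(one, 2), 1, tolerance = 1e-12)
  # dominant-class prior vs likelihood advantage of the near class
  q <- posterior_probs(competing_state(), 3)
  w <- c(0.95 * dnorm(3), 0.05 * dnorm(2))
  expect_equal(q, w / sum(w), tolerance = 1e-12)
  expect_equal(q, c(0.609, 0.391), tolerance = 2e-3)
  set.seed(21)
  for (i in 1:25) {
    st <- random_state(sample(2:5, 1), beta = sample(c(0.5, 1.5, 2), 1))
    q <- posterior_probs(st, rnorm(1, 0, 4))
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_true(all(q >= 0))
  }
})

test_that("underflowing total density raises a degenerate-input error", {
  st <- mixture_state(0, 1, sigma = 1, beta = 2)
  expect_error(posterior_probs(st, 60), "degenerate")
})

test_that("classification takes the argmax or samples the posterior", {
  st <- competing_state()
  expect_identical(classify_element(st, 3), 1L)
  # certain posterior: stochastic draw is deterministic
  sure <- mixture_state(c(0, 50), c(0.5, 0.5), sigma = 1, beta = 2)
  set.seed(5)
  expect_identical(classify_element(sure, 0.1, mode = "stochastic"), 1L)
  # sampling frequency matches the posterior (binomial 3-sigma band)
  q1 <- posterior_probs(st, 3)[1]
  set.seed(99)
  n <- 1e5
  draws <- vapply(seq_len(n),
                  function(i) classify_element(st, 3, "stochastic"),
                  integer(1))
  expect_lt(abs(mean(draws == 1L) - q1), 3 * sqrt(q1 * (1 - q1) / n))
  # exact tie breaks toward the lowest index
  tie <- mixture_state(c(-1, 1), c(0.5, 0.5), sigma = 1, beta = 2)
  expect_identical(classify_element(tie, 0), 1L)
})

test_that("centroid update moves only the selected class", {
  st <- competing_state()
  expect_equal(update_centroid(st, 1, 3, gamma = 0)$mu, st$mu)
  # full step with certain posterior lands on the element
  one <- mixture_state(0, 1, sigma = 1, beta = 2)
  expect_equal(update_centroid(one, 1, 2.5, gamma = 1)$mu, 2.5)
  # partial step proportional to the posterior
  q1 <- posterior_probs(st, 3)[1]
  up <- update_centroid(st, 1, 3, gamma = 0.1)
  expect_equal(up$mu[1], 0.1 * q1 * 3, tolerance = 1e-12)
  expect_equal(up$mu[1], 0.1824, tolerance = 5e-3)
  expect_equal(up$mu[2], st$mu[2])
  expect_equal(up$pi, st$pi)
})

test_that("mixing update transfers evidence and conserves total mass", {
  # equal conditional likelihoods: no change
  two <- mixture_state(c(-1, 1), c(0.3, 0.7), sigma = 1, beta = 2)
  expect_equal(update_mixing(two, 0, eta = 0.8)$pi, two$pi,
               tolerance = 1e-12)
  # the likelihood-favored (near) class gains even with a small prior
  st <- competing_state()
  d <- c(dnorm(3), dnorm(2))
  px <- sum(st$pi * d)
  up <- update_mixing(st, 3, eta = 0.5)
  expect_equal(up$pi[2], 0.05 * (1 + 0.5 * (d[2] - px)), tolerance = 1e-12)
  expect_equal(up$pi[2], 0.051177, tolerance = 1e-6)
  expect_equal(sum(up$pi), 1, tolerance = 1e-12)
  expect_equal(up$mu, st$mu)
  # conservation over random states and inputs
  set.seed(31)
  for (i in 1:30) {
    st <- random_state(sample(2:4, 1), beta = sample(c(0.5, 1.5, 2), 1))
    up <- update_mixing(st, rnorm(1, 0, 3), eta = runif(1, 0, 0.3))
    expect_equal(sum(up$pi), 1, tolerance = 1e-9)
    expect_true(all(up$pi > 0))
  }
})

test_that("extreme mixing factors are clamped with a warning", {
  # narrow heavy-tailed peak: density height ~54, so eta * p(x|k) >> 1
  st <- mixture_state(c(0, 3), c(0.5, 0.5), sigma = 0.005, beta = 0.5)
  expect_warning(up <- update_mixing(st, 0, eta = 10), "clamped")
  expect_true(all(up$pi > 0))
  expect_equal(sum(up$pi), 1, tolerance = 1e-9)
})

test_that("class creation is gated by the likelihood threshold", {
  one <- mixture_state(0, 1, sigma = 1, beta = 2)
  # likely element: no-op
  expect_identical(n_classes(maybe_add_class(one, 0.2, theta = 1e-4,
                                             p_init = 0.001)), 1L)
  # surprising element: new class centered on it
  st2 <- maybe_add_class(one, 10, theta = 1e-4, p_init = 0.001)
  expect_identical(n_classes(st2), 2L)
  expect_equal(st2$mu, c(0, 10))
  expect_equal(st2$pi, c(0.999, 0.001), tolerance = 1e-12)
  expect_equal(sum(st2$pi), 1, tolerance = 1e-12)
  # once the new class covers the region, creation does not re-trigger
  st3 <- maybe_add_class(st2, 10, theta = 1e-4, p_init = 0.001)
  expect_identical(n_classes(st3), 2L)
  # theta = 0 disables creation entirely
  expect_identical(n_classes(maybe_add_class(one, 50, theta = 0,
                                             p_init = 0.001)), 1L)
})

test_that("zero rates make the state a fixed point of the full step", {
  set.seed(41)
  st <- random_state(3, beta = 1.5)
  cur <- st
  for (x in rnorm(50, 0, 3)) {
    cur <- step_element(cur, x, gamma = 0, eta = 0, theta = 0)$state
  }
  expect_equal(cur$mu, st$mu, tolerance = 1e-15)
  expect_equal(cur$pi, st$pi, tolerance = 1e-15)
})

test_that("states serialize to JSON and back losslessly", {
  set.seed(51)
  st <- random_state(3, sigma = 0.7, beta = 0.5)
  st2 <- state_from_json(state_to_json(st))
  expect_equal(st2$mu, st$mu, tolerance = 1e-15)
  expect_equal(st2$pi, st$pi, tolerance = 1e-15)
  expect_equal(st2$shape$beta, st$shape$beta)
})

test_that("invalid states are rejected", {
  expect_error(mixture_state(c(0, 1), c(0.5, 0.6), sigma = 1, beta = 2),
               "sum to 1")
  expect_error(mixture_state(c(0, 1), c(1, -0.1) / 0.9, sigma = 1, beta = 2),
               "positive")
  expect_error(mixture_state(c(0, 1), 1, sigma = 1, beta = 2), "equal length")
})
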