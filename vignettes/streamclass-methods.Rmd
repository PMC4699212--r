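---
title: "Online mixture classification of auditory streams: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online mixture classification of auditory streams: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamclass)
```

## The model

An alternating two-tone sequence (`ABA-` triplets with a silent gap, or
`ABAB`) is presented one element at a time; tone A sits at feature value 0
and tone B at `delta` on a one-dimensional feature axis (frequency, for
pure tones). The listener's belief about the scene is a mixture of
generalized-normal classes — one class per candidate stream — with
centroids `mu_k`, mixing probabilities `pi_k` (summing to 1), shared width
`sigma` and shape `beta`. The scale parameter is derived from `sigma` so
that every class has variance `sigma^2`; `beta = 2` is Gaussian and
`beta < 2` gives the heavier tails used in the simulations here.

Each element is classified to a class: the a-posteriori argmax in
deterministic mode, a posterior draw in stochastic mode. Two updates then
compete:

* the selected class's centroid moves toward the element, at rate `gamma`
  weighted by the class's *posterior* probability — this stabilizes the
  current interpretation (during integration, the dominant class's
  centroid drifts between A and B);
* every class's mixing probability is multiplied by
  `1 + eta * (p(x|c=k) - p(x))` — evidence flows toward classes whose
  *conditional likelihood* of the element is high, regardless of their
  current weight. The sum of mixing probabilities is conserved
  algebraically.

The difference in weighting (posterior vs likelihood) is what generates
competition: a B element is usually classified to the dominant class, yet
it strengthens the B-centered class's mixing probability. When the mixture
likelihood of an element falls below `theta` a new class is created around
it with weight `p_init`; with the default two-class initialization
(`init_mixture()`: classes at A and B, the B class starting at `pi2_init`)
class creation is not needed and `theta` defaults to 0.

Classifying B to the A class is the integration percept; to its own class,
segregation. In deterministic mode the percept simply tracks the most
recent B classification and the run settles into periodic switching after
a transient. In stochastic mode the percept is a latent state: a counter
accumulates B elements drawn against the current percept and flips it when
`K` have occurred, then resets. B draws consistent with the percept leave
the counter unchanged by default (`counter = "cumulative"`); a
`"consecutive"` variant that resets on consistent draws is available but
produces far longer phases. A bounded time window for the counting process
would be a natural refinement; it is deliberately omitted because phases
are short at the parameter settings of interest.

## Parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `gamma` | — | 0.1 | centroid update rate; larger values re-center classes faster and favor integration |
| `eta` | feature | 0.5 | mixing update rate; it multiplies a density, so `eta / sigma` is the scale-free quantity |
| `sigma` | feature | 1 | shared class width (standard deviation) |
| `beta` | — | 2 | tail shape; simulations here use 0.5–1.5 (heavier than normal) |
| `delta` | feature | — | A–B separation; `delta / sigma` is the scale-free separation |
| `K` | count | 6 | opposite classifications needed for a percept switch (stochastic) |
| `theta` | density | 0 | class-creation threshold; 0 disables creation |
| `p_init` | prob. | 1e-3 | weight of a newly created class |
| `pi2_init` | prob. | 1e-4 | initial weight of the B class; smaller values lengthen the initial integration phase |

Everything depends on `(delta, sigma, eta)` only through `delta/sigma` and
`eta/sigma`; simulations with `(delta, sigma, eta)` and
`(delta, sigma, eta)/s` produce identical classification sequences, which
the test suite asserts bit-for-bit.

## Numerical choices

* Densities are evaluated in closed form via `lgamma`; the mixture total
  is accumulated left-to-right so the compiled loop and the plain-R
  reference path (`step_element()`) agree to 1e-12, which is tested on
  3-class mixtures in both classification modes.
* A total mixture density below 1e-300 raises a degenerate-input error
  instead of returning NaN posteriors.
* The mixing factor `1 + eta * (p(x|c=k) - p(x))` can go non-positive for
  extreme `eta` against narrow heavy-tailed peaks; it is clamped at 1e-12
  (with renormalization and a warning/counter). Individual weights are
  floored at 1e-300 to avoid hard underflow to zero in extreme sweep
  cells, where the B class is effectively extinct.
* Exact posterior ties in deterministic mode go to the lowest class index
  (relevant only to perfectly symmetric starts).
* Stochastic draws invert one uniform variate against the cumulative
  posterior; R's RNG is used in both the compiled and reference paths, so
  seeded runs are bit-reproducible.

## Two genuinely open couplings

Two implementation details are underdetermined by the model's verbal
description; both are exposed as options with the following defaults.

**Likelihoods used by the mixing update** (`mixing_update`). The mixing
update could use the likelihoods evaluated when the element arrived
(`"shared"`, default) or re-evaluate the selected class at its
just-updated centroid (`"recompute"`). The difference is a second-order
effect, but across seeds the shared variant reproduces the expected mean
phase durations of the reference stochastic run slightly better
(37.2/36.2 vs 37.9/35.5 elements), so it is the default.

**What the parameter updates classify** (`update_class`). With
`"drawn"` (default) the stochastic draw *is* the classification: it feeds
the centroid/mixing updates and the K-counter alike. With `"percept"` the
updates classify each element according to the current perceptual
interpretation (B to the percept's class, A to class 1) and the draws feed
only the counter, coupling the mixture dynamics to the percept. The drawn
variant matches the reference run's diagnostics (mixing probability of the
B class fluctuating around 0.1, mean phase durations near 36 elements);
the percept variant produces a much stronger memory of a segregation
phase's length in the following integration phase (within-run lag-1
correlations reaching 0.8 in parts of the rate plane) at the cost of
asymmetric mean durations. The two variants emphasize different aspects of
the switching statistics and no single coupling captures both regimes at
once; the default follows the literal reading of the classification rule,
and the alternative is one option away for users studying the
stronger-coupling regime.

## The synthetic report generator

`generate_reports()` emulates a typical switch-report corpus (21 subjects
× 6 trials × 240 s): alternating percept phases with log-normal durations
(`sdlog = 0.5`), per-type means 6.0 s (integration) and 8.1 s
(segregation), a per-subject multiplicative rate factor with geometric SD
`subject_spread`, and a latent standardized Gaussian AR(1) chain giving a
tunable lag-1 association `r` between successive log-durations with
geometrically vanishing higher-lag partial structure. The induced
correlation between *durations* is smaller than `r` (log-normal
attenuation); tests compute it with a Monte-Carlo oracle rather than
assuming it equals `r`.

What it deliberately does not emulate: the long right tail of empirical
duration distributions (attention lapses), reaction-time lag in key
presses, any "third percept" reports, and non-stationarity across a trial.
Passing tests on this corpus therefore validate the *pipeline* (pair
bookkeeping, normalization, test calibration), not distributional realism.

Truncated first/last phases are emitted as-is because the analysis
excludes boundary phases anyway: in reports, the interval before the first
key press is unobserved and the last press's phase is cut off by trial
end, so `trial_phases()` drops the first and last inter-event phases. For
simulated traces the opening (pre-first-switch) and trailing (truncated)
phases play those roles and are flagged `boundary`.

## Analysis pipeline

Durations are normalized by the per-trial, per-type mean, which removes
the spurious positive pooled correlation that between-subject switching
rates would otherwise induce (demonstrated in the tests with a five-fold
rate spread). Lag-1 pairs are split by transition (`I->S` vs `S->I`)
because a within-subject rate difference between percept types would
otherwise bias a mixed-type correlation. Pairs are pooled unweighted
across trials and subjects; per-trial correlations require at least three
pairs. The mean per-trial correlation is tested with
`rho ~ 1 + (1 | subject)` fitted by REML, the intercept tested with
Satterthwaite degrees of freedom and the random effect by a restricted
likelihood-ratio test; singular fits fall back to a one-sample t-test and
are flagged. The test suite checks the procedure's type-I rate at the
0.01 level (about 1% over 1000 simulated null corpora) and its power
against a 0.25 mean correlation with realistic variance components.

## Problem sizes used in the checks

The reference stochastic run collects 1572 phases per percept type
(~115k elements, around a second of compute). The rate sweep covers the
full 30×30 grid with at least 500 phases per run, capped at 1e6 elements
per run (seconds of compute in the compiled loop). The separation/width
grid uses 30000-element deterministic runs, and build-up curves average
100 stochastic runs per separation over a few hundred elements. These
sizes give standard errors comfortably below the tolerances being checked
while keeping the whole suite fast.

## Known limitations

* One-dimensional features only; the update rules generalize to vector
  features, but no multidimensional front-end is provided.
* Per-class widths are fixed and shared; `sigma` is not learned.
* No explicit time axis: silence contributes no element and durations are
  element counts; mapping to seconds is left to the user's presentation
  rate.
* Class pruning is not performed: an unused class's weight decays and
  stays irrelevant, which is harmless for the stimuli considered here.
* The percept model covers exactly two interpretations; richer scenes
  (more streams) simulate fine at the mixture level, but the
  integration/segregation percept labeling is specific to two-tone
  sequences.
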