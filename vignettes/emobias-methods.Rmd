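---
title: "Methods: psychometric bias, moderation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometric bias, moderation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emobias)
```

## The observer model

Each trial presents a face from a signed morph continuum (angry negative,
neutral 0, happy positive, in percent) and collects a binary happy/angry
judgment, or nothing if the response window lapses. The probability of a
happy judgment is modelled as

$$F(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{x - \mu}{\sigma}\right),$$

where $\mu$ is the point of subjective equality (PSE) when $\gamma =
\lambda$, $\sigma > 0$ the width, and $\gamma, \lambda \in [0, 0.5)$ the
guess and lapse rates. In general the PSE solves $F(x) = 0.5$, i.e.
$\mathrm{PSE} = \mu + \sigma\,\Phi^{-1}\!\big(\tfrac{0.5-\gamma}{1-\gamma-\lambda}\big)$,
and the slope at the PSE is $F'(\mathrm{PSE})$, which reduces to
$(1-\gamma-\lambda)/(\sigma\sqrt{2\pi})$ under symmetric asymptotes. A
positive PSE is a negative perceptual bias: the face needs extra physical
happiness to be judged neutral.

**Slope units.** Slopes are reported strictly as probability per morph-%,
the derivative on the same axis as the PSE. Published slope magnitudes in
this literature sometimes imply a rescaled axis (values of 0.2–0.8 would
require widths of ~0.5–2 morph-%, far steeper than a 10-percent level
spacing can resolve); this package does not attempt to match any such
convention and documents its own.

## Fitting

Per participant, valid trials are aggregated to per-level counts $(n_x,
k_x)$ and the binomial log-likelihood
$\sum_x k_x \log F(x) + (n_x - k_x)\log(1 - F(x))$
is maximised over $(\mu, \sigma)$ (default $\gamma = \lambda = 0$; a shared
lapse in $[0, 0.05]$ can be fitted for sensitivity analysis — the simplest
stated model is the default because the constraint settings behind the
original per-participant fits are not recoverable). Numerical choices:

* $F$ is clipped to $[10^{-9}, 1 - 10^{-9}]$ inside the likelihood so
  boundary parameters stay finite.
* Initialisation is a deterministic grid: 21 $\mu$ values across the
  observed level range crossed with 25 log-spaced $\sigma$ values in
  $[0.1, 100]$, ties broken toward the smallest $\sigma$. Refinement is
  Nelder–Mead on $(\mu, \log\sigma)$, restarted once from its own optimum;
  with a fixed grid the whole fit is reproducible.
* Bounds: $\mu \in [-100, 100]$, $\sigma \in [0.05, 200]$. A fit that ends
  on the $\mu$ bound, fails the optimizer, or faces degenerate data (all
  valid responses identical — $\mu$ is then unidentified and pinned at the
  boundary) is returned with `converged = FALSE` instead of raising, so a
  cohort run completes; the pipeline drops such fits downstream and records
  them in the exclusion ledger. Goodness of fit is the binomial deviance
  against the saturated model (with $0\log 0 = 0$).

The tests hold the refined likelihood against exhaustive grid search of the
same objective, and check recovery, mirror symmetry, and shift/scale
equivariance on noise-free and simulated data.

## Quality control

Inclusion follows three trial-computable rules, with thresholds exposed as
arguments and the study-style values as defaults: at least 30 valid
(answered) trials of 64; at least 75% happy judgments at the +80 morph; at
most 25% happy judgments at the −80 morph. Boundaries are inclusive
(exactly 30, 0.75, 0.25 all pass). Extreme-level proportions use valid
trials as the denominator — the natural reading since omitted trials carry
no judgment. A participant with *no* valid trials at an extreme level gets
reason `no_extreme_trials` and is excluded: the consistency check cannot be
verified, and the conservative default seemed right for a gate whose whole
point is auditability (the threshold set is configurable for other
designs). Exclusions that are not trial-computable (experimenter-logged key
errors, technical faults, depression-score gates, comorbid conditions) are
enforced at the participant-table schema level, not inferred from trials.

## Group inference

PSE and slope are screened with sample-size-adjusted skewness (pass within
±1) and excess kurtosis (±2). Negative affect, an integer scale with floor
10 and right skew, is square-root transformed before modelling. Group
comparisons run a mean-centered Levene test (the classical form, matching
the era's default software behaviour); if it rejects at $\alpha = 0.05$ the
Welch t-test is reported, otherwise the pooled Student test. Cohen's d
always uses the pooled SD regardless of the t variant, which is the pairing
that reproduces published (t, d) couples from group summaries. All tests
are two-tailed at $\alpha = 0.05$.

## Moderation

The moderation model regresses the outcome on the social-anxiety indicator
(0 = LSA, 1 = HSA), $\sqrt{\mathrm{NA}}$ centered at its complete-case
mean, and (in step 2) their product. Rows missing NA are dropped listwise —
the convention that reproduces the degrees-of-freedom bookkeeping of a
127-participant cohort with 5 missing affect records, $F(1, 118)$.
Estimation is OLS; standard errors are heteroscedasticity-consistent, HC3
by default (the conservative small-sample flavour common in the
moderation-macro ecosystem; HC0–HC2 are available) and applied in both
steps since the source convention is unstated. The increment test is
$F_{change} = \Delta R^2 (n-4)/(1 - R^2_2)$ on $(1, n-4)$ df. Because the
"standardized beta" convention in this literature is ambiguous, two are
reported: `beta` scales each coefficient by the SD of its realized design
column (the interaction uses the realized product's SD), and
`beta_fullstd` refits with outcome and moderator z-scored and the product
rebuilt from z-scored components. Simple slopes probe the SA effect at
$\pm 1$ SD of centered $\sqrt{\mathrm{NA}}$ with variance
$V_{sa} + m^2 V_{int} + 2m\,\mathrm{Cov}$ from the robust covariance; the
tests verify this against an exact re-centering refit identity.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` states a world resembling the emulated study and holds
it fixed:

* **Design**: 64 trials over levels $\{\pm 80, \pm 40, \pm 20, \pm 10,
  0\}$, 8 repetitions each except 4 at $\pm 80$; ~7% of trials omitted
  independently of level (mean completed trials ≈ 59.5 of 64, matching the
  reported 57.8–59.8 range; no level-dependent omission mechanism is
  described anywhere, so none is modelled).
* **Groups**: 90 HSA / 37 LSA; raw PANAS-NA drawn per group as
  $N(13.81, 3.38)$ / $N(11.68, 2.02)$, rounded and clamped to $[10, 50]$
  (an integer sum score with floor 10); ~4% of participants have missing
  affect records (5 of 127 in the emulated cohort), exercising listwise
  deletion.
* **Structure**: true PSE $= b_0 + b_1\,SA + b_2 z + b_3\,SA\,z +
  \varepsilon$ with $z$ the *centered square-root* NA — the same
  parameterisation the moderation model fits, so $b_1$–$b_3$ are directly
  comparable to fitted coefficients and calibration studies are exactly
  specified. Defaults $b_0 = 3$, $b_1 = 6.5$, $b_2 = -10$, $b_3 = 15.7$,
  residual SD 11.5 morph-% give a group PSE gap near 5 morph-% (d ≈ 0.4)
  concentrated at high negative affect, mirroring the published effect
  sizes on this scale; $\sigma$ is log-normal around 12 morph-% so that
  64-trial fits have realistic precision.
* **Reproducibility**: each participant draws from an RNG substream keyed
  by (master seed, participant index); growing a cohort never changes
  earlier participants' draws. Only the mean-centering constant of $z$ can
  shift when the cohort changes, which is intrinsic to centering at the
  realized mean.

Not emulated: reaction times, identity-specific face effects, adaptation or
order effects, and the exact trial-count bookkeeping of the original data
deposit. A green test on this cohort therefore establishes that the
*pipeline* is correct and calibrated under the stated world — unbiased PSE
recovery, nominal type-I error for the F-change test, power for the
simple-slope pattern — not that any particular real dataset will show those
effects, and not that real omission or lapsing behaves independently of the
stimulus.

## Design choices that were genuinely open

* **Generator scale for the PSE equation** (raw vs transformed NA): centered
  $\sqrt{\mathrm{NA}}$, so generating coefficients live on the fitted
  model's scale and null-hypothesis cohorts are exactly null for the tests
  run on them.
* **Depression-score inclusion boundary**: the source material is
  internally inconsistent (< 17 vs ≤ 17); the schema admits scores up to
  and including 17, matching the printed score range of the emulated
  cohort.
* **Report determinism vs timestamps**: `report.json` is byte-identical for
  identical config + seed; wall-clock metadata lives only in the side
  manifest.
* **Config format**: JSON (key-compatible with the YAML-style examples in
  this problem space) to keep the dependency footprint at `jsonlite`.

## Known limitations

* With 64 trials and a 10-percent level spacing, $\sigma$ below ~2 morph-%
  is not resolvable; fits to near-step observers legitimately end flagged
  or at bounds.
* The simple-slope "pattern" power criterion sits at the null coverage of
  the −1 SD test (~95.4% per replicate); a run of 200 replicates passes a
  95% bar in expectation but not with high margin — an intrinsic property
  of the construction, not a tunable.
* HC3 is conservative at small n; at n ≈ 30 robust CIs can over-cover.
* The deviance is reported as a descriptive diagnostic; no Monte-Carlo
  goodness-of-fit test is run per participant.
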