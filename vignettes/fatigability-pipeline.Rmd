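---
title: "Performance fatigability from wrist accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance fatigability from wrist accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppfi)
```

## The problem

Performance fatigability is the decline in performance during a
standardized physical task. For older adults walking 400 m at their usual
pace, the natural performance signal is cadence (steps/min): a person who
fatigues starts near their maximal cadence and slows as the walk
progresses. The Pittsburgh Performance Fatigability Index (PPFI)
quantifies this as an area deficit,

$$\mathrm{PPFI} = 100\left(1 -
  \frac{\int_0^T \hat c(t)\,dt}{T \cdot \max_t \hat c(t)}\right)\;\%,$$

where $\hat c(t)$ is the smoothed cadence trajectory over the
accelerometer-covered walk of duration $T$. A flat trajectory scores 0%, a
steep decline scores high; the score is a ratio of areas, so it is
invariant to the overall cadence level. Participants who finish the 400 m
within 6 minutes show negligible decline by construction and are assigned
0% regardless of the computed value (the raw value is retained for
audit, and a tie at exactly 360 s counts as "within").

This package implements the full chain — raw 80-Hz wrist signal to PPFI
to population-level regression — together with a synthetic-data generator
that provides ground truth for every stage, since the motivating cohort
data (muscle energetics and accelerometry in adults aged 70+) are only
available by application.

## Signal model of the simulated walk

The generator integrates a user-supplied cadence function $c(t)$ to
walked distance ($v = c/60 \times$ step length) and stops the recording
when 400 m are covered; a cadence function too slow to ever cover 400 m
is an error, not a truncated walk. The wrist signal places gravity plus
the arm swing on the forearm axis:

$$a_x(t) = 1 + A\sin\phi(t) + \tfrac{A}{2}\sin 2\phi(t) + \epsilon(t),
  \qquad \dot\phi = 2\pi \frac{c(t)}{120},$$

with $A$ the arm-swing amplitude (default 0.25 g), Gaussian sensor noise
(default SD 0.05 g), and 0.5-s wide-band bursts at every 20-m lap turn.
The arm swings once per stride, i.e. once per two steps — hence the
divisor 120. The first harmonic at half amplitude makes the waveform
asymmetric like real arm swing while keeping the fundamental the
strongest component, so the extractor's target remains analytic.

What this emulates: the spectral structure, noise floor, turn artifacts
and stop-at-distance geometry of a corridor walk. What it does not:
gait-cycle variability, posture changes, sensor drift and orientation
wobble, or any physiological coupling between fatigue and step length.
Passing tests therefore show the estimator recovers cadence under the
stated signal model, not that it would match a validated step-detection
algorithm on arbitrary field data.

## Cadence extraction

`preprocess()` takes the vector magnitude, removes the gravity/posture
component with a 5-s rolling median, and band-passes 0.4–3.0 Hz with a
4th-order zero-phase Butterworth filter (order-2 design run forward and
backward via `signal::filtfilt`). `estimate_cadence()` slides a 6-s
window in 1-s hops (at usual cadence this holds at least five stride
cycles), Hann-tapers each window, and takes the periodogram peak in the
0.4–1.5 Hz stride band; cadence is $120 f^{*}$. The spectrum is
zero-padded eightfold and the peak refined by quadratic interpolation of
log-power, giving resolution well below the 1/6-Hz window limit (about
0.01 steps/min on a pure tone). A spectral rather than step-by-step
estimator was chosen because wrist signals around turns are noisy and the
window statistic has an analytic oracle; the 0.4–1.5 Hz search band is
also what guards against picking the step (double) frequency.

Windows whose peak is less than 10 times the median passband power are
flagged, as are the first and last 3 s (start/turn transients); flagged
points are linearly interpolated from unflagged neighbours, and more than
50% flagged windows aborts with an "unreliable cadence" error. The
threshold of 10 sits between the typical peak-to-median ratio of pure
noise (about 4–8 for the effective number of independent bins in the
passband) and that of any detectable periodic component (hundreds).
The grid is left-aligned, 1-s spaced, 0-based elapsed time.

## Smoothing and scoring

`smooth_trajectory()` is a P-spline: cubic B-splines with one interior
knot per 10 s (never fewer than 8 basis functions), a second-order
difference penalty on the coefficients, and the smoothing parameter
chosen by GCV over the log-spaced grid $10^{-4}, \dots, 10^{6}$ (41
points). The second-difference penalty leaves straight lines unpenalized,
so a noiseless linear decline is reproduced exactly even at maximal
smoothing; a constant trajectory yields a constant fit rather than an
error. Flagged cadence points are excluded from the fit; fitted values
are evaluated on the full grid and clamped at zero before integration.

`compute_ppfi()` integrates by the trapezoid rule on the 1-s grid
($O(\Delta t^2)$ error, negligible at this spacing) and takes the
maximal cadence from the *smoothed* curve: a raw-window spike would
inflate the hypothetical maximal-cadence area and bias every score
upward. The stopwatch completion time governs only the 6-minute rule;
both areas use the accelerometer-covered duration. Severity strata use
the published sex-specific cut-points (3.5% women, 5.4% men, boundary
inclusive), `none` being reserved for exactly 0%.

## The cohort generator and its calibration

`simulate_cohort()` draws three energetics exposures — maximal OXPHOS
and maximal ETS capacity (pmol O$_2$/(s·mg), respirometry scale) and
ATPmax (mM/s, MRS scale) — around the published medians with the
published standardisation SDs (18.4, 22.1, 0.15), independent of each
other and of the covariates by default (the inter-energetics correlation
is configurable but is not a calibration target). The latent outcome is

$$\mathrm{PPFI}^* = \mu + \textstyle\sum_k \beta_k(-z_k) +
  \gamma^\top(x - \mathbb E x) + \varepsilon,$$

observed as $\max(0, \mathrm{PPFI}^*)$, with the residual SD derived so
the *marginal* latent SD equals `latent_sd` whatever the effects. The
default effects are $\beta = (0.55, 0.39, 0.54)$ PPFI-% per 1 SD lower
exposure — the fully adjusted published associations — and all covariate
effects default to zero so that recovery simulations isolate the
exposure effect; both are configurable.

`calibrate_generator()` pins the latent scale to two observable targets:
the fraction of exact zeros $p_0$ and the median $m$. With $p_0 < 0.5$
the censored median equals the latent median, so $\mu = m$ and
$\sigma = m / |\Phi^{-1}(p_0)|$; the defaults $\mu = 1.4$,
$\sigma = 3.79228$ reproduce 35.6% zeros and a 1.4% median. A single
left-censored normal cannot also match the published 75th percentile
(2.9%) — matching zeros and median forces a heavier upper tail — so the
calibration deliberately targets those two quantities only. No
right-censoring at 100% is modelled (observed maxima are far below it);
simulated values are clamped to [0, 100] as a formality. Missingness is
imposed MCAR per exposure at the published rates (13.5%, 29.3%, 6.7%);
models are complete-case per exposure, so each exposure's analytic n
differs, as in the motivating study.

## Censored and ordinal regression

Continuous PPFI is right-skewed with a point mass at zero, so the linear
model is fitted as a tobit: censored rows contribute
$\log\Phi((0 - x\beta)/\sigma)$, uncensored rows the usual normal
density. `tobit_fit()` maximizes this in $(\beta, \log\sigma)$ by BFGS
with the analytic gradient from an OLS start, polishes with Newton steps
until the gradient sup-norm is below $10^{-6}$ (up to five jittered
restarts), and takes the covariance from the inverse observed
information (central differences of the analytic gradient). CIs are
normal-based $\pm 1.96\,\mathrm{se}$.

The exposure enters standardized on the analytic rows and sign-flipped,
so coefficients read "PPFI-% per 1 SD *lower* energetics" and ordinal
odds ratios above 1 mean lower energetics, greater odds of a worse
stratum. The model tiers accumulate covariates: tier 1 technician/site
(simulated as 2 sites × 2 technicians, entering as a 4-level factor),
age, sex, race (binary analytic coding); tier 2 adds height and weight;
tier 3 adds total activity count. SPPB is never a model covariate — it
is the stratification variable (≥ 10 vs < 10) and interaction modifier.
Alpha is 0.05 two-sided throughout with no multiplicity adjustment,
matching the analysis the pipeline reproduces.

The exposure's explained variance is reported as a partial
McKelvey–Zavoina $R^2$: $R^2 = \mathrm{var}(x\hat\beta) /
(\mathrm{var}(x\hat\beta) + \hat\sigma^2)$ per model, combined as
$(R^2_{full} - R^2_{red})/(1 - R^2_{red})$ and floored at 0. This
latent-scale definition is the standard choice for censored models, but
it is one of several defensible definitions, so published partial-$R^2$
values are treated as context, not as quantities this package claims to
reproduce.

`ordinal_fit()` maximizes the proportional-odds cumulative-logit
likelihood by Newton iteration with step-halving (steps that break the
threshold ordering or reduce the likelihood are halved), starting from
the empirical cumulative logits. `brant_wald()` checks proportionality
by fitting the $J-1$ binary logits of $I(Y > j)$ and testing equality of
slopes across logits with Brant's covariance construction; the statistic
is $\chi^2$ with $(J-2)p$ df. Fewer than 10 observations in an outcome
level triggers a small-sample warning. No published value exists for
this diagnostic; it is validated by simulation instead (size ≈ 0.05
under a proportional-odds truth, power > 0.8 at $n = 2000$ for a slope
gap of 1).

## Problem sizes and numerical choices

The test and acceptance runs use the study's own scale where that is the
point — cohorts of $n = 795$ with 500 replicates for recovery and
coverage, $n = 50{,}000$ for calibration checks — and desk scale
elsewhere (single walks of 300–400 s at 80 Hz; 100 random walk profiles
for the extractor's error budget; 500 null replicates for the size of
the Brant and interaction tests). Spectral windows use 6 s/1 s hop;
GCV grid $10^{-4}$–$10^{6}$; tobit convergence at gradient sup-norm
$10^{-6}$; Newton step-halving up to 40 halvings; all simulators take a
single integer seed and are bit-reproducible given it.

## Known limitations

The cadence extractor is a declared stand-in validated against the
generator's ground truth, not a re-implementation of the published
step-detection pipeline behind the original index. The generator's
exposures and covariates are mutually independent by default, so
adjusted and unadjusted effects coincide in simulation — convenient for
recovery studies, unrealistic as epidemiology. The latent-normal outcome
reproduces the zero mass and median but not the full published quantile
profile, and fatigue dynamics within a walk (the shape of $c(t)$) are an
input, not an emergent property. Finally, free-living actigraphy (total
activity count) is simulated as a plain covariate; no wear-time
modelling is attempted.

## A minimal end-to-end run

```{r example, eval = FALSE}
prof <- walk_profile(function(t) 100 - 22 * pmin(t / 450, 1),
                     sex = "female", seed = 13)
w <- simulate_walk(prof)
cadence <- estimate_cadence(preprocess(w$recording))
sm <- smooth_trajectory(cadence)
compute_ppfi(sm, w$recording$completion_time_s, sex = w$recording$sex)

cohort <- simulate_cohort(cohort_params(n = 795, seed = 20))
tidy_model_sequence(run_model_sequence(cohort, "max_oxphos"))
```

The `analysis/` scripts run this pipeline end to end and write their
tables under `results/`.
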