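---
title: "Respirometry metrics and staged inference: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respirometry metrics and staged inference: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroscope)
```

## The measurement problem

Intermittent-flow respirometry measures a fish's oxygen uptake by sealing it
in a chamber and watching dissolved O2 fall, alternating sealed
("flush-off") measurement phases with flushing phases that re-oxygenate the
water. Each sealed phase yields one mass-specific uptake rate through

$$\dot{M}_{O_2} = \frac{\Delta O_2 \,(v_R - v_F)}{m},$$

where $\Delta O_2$ is the magnitude of the linear O2 decline (mg l^-1^
s^-1^), $v_R$ the respirometer volume (l), $v_F$ the fish volume (l,
assuming 1 kg = 1 l) and $m$ the fish mass (kg). `aeroscope` standardises
rates as mg O2 kg^-1^ min^-1^ — the scale on which aerobic performance of
salmonids is usually plotted — and provides `mdot_to_hourly()` for the
per-hour convention that parts of the methods literature use instead; the
package treats the per-minute unit as canonical and leaves the choice
explicit rather than resolving it silently.

From many such cycles the package derives the classical performance
metrics:

* **RMR** (resting metabolic rate): the 0.10 quantile of all validated
  cycles (coefficient of determination above 0.90, negative slope), with a
  minimum of 60 validated cycles before an estimate is reported. The low
  quantile discards the elevated post-exercise cycles without modelling
  them.
* **MMR** (maximum metabolic rate): a sliding-window steepest-slope search
  over the first post-chase measurement — every window of at least 180 s,
  advanced in 1-s steps, fitted by OLS; the steepest window with
  $R^2 > 0.95$ defines MMR.
* **AAS / FAS**: absolute (MMR − RMR) and factorial (MMR / RMR) aerobic
  scope.
* **EPOC**: the excess of the recovery curve above RMR, integrated under a
  monotone shape-preserving cubic spline from the MMR measurement until the
  curve sustainably returns to RMR; its duration is the time of that
  return.
* **CTmax**: the temperature at loss of equilibrium under a 0.1 °C min^-1^
  ramp, `start_temp + ramp_rate × t_LOE`.
* **Somatic indices and percent compact myocardium**: organ mass over body
  mass × 100, and compact dry mass over total ventricular dry mass × 100.
* **Venous PO2**: the plateau of a sealed-chamber optode record, read as
  the mean of the final 30 s once the tail slope falls below
  0.5 Torr min^-1^.

## The synthetic cohort generator

No raw traces are distributed with the study this workflow reproduces, so
the generator is a first-class module: it emulates the experiment with
known ground truth, which makes every downstream stage testable and lets
recovery of the published group values be measured directly.

**Recovery kinetics.** Post-exhaustion uptake decays as a single
exponential, $\dot{M}_{O_2}(t) = \mathrm{RMR} + (\mathrm{MMR} -
\mathrm{RMR})e^{-kt}$ with $k = 0.05$ min^-1^ by default (a ~20-min time
constant, i.e. recovery over a few hours). This is the simplest monotone
model consistent with a steadily declining recovery curve, and its excess
integral has the closed form $(\mathrm{MMR}-\mathrm{RMR})/k$, which serves
as an analytic oracle for the spline EPOC estimator.

**Cycle-level discretisation.** Consumption is held constant within each
sealed phase at the recovery curve's value at the seal time. The assay
resolves exactly one rate per cycle, so nothing finer is observable; the
payoff is that noiseless traces round-trip exactly (fitted slope ↦
programmed consumption to float precision). The first post-chase
measurement is programmed at MMR itself — physiologically, uptake remains
at its peak for the few minutes the MMR measurement spans — which makes the
sliding-window estimator exact on noiseless traces.

**Resting variability and the quantile anchor.** Overnight cycles receive
multiplicative lognormal jitter (default cv 5%) on the resting component,
so the quantile estimator is exercised non-trivially. The jitter is centred
so that its 0.10 quantile equals 1. The rationale: the study's RMR is
*operationally defined* as the 0.10 quantile of a fish's validated cycles,
so the generator places `rmr_true` at exactly that quantile of the resting
distribution — the configured value is then the estimand of the estimator,
and recovery runs measure estimator error rather than a definitional
offset.

**Saturation floor.** The automated overnight cycles are clamped at 80% air
saturation, mirroring how such experiments adjust cycling to protect the
fish. The first MMR measurement is exempt: a ~2.5 kg fish at maximal uptake
in a 54.5-l chamber necessarily draws O2 below 80% of saturation within
4–6 min, and clamping there would corrupt the very slope MMR is read from.

**Default study conditions.** The default cell means encode the study's
group values: pooled resting rates of 2.96 (sham) and 2.92 (ligated)
mg O2 kg^-1^ min^-1^; pooled maxima of 11.94 and 10.03 (a 16% reduction,
which with the resting anchors implies a 21% reduction in absolute scope).
Females sit 0.3 (RMR) and 1.0 (MMR) units below males — the direction the
study reports; the magnitudes are the package's choice since only pooled
values are printed. Cells are anchored so that the *study's own cell
compositions* (overnight records: sham 5 F / 4 M, ligated 7 F / 7 M; chase
measurements: sham 8 F / 5 M, ligated 9 F / 10 M) reproduce the pooled
values exactly, because the printed pooled means are means over exactly
those fish. Between-fish standard deviations (0.30 for RMR, 1.2 for MMR)
are set at the scale implied by standard errors typical of such cohorts.
Thermal trials use group means of 26.9 and 25.8 °C with a between-fish sd
of 0.8 °C; blood analytes follow the published recovery trajectories, with
cortisol and glucose drawn on the log10 scale so the inference module's
transform gate is exercised by construction.

A deliberate consequence of anchoring both the resting rates and the 16%
maximum-rate reduction: because group-mean absolute scope is linear in the
group means, the implied reduction in mean factorial scope is
$1 - (10.03/2.92)/(11.94/2.96) \approx 15\%$, not the 20% the study prints
for FAS. Per-fish mean-of-ratios in the real cohort can differ from the
ratio of means; a generator constrained to the printed RMR and MMR values
cannot reproduce all three reduction percentages simultaneously, and the
package reports the honest consequence of its anchors rather than tuning
group-specific variance structure to close the gap.

**What the generator does not emulate.** No post-chase activity spikes (no
spike filtering is part of the workflow, so none is simulated), no optode
calibration drift physics beyond an optional linear term, no hydrodynamic
mixing lag (a configurable `wait_s` trim exists but defaults to 0, since
the workflow applies none), and no background (microbial) respiration — a
`blank_slope` hook exists but defaults off. Passing tests therefore show
that the estimators are correct under clean, well-mixed, spike-free
conditions; they do not certify behaviour on traces with activity bursts,
which would bias a low-quantile RMR upward less than a mean but could still
defeat it.

## Numerical and convention choices

* **Quantile convention**: linear interpolation between order statistics
  (R type 7). The "lowest 10% quantile" is read as the 0.10 quantile value,
  not the mean of the lowest decile. The choice shifts RMR by well under 1%
  at 60+ cycles and is configurable (`type` argument of
  `estimate_rmr()`).
* **$R^2$ of a zero-variance response** is defined as 0, so flat cycles
  fail the linearity gate instead of producing 0/0.
* **Sliding-window tie-break**: the minimum window length is scanned
  first; longer windows replace the incumbent only when strictly steeper;
  within a length the earliest window wins. Float-level ties (a perfectly
  linear slice) resolve to the earliest window via a relative tolerance of
  1e-12.
* **EPOC start** is the midpoint of the MMR window — MMR is the recovery
  curve's first ordinate, and the study does not specify otherwise.
* **"Returned to RMR"** means the first down-crossing of the spline through
  RMR that stays at or below RMR until the next cycle point, preventing
  noise-induced early termination. With cycle-level jitter this rule
  censors often — RMR is the 10th percentile of resting activity, which
  the mean recovery curve approaches from above — so censored EPOCs are
  reported as lower bounds with a flag rather than silently truncated.
  This is the main known limitation of the EPOC stage under realistic
  resting variability.
* **Spline**: Fritsch–Carlson monotone cubic (`stats::splinefun`,
  `method = "monoH.FC"`), integrated by trapezoid on a 1-s grid. A natural
  cubic can overshoot below RMR between points; the monotone spline cannot,
  which keeps the excess integral non-negative by construction. At 10-min
  sampling of the exponential recovery the integral is within 2% of the
  closed form, at 1-min sampling within 0.5%.
* **PvO2 plateau criterion** (tail slope below 0.5 Torr min^-1^ over the
  final 30 s) is invented: the study only states that readings plateaued at
  about 3 min, and this default reproduces that timing on simulated
  equilibration curves with a 30-s time constant. With 0.3 Torr sensor
  noise at 1 Hz the tail-slope standard error is ~0.37 Torr min^-1^, so a
  non-trivial fraction of clean records is flagged non-plateaued; the tail
  mean is returned alongside the flag so group summaries remain unbiased.

## The staged statistical workflow

Every endpoint passes an assumption gate: Shapiro–Wilk normality and (with
a grouping factor) Levene's heteroscedasticity test at α = 0.05; endpoints
failing normality are log10-transformed and retested, one decision per
metric across all observations. Metabolic endpoints then go through a
type III ANOVA (sum-to-zero contrasts — type III is contrast-dependent and
only meaningful under effects coding) with the treatment × sex interaction;
a non-significant interaction drops to an additive model tested with
type II sums of squares. Morphometric endpoints use type II directly.
Repeatedly measured endpoints (recovery uptake, venous PO2, blood
chemistry) are fitted as linear mixed models with a per-fish random
intercept; candidate fixed-effect structures — all main effects, every
subset of the two-way interactions, and the full factorial — are compared
by BIC on maximum-likelihood fits, and the winner is reported with both
Wald chi-square and Satterthwaite F tables (the two conventions in which
such models are commonly reported), plus Tukey-adjusted contrasts across
time points and a compact letter display. Endpoints with small cells
(EPOC, thermal limits) drop sex under a configurable minimum-cell-size
guard (default 5). A singular random-intercept fit falls back to a
fixed-effects model with an explicit warning.

The letter display is computed in-package by the insert-and-absorb
algorithm and property-tested against the contrast matrix (no letter shared
across a significant pair, a shared letter for every non-significant one)
and cross-checked against `multcomp::cld()`.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle rather
than against itself: brute-force window enumeration for MMR (1000 random
slices), hand-evaluated arithmetic for the uptake equation and quantile,
the closed-form exponential integral for EPOC, exact ramp inversion for
CTmax, and hand-computed sums of squares for the factorial ANOVA.
Parameter-recovery runs simulate 100 replicate cohorts per comparison at
the study's cell sizes and noise scale and require the across-seed mean to
sit within twice the group-level standard error of the anchored value.
Statistical calibration uses 500 null cohorts through the full
gate-to-ANOVA chain, requiring a rejection rate of 0.05 ± 0.02. These
problem sizes were chosen so that each recovery comparison completes in a
few minutes on a single core while keeping Monte-Carlo error an order of
magnitude below the tolerance it checks.

## Known limitations

* EPOC under realistic cycle jitter is usually censored (see above); the
  reported value is then a lower bound dominated by resting fluctuation
  area, and comparisons of EPOC between groups should use matched record
  lengths.
* The generator's sex effect sizes, between-fish spreads and blood-panel
  variances are plausible choices, not published values; conclusions about
  those specific magnitudes should not be read off the defaults.
* The mean factorial-scope reduction implied by the anchored group means is
  ~15%, not the printed 20% (see the generator section); the discrepancy is
  documented rather than absorbed into tuned variance structure.
* The plateau reader assumes monotone exponential-like equilibration;
  oscillating or drifting chamber records are flagged, not corrected.
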