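---
title: "Methods: oxygen-deficit computation and its diagnostic accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxygen-deficit computation and its diagnostic accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxydeficit)
```

## The measurement model

A bedside expired-gas monitor samples the partial pressures of O₂ and CO₂
at the mouth at 100 Hz during quiet tidal breathing, alongside a single
concurrent pulse-oximetry reading. From a usable recording the device
reports one gas-exchange measurement:

1. **Breath segmentation.** Expirations are found on the CO₂ channel.
   Inspired air carries essentially no CO₂, so an expiration opens when CO₂
   rises through 5 mmHg and closes when it falls back below 4 mmHg (1 mmHg
   of hysteresis avoids chatter at the threshold). The *end-tidal* value of
   a breath is the CO₂ maximum over the final 30% of its expiration — the
   plateau end, where mouth gas best approximates alveolar gas — with the
   end-tidal O₂ read off the same sample.
2. **Steady state.** Averaging end-tidal values only makes sense once
   breathing is stable. The rule is the absence of variation in end-tidal
   CO₂ over the preceding 45 s; we operationalize "absence of variation" as
   a max−min range of at most 2 mmHg (configurable — no numeric tolerance
   is published for the device) over the trailing 45 s, requiring at least
   5 breaths and no artifact-flagged breath in the window. The *earliest*
   qualifying window is reported, mirroring a device that fires as soon as
   steady state is reached. Stability is typically achieved in one to four
   minutes of quiet breathing.
3. **Alveolar tensions.** PAO₂ is the mean end-tidal O₂ of five consecutive
   steady-state breaths; PACO₂ likewise from end-tidal CO₂. The source
   material says "five consecutive breaths" without choosing which five;
   we average the *last* five unflagged breaths of the window — the most
   recent steady data.
4. **Calculated arterial O₂ (gPaO₂).** Rather than an arterial puncture,
   the arterial O₂ tension is *calculated* by inverting the oxyhemoglobin
   saturation curve at the observed SpO₂. The curve is the Hill equation
   with exponent n = 2.88 (Severinghaus' fit to the standard adult curve),
   solved in closed form from the logarithm of the Hill equation:
   gPaO₂ = P50 · (S/(1−S))^(1/n), S = SpO₂/100.
5. **Bohr correction of P50.** CO₂ shifts the curve: we estimate pH from
   PACO₂ (as proxy for PaCO₂, no gradient term) by Henderson–Hasselbalch
   with bicarbonate fixed at 24 mmol/L (pK 6.1, solubility 0.03), and shift
   log₁₀ P50 by −0.48 per unit pH. Applied to the pH *difference* from the
   reference PACO₂ of 40 mmHg this collapses to
   P50 = 26.86 · (PACO₂/40)^0.48 mmHg, which is exact at the reference
   point. (Applying the shift to pH − 7.40 instead would leave a 0.1%
   discrepancy at PACO₂ = 40, because Henderson–Hasselbalch with
   HCO₃⁻ = 24 gives pH 7.401, not 7.400; we chose the formulation in which
   the reference point is an identity.) The commercial device uses a
   Kelman-style correction whose exact form is not public; all constants
   here are configurable so an alternative formulation can be swapped in.
   Temperature and 2,3-DPG are held at standard conditions.
6. **Oxygen deficit.** OD = PAO₂ − gPaO₂, the noninvasive surrogate of the
   alveolar–arterial gradient. ODFlip = 100 − OD re-orients it (higher =
   better) so OD and SpO₂ can share a ROC axis; thresholds are converted
   back by OD = 100 − ODFlip.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| Hill exponent n | 2.88 | — | Severinghaus fit of the standard curve |
| P50 (standard) | 26.86 | mmHg | standard adult curve at PACO₂ 40 |
| Bohr slope | −0.48 | Δlog₁₀P50/ΔpH | classic Bohr coefficient |
| assumed HCO₃⁻ | 24 | mmol/L | normal bicarbonate; device measures no pH |
| steady tolerance | 2 | mmHg | etCO₂ range read as "no variation" |
| steady window | 45 | s | the published steady-state rule |
| breaths averaged | 5 | — | the published averaging rule |
| SpO₂ clamp | [50, 99.5] | % | inversion is singular at 100%; devices do report 100%, so we clamp with a warning rather than reject. Below 50% the input is implausible and rejected. |

## What the synthetic generators emulate

**Traces.** `synthesize_trace()` produces the waveform features the breath
engine must survive: inspiratory segments at inspired tensions, expirations
approaching an end-tidal plateau, per-breath plateau noise, slow drift, and
0.3 s ±15 mmHg high-frequency cough excursions that disrupt a plateau the
way a real cough defeats end-tidal detection. The plateau shape is an
exponential approach with time constant 20% of expiratory time — a
realistic capnogram shape without modelling lung mechanics — *normalized*
so the final expiration sample lands exactly on the planted end-tidal
value. The normalization is deliberate: it makes planted truth recoverable
to machine precision, turning pipeline tests into exact checks instead of
tolerance negotiations. `synthesize_unsteady_then_steady()` makes the
pre-settle end-tidal CO₂ targets alternate by ±6 mmHg (amplitude
configurable) for every breath *starting* before the settle time, so no
trailing 45 s window overlapping the unsettled phase can pass a 2 mmHg
tolerance, and the detector provably cannot fire before settle + 45 s.

Not emulated: lung mechanics (compliance/resistance), pulse waveforms,
within-breath cardiogenic oscillations, sensor response lags, or variable
breath timing — breath periods are exact, only plateau values vary. A green
pipeline test therefore establishes correct *algorithmic* behavior on
idealized waveforms, not robustness to every device artifact.

**Cohorts.** `simulate_cohort()` draws (ODFlip, SpO₂) from a correlated
Gaussian — defaults: OD mean 35 / SD 15 mmHg, SpO₂ mean 94 / SD 2%,
correlation +0.6 — and generates the supplemental-oxygen outcome from a
logistic model with planted coefficients at the published multivariable
scale (ODFlip −0.153 per mmHg, SpO₂ −0.315 per %, intercept 38.436). The
correlation is a convention chosen to reproduce the qualitative phenomenon
of interest (the deficit carries information beyond saturation); no joint
empirical distribution is published, so these defaults are a stated world,
not estimates. SpO₂ is truncated to [88, 97]% by joint rejection, mirroring
eligibility (enrollment required SpO₂ < 97% on room air; protocols stop
below 88%). `simulate_cohort_from_traces()` instead computes every row's OD
through the full trace pipeline and censors participants whose traces never
reach steady state — the bookkeeping that turns 45 enrollees with 3 failed
measurements into 42 analyzable rows.

## Statistical conventions

- **Logistic regression** is fit by IRLS with step-halving (deviance is
  monotone by construction), convergence at max coefficient change < 10⁻⁸
  or 100 iterations. Inference is Wald — (B/SE)² on 1 df, Exp(B) with
  exp(B ± 1.96·SE) CIs — matching the SPSS-style table layout
  (B / S.E. / Wald / df / Sig. / Exp(B)); the z statistic is also emitted
  since univariable tables are often reported with t values. Complete
  separation is reported (non-converged flag plus message), never silently
  penalized away.
- **Box–Tidwell**: each continuous predictor contributes an x·ln x
  augmentation term; linearity of the logit is accepted when every
  augmentation Wald p ≥ 0.05/k with k counting *all* terms of the augmented
  model (intercept + predictors + augmentation terms). For the
  two-predictor model k = 5, hence the p < 0.01 Bonferroni threshold.
  Predictors must be strictly positive; a documented `shift` argument
  handles rare non-positive values (the Gaussian ODFlip generator emits one
  in ~10⁵ draws).
- **ROC/AUROC**: thresholds are the unique scores; AUROC is Mann–Whitney
  concordance with half credit for ties (identically the trapezoidal
  area); the CI is DeLong's placement method — a convention, since no CI
  method is published for the reference results. The `direction` flag
  orients scores (OD: higher = positive class; SpO₂ and ODFlip: lower =
  positive class), and reflection symmetry (OD "higher" vs ODFlip "lower")
  holds exactly.
- **Youden point**: maximize sensitivity + specificity − 1; ties break
  toward higher sensitivity, then the lower threshold (the source is
  silent on ties; screening favors sensitivity).
- **Paired AUROC comparison** uses the covariance of DeLong placements on
  the same subjects.

## Numerical and degenerate-input choices

- Half-open breath intervals [start, end), times in seconds from trace
  start; an expiration still open at the end of the recording closes there.
- Artifact rule: expiratory duration outside [0.5, 10] s, or end-tidal CO₂
  deviating from the reference median by more than max(3 SD, 2 mmHg). The
  reference is the trailing up-to-8 unflagged breaths when ≥ 3 exist,
  otherwise all other breaths — so a cough in breath 2 is still caught.
  The 2 mmHg floor prevents the noiseless-trace degeneracy (SD = 0) from
  flagging everything.
- A flat (never-crossing) trace segments to an empty breath set with a
  warning; steady-state absence returns `NULL` rather than an error —
  "no steady state" is a finding, and the CLI maps it to exit code 3.
- OD may be negative on noisy input (gPaO₂ > PAO₂); it is passed through
  with a warning rather than clipped.

## Known limitations

- The Kelman-style P50 correction is a documented stand-in
  (Henderson–Hasselbalch + Bohr slope), not the device's proprietary form.
- Published patient-level discrimination (AUROCs near 0.9) is *not*
  reproduced here: the underlying cohort data are not deposited, and the
  package's cohorts are synthetic by design.
- Recovery-style simulation checks that demand ≥ 95% success of an event
  whose true probability is itself ≈ 95% (a ±2 SE band) sit at the edge of
  their own Monte-Carlo noise; with a fixed seed set such a check can land
  a few replicates under the line without indicating an estimation defect.
  The package's fits agree with `stats::glm` to 10⁻⁶.
- The trace CSV dialect is a declared convention for this package; the
  commercial device's raw export layout is not public.
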