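---
title: "Measuring PEEP-induced lung recruitment: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring PEEP-induced lung recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitquant)
```

# The problem

In ARDS, part of the lung is collapsed (nonaerated). Raising PEEP can reopen
it — *recruitment* — which enlarges the resting aerated volume and lowers
**dynamic strain** (tidal volume over resting aerated volume, a principal
determinant of ventilator-induced lung injury). But PEEP also inflates the
lung that was already open, raising **static strain**. Quantitative CT
separates the two but is impractical at the bedside; the
**recruitment-to-inflation ratio (R/I)** estimates recruitability from a
single-breath derecruitment maneuver on the ventilator. This package
implements both chains, and a phantom generator that provides ground truth
for validating them end to end, since the underlying animal data are not
publicly deposited.

# The phantom: threshold lung units

The synthetic lung is a population of independent units, each with

* a tissue mass $w_i$ (lognormal heterogeneity, renormalised so masses sum
  to `weight_total`),
* a threshold **opening pressure** $O_i \sim \mathcal N(\mu, \sigma)$
  clamped at 0 — the unit aerates during inspiration once the plateau
  pressure reaches $O_i$,
* a **closing pressure** $C_i = \max(O_i - \delta, 0)$ — the unit stays
  aerated at end-expiration iff PEEP $\ge C_i$ (hysteresis limited to
  open-at-inspiration / close-at-expiration),
* a linear gas content when open: $g_i(P) = w_i\,(r + s\,P)$ ml at
  distending pressure $P$, with resting gas $r$ (ml/g) and specific
  compliance $s$ (ml/(cmH2O·g)).

The plateau pressure at each PEEP solves the self-consistency
$P = \mathrm{PEEP} + V_T / C(P)$ with $C(P) = \sum_{O_i \le P} w_i s$
(bisection; $C(P)$ is a step function and the crossing is unique). Every
downstream "truth" — tissue recruitment (mass of units aerated at
end-expiration only at the high PEEP), gas recruitment, $\Delta$EELV,
$C_{RS}$, R/I, strains — follows analytically from this model
(`export_ground_truth()`).

This is deliberately the *simplest* model that reproduces PEEP-dependent
recruitment. It has no gas exchange, no perfusion, no gravitational
gradient, no intra-breath time constants heterogeneity; a green validation
therefore establishes the *measurement chain*, not the realism of lung
mechanics.

## Desk scale

The CT geometry is fixed at the conventional 0.35 mm² pixel × 5 mm slice,
and the default grid is 32×64×64 (131,072 voxels ≈ 229 ml) so a phantom
renders in well under a second. A real injured porcine lung (~1000 g, ~2 L
aerated at high PEEP) cannot fit that grid, so the default phantom is a
~1/20-scale lung: 50 g of tissue, VT 16 ml, compliance ~2–3 ml/cmH2O.
All acceptance-relevant quantities (R/I, strains, normalised recruitment,
correlations) are dimensionless ratios and are unaffected by the scale.
Two knock-on choices follow at this scale: the low-flow AOP breath defaults
to 0.5 L/min (preserving the flow-to-VT proportion of the bedside 5 L/min
maneuver), and the derecruitment breath keeps the tidal inspiratory time —
only its expiration is prolonged (6.7 s at the 6/min, i:e 1:2 setting) —
because a 3.3 s inspiration of 16 ml would fall below the zero-flow
detection threshold.

## Rendering and noise

Each unit occupies `round(total volume / voxel volume)` consecutive voxels,
all carrying the unit's gas fraction; voxel
$HU = \mathrm{round}(-1000\,\mathrm{gasfraction}) + \mathcal N(0,
\sigma_{HU})$, clipped to $[-1000, +100]$ (CT HU are integers; the
compartment bins stop at +100). Tissue density is 1 g/ml, so a closed unit
renders at 0 HU. Rounding unit volumes to whole voxels leaves signed
per-unit errors below half a voxel that cancel across units: noiseless
round-trip error on totals is ~0.05% (tested against 0.2%). The default
noise, sd 30 HU, is typical of a standard-kernel chest reconstruction. The
expiratory flow of the derecruitment breath is scaled so its discrete
trapezoidal integral equals $V_T + \Delta EELV$ exactly: the measurement
chain, not an ODE solver, is under test.

# Quantitative CT

Gas/tissue decomposition is the standard linear mixture (−1000 HU pure gas,
0 HU pure tissue at 1 g/ml). Choices where conventions vary:

* **HU above +100 inside the mask** are counted as nonaerated at the +100
  density (1.1 g/ml) with a warning, rather than dropped, so mask totals
  are conserved.
* **Bins are defined on integer HU** exactly as printed; non-integer HU
  (possible after resampling) are rounded to nearest before binning.
* **The gas/tissue ratio at high PEEP** used for GAS_REC is not uniquely
  defined in the literature; the default is the median of voxelwise ratios
  over the masked end-expiratory high-PEEP volume (voxels with < 1e-9 g of
  tissue excluded), with `gt_mode = "whole_lung_ratio"` as the alternative
  reading (total gas / total tissue).
* **Negative recruitment** (derecruitment) propagates with a flag, never
  clamped.

# Waveform mechanics

Pressures are cmH2O, volumes ml, flows L/s throughout. Fixed numerical
choices:

* zero-flow threshold 0.005 L/s; breath onsets need ≥ 50 ms below it first;
* occlusion plateaus are the mean airway pressure over the **last 0.5 s**
  of each ≥ 0.3 s occlusion window (event labels take precedence over
  detection);
* the stress index fits $P_{aw} = a t^b + c$ over samples whose flow is
  within 5% of the inspiratory plateau median, excluding the first 50 ms of
  circuit transients, with $t$ zeroed at the inspiratory onset (a shifted
  origin misspecifies the power law and biases $b$ by ~0.04). The fit
  profiles $b$: for fixed $b$, $(a, c)$ is a linear least-squares solve;
  $b$ is then minimised on [0.2, 3] — more robust than a raw nonlinear
  optimiser on exact-fit data;
* AOP detection fits a continuous two-segment (hinge) line to pressure vs
  delivered volume by exhaustive breakpoint search, and declares an AOP
  only if the pre/post slope ratio is ≥ 3, the breakpoint lies in the first
  20% of the delivered volume, and the breakpoint pressure exceeds the low
  PEEP. The thresholds are configurable; "inflection point" alone does not
  define an algorithm.
* the exhaled volume of the derecruitment maneuver is integrated over the
  labelled expiration window (or, unlabelled, from expiratory onset until
  flow decays below threshold or the expiratory time ends). No
  compression/humidity correction is applied.
* Negative $V_{REC}$ and R/I are reported with the flag
  `non_recruiter_negative`.

# Strain

$EELV_{LOW}$ (CT end-expiratory gas at low PEEP) is the FRC surrogate, and
static strain at low PEEP is 0 by definition — the low PEEP is the baseline
condition. The $\Delta EELV$ entering static strain is by default the CT
gas-volume difference (these are CT-based strains); the maneuver-derived
value is available via `delta_eelv_source = "maneuver"` for sensitivity
analysis. GAS_REC is propagated from the recruitment result under the
chosen `gt_mode`, never recomputed. A gas recruitment exceeding
$\Delta EELV$ makes static strain negative; it is flagged, not clamped.

# Cohort statistics

Median [IQR] summaries (type-7 linear-interpolation percentiles — stated
because published medians can shift across conventions); Shapiro–Wilk at
$\alpha = 0.05$ on paired differences gates paired t vs Wilcoxon (a
multivariate normality pre-test is deliberately replaced by these
per-variable checks); Pearson r with the Fisher-z 95% CI
($\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$) and a t-based two-sided p;
OLS diagnostics via hat values and Cook's distance (set to 0 on an exactly
collinear fit, where the usual ratio is 0/0); coefficient of variation
$sd/|\bar x| \times 100$. No multiple-testing correction is applied.

# The synthetic cohort

`cohort_configs()` varies recruitability across subjects by spacing the
mean opening pressure over [2, 11] cmH2O (shuffled across subject indices)
and jittering total mass (N(50, 4) g at desk scale). That range maps to
true R/I ≈ 0.3–2 and baseline dynamic strains ≈ 0.33–0.85 under the default
PEEP step 5 → 15 cmH2O — the spread of a highly recruitable injured-lung
cohort. With it, the pipeline reproduces the qualitative headline
structure: strong negative correlation between R/I and the PEEP-induced
change in dynamic strain, strong positive correlation with normalised gas
recruitment. The exact coefficients depend on the cohort draw; the tests
assert sign and strength (|r| ≥ 0.8), not specific values.

# Known limitations

* Units are binary and share one specific compliance and resting gas
  density; real lungs have continuous aeration spectra, so phantom
  histograms are less smooth than real ones (noise sd 30 HU blurs but does
  not remove this).
* The waveform model uses a constant (secant) compliance per PEEP step;
  intra-tidal recruitment does not curve the pressure rise, so phantom
  stress indices are 1 unless explicitly constructed otherwise.
* The trace's derecruitment exhaled volume is imposed from the unit model,
  so R/I recovery validates the measurement chain and the CT/maneuver
  consistency, not expiratory flow physics.
* No registration between PEEP levels, no regional analysis, no
  transpulmonary pressure.
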