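---
title: "Hybrid planar/SPECT dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid planar/SPECT dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridose)
library(dplyr)
```

## The problem

After a cycle of [^177^Lu]Lu-DOTA-TATE peptide receptor radionuclide
therapy, the mean absorbed dose to the organs at risk (kidneys, red
marrow) and to tumour lesions must be estimated from a small number of
post-therapy scans. The *hybrid* design uses serial planar scintigraphy
— cheap, whole-body, but only semi-quantitative — for the kinetics, and a
single quantitative SPECT/CT for the absolute activity scale. Different
dosimetry systems implement the same chain with different curve-fitting
rules, start conventions and integration horizons, and their dose
estimates differ accordingly. `hybridose` implements the full chain with
every such choice exposed as configuration, so processing arms can be
compared on identical inputs, and implements the agreement statistics
that quantify how far two arms may be used interchangeably.

## Quantification model

Planar counts from opposed detectors depend on target depth; the
geometric mean $GM(t) = \sqrt{C_{ant}(t)\,C_{post}(t)}$ cancels the
first-order depth dependence. Counts are assumed comparable across time
points because the acquisition speed is constant (a
`scan_speed_cm_min` column triggers a proportional renormalisation if it
is not). Absolute calibration comes from one SPECT-derived activity
$A_{SPECT}$ at an anchor time (24 h by default):

$$A(t_i) = GM(t_i)\,\frac{A_{SPECT}}{GM(t_{anchor})}.$$

The count scale cancels, so the planar sensitivity never needs to be
known; the anchor value is reproduced exactly. No background,
attenuation or partial-volume correction is applied — a deliberate
limitation matching clinical hybrid workflows whose errors cancel in a
two-arm comparison on the same data.

The red marrow is sampled by a 4.2 ml sphere in the proximal humerus.
Reference anatomy places 2.3 % of the marrow in the upper half of the
humerus (reference volume 180 ml). The printed scaling arithmetic is
ambiguous: $0.023 \times 4.2/180 = 0.054\,\%$, yet the working value
quoted alongside it is "approximately 0.1 %", which corresponds to
spreading the 2.3 % over *half* the reference volume,
$0.023 \times 4.2/90 = 0.107\,\%$. Both readings are implemented
(`red_marrow_fraction()`, `interpretation = "half_volume"` (default,
reproduces ~0.1 %) or `"full_volume"`).

## Kinetic models and the composite curve

Three empirical TAC models are fitted by bounded Levenberg–Marquardt
least squares (`minpack.lm`), with deterministic log-linear-regression
initial guesses and decay constants constrained to
$[10^{-6}, 10]\ \mathrm{h^{-1}}$:

* `mono`: $A_0 e^{-\lambda t}$ (≥ 3 samples);
* `bi_sum`: $A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$, both
  amplitudes non-negative — the fit starts at the highest observed
  value, the "line"-like behaviour of organ-level MIRD systems
  (≥ 4 samples);
* `bi_origin`: $A_0\,(e^{-\lambda_w t} - e^{-\lambda_u t})$ with
  $\lambda_u > \lambda_w$ — exactly zero at $t=0$, the origin-anchored
  behaviour of voxel-kernel systems (≥ 4 samples).

The exact functional forms inside commercial systems are vendor black
boxes; these two parameterisations emulate the documented *behaviours*
(start at the first sample vs. anchored through the origin), not the
vendors' bits. Fitting four points with four bi-exponential parameters
is intentionally ill-posed — as it is in practice — so non-convergence
and bound-hitting rates are reported (`converged`, `at_bound`), never
silently repaired: a fit that rides $\lambda_u$ to its bound on
monotone-decreasing data is the package's analog of a commercial system
failing to determine an origin-anchored fit.

The effective decay constant $\lambda_e$ is the terminal (smallest)
fitted rate; the effective half-life is $\ln 2/\lambda_e$, about 4 days
(~96 h) for kidney kinetics under this radiopharmaceutical.

TIA integration uses the vendor-style four-step composite curve
(`compose_hybrid_curve()`):

1. extrapolation of the first sample to $t = 0$ — constant at the first
   sample's value (`line`, the default), a linear ramp from $(0,0)$
   (`origin`), or the fitted model itself (`continue`); which shape the
   organ-level system actually uses is undocumented, and `line` was
   chosen as the conservative default consistent with the comparable
   "line" option of the voxel system;
2. trapezoidal bridging between samples up to a user-selectable first
   fit point (default: the first sample, so this segment is empty);
3. the fitted model to the last sample;
4. an exponential tail from the *fitted* value at the last sample. The
   tail decays at $\lambda_e$ unless the effective half-life exceeds the
   physical half-life, in which case the physical decay constant is used
   (the cap). The ^177^Lu half-life is taken as 6.6443 d = 159.46 h
   (evaluated nuclear data; the source texts do not print it), exposed
   via `nuclide_constants()`.

Integration is closed-form per segment and exact; horizons of 2400 h and
infinity are both first-class, matching the two systems' defaults. For
$\lambda_e = \ln 2/96\ \mathrm{h^{-1}}$ the two differ by less than
$10^{-7}$ relative, so horizon choices only matter for pathologically
slow fits. `origin` as a start mode is rejected only for `bi_sum` (whose
sum of decaying exponentials cannot vanish at $t=0$); with a mono model
it is legal and shapes only the extrapolation segment, since mono fits
with an origin-style $t=0$ option do occur in practice.

Where the composed fit does not pass exactly through the samples (noisy
data), the junction between steps 2 and 3 may jump; the curve is exactly
continuous for in-class noiseless fits, and tail continuity with the
fitted value at the last sample always holds. Two model-free estimators
complete the kinetics module: trapezoid-plus-physical-decay
(`trapezoid_physical_decay_tia()`) and a single-time-point
back-extrapolation $\tilde A = A(t_s)e^{\lambda_e t_s}/\lambda_e$
(`single_time_point_tia()`, tagged approximate; the convention is a
design choice, as the cited method's formula is not printed in the
source texts).

## Dose and radiobiology

Mean absorbed dose follows organ-level MIRD self-dose with inverse
patient-mass scaling, $D = \tilde A\, S\, m_{phantom}/m_{patient}$.
Because no vendor publishes its Monte Carlo S values, the package ships
a *synthetic*, clearly-labelled ^177^Lu table
(`inst/extdata/s_values_177lu_synthetic.csv`): non-penetrating energy
0.1473 MeV/decay absorbed locally plus a small mass-dependent photon
fraction, on ICRP-89-like masses (paired kidneys 310 g, single kidney
155 g, marrow 1170 g, unit-density spheres 1–1000 g). Absolute doses are
therefore illustrative; every fixture-based statistic and every
comparison is independent of the S scale. Lesions use log-log sphere
interpolation at the lesion mass (default 4.19 g, a 2 cm unit-density
sphere); extrapolation outside the table is refused. Cross-dose terms
are omitted throughout (the marrow is treated as self-dose only), and
kidneys are combined either as the average of the two doses or via the
averaged residence time — identical under a shared S value and mass, but
recorded distinctly for provenance. A patient with one visible kidney
receives that kidney's dose flagged as a paired-organ estimate.

The biologically effective dose for an exponentially decaying dose rate
$R(t) = R_0 e^{-\lambda_e t}$ is

$$BED = \frac{R_0}{\lambda_e}\left[1 +
  \frac{R_0}{(\mu+\lambda_e)(\alpha/\beta)}\right],$$

with kidney literature values $\mu = 0.248\ \mathrm{h^{-1}}$ and
$\alpha/\beta = 2.6$ Gy as defaults. The implementation works in
absolute Gy/h (an initial dose rate quoted per unit administered
activity must be multiplied by the administered activity first);
dimensional consistency requires rate/decay-constant = dose, and the
identity $D = R_0/\lambda_e$ is part of the returned record. The closed
form equals the linear-quadratic quadrature
$D + (2/(\alpha/\beta))\int_0^\infty R(t)\int_0^t R(w)e^{-\mu(t-w)}\,dw\,dt$,
which the test suite verifies across a seeded parameter grid. BED is
computed for kidneys only — the organ with usable clinical evidence —
with $\lambda_e$ taken from the kidney TAC fit of the same analysis
profile. Cycle planning multiplies the per-cycle BED by the planned four
cycles against the 27 Gy kidney limit; a cumulative BED exactly at the
limit is compliant (the per-cycle threshold line sits at 6.75 Gy), and
`max_allowed_cycles` is the floor of limit/per-cycle.

## Agreement statistics

Two processing arms are compared per stratum (kidneys, red marrow,
tumour lesions) and model with:

* Bland–Altman: bias = mean of $d_i = x_i - y_i$, sample SD
  ($n-1$), limits of agreement bias ± 1.96·SD. The 1.96 multiplier is
  fixed: "95 % limits of agreement" with no stated multiplier, and 1.96
  reproduces the published limits from the fixture values at two
  decimals.
* Relative differences: $r_i = (x_i-y_i)/((x_i+y_i)/2)\times 100\,\%$,
  then the same Bland–Altman machinery; zero-average pairs are excluded
  with a warning.
* Spearman $\rho$ as the Pearson correlation of midranks (tie-corrected);
  on untied data this equals $1 - 6\sum d_i^2/(n(n^2-1))$ exactly.
* ICC(A,1), the McGraw–Wong two-way absolute-agreement single-rater
  coefficient, computed from the ANOVA decomposition with the two arms
  as raters. Absolute agreement penalises systematic offsets, so a
  consistent inter-arm bias can drive the estimate negative; negative
  values are reported as-is with a flag. No implementation of ICC was
  available among the package's dependencies, so the (short) estimator
  is implemented directly and cross-checked against `stats::aov()` in
  the tests.

Fixture-based checks compare at the printed precision (two decimals for
Gy/GBq, integers for percent), because the published statistics were
computed from unrounded clinical values while the fixtures carry the
rounded printed ones. Two known quirks are preserved rather than
repaired: the published kidney mono SD is internally inconsistent with
its own printed limits (the package reports the LOA-consistent SD), and
one red-marrow bi-exponential entry (0.010 Gy/GBq) is a suspected typo
(0.100 would reconcile the published bias of 0.088); the fixture keeps
the printed value under a `suspected_typo` flag, and the rebuilt bias is
0.079. The published red-marrow Spearman (−0.701) is not recoverable
from rounded values — four-way ties dominate the ranks — and is
documented, not asserted.

## The synthetic cohort

`cohort_spec()`/`generate_cohort()` emulate the study design: 10
patients, 7.4 GBq per cycle, planar sampling at 0.5, 4, 24, 72 h, one
SPECT anchor at 24 h. Kinetic priors: kidneys mono-exponential with
lognormal effective half-life (median 96 h, sdlog 0.2, shared between a
patient's kidneys so the paired BED is well-defined); red marrow
mono-exponential, sampled at the 4.2 ml VOI scale; lesions
uptake–washout with a median uptake rate of 0.35 h⁻¹ (peak within the
first day). Planar counts are Poisson around sensitivity × activity ×
view factor, with a single multiplicative anterior/posterior asymmetry
per target depth class — the simplest model that makes the geometric
mean non-trivial — and a planar sensitivity of 30 counts/MBq. Uptake
fractions (0.6 % per kidney, 0.7 % total marrow, 0.11 % per lesion) were
calibrated once so the synthetic dose coefficients land on the clinical
scale of the published tables (~0.5, ~0.06 and ~3 Gy/GBq respectively)
under the shipped S table. At this sensitivity the marrow VOI yields
single-digit counts — deliberately so, as humerus-VOI noise is a known
weakness of the design — and occasionally a target becomes
unquantifiable (zero geometric mean at the anchor); the pipeline records
and excludes such targets with a warning, mirroring the cohort's one
invisible kidney, rather than aborting.

What the generator does *not* model: inter-cycle variability,
amino-acid co-infusion kinetics, scatter/attenuation structure, organ
superimposition, or intra-ROI heterogeneity. Passing recovery tests
therefore demonstrate correctness of the estimation chain under the
stated noise model, not planar quantification accuracy on real images.

With noise off, the full pipeline is an exact identity: anchored
geometric means equal the true TAC at the sample times, `continue`-mode
fits recover the true parameters, and TIA, dose and BED match their
closed-form ground truths to well below $10^{-6}$ relative — verified
end-to-end in the test suite at cohort sizes of 2–3 patients (and 10 for
the two-arm emulation), sizes chosen to exercise every path while
keeping the default test run quick.

## Two-arm emulation

`shipped_profile()` provides two documented-behaviour profiles:
`organ_mird` (integration to infinity, `line` start, `bi_sum`
bi-exponential, kidneys via combined residence time) and `voxel_like`
(2400 h horizon, origin-anchored bi-exponential, per-kidney averaging).
They emulate the two compared system families' *documented* settings and
claim no vendor equivalence. `emulate_pipeline_variants()` runs a cohort
through both and returns paired dose coefficients; identical profiles
give a perfect-agreement control (bias 0, $\rho$ = 1, ICC = 1), and a
mono arm against an origin-anchored bi arm on uptake-phase lesions shows
a positive bias — the origin-anchored arm underestimates the early peak,
consistent with the qualitative failure mode reported for voxel-system
origin fits.

```{r example}
comparison <- reproduce_comparison()
comparison |> filter(model == "mono") |> select(stratum, n, bias, loa_low, loa_high, spearman, icc)
```

## Known limitations

* Organ-level only: no voxel kernels, no dose-rate maps, no
  partial-volume or recovery-coefficient correction.
* Absolute doses inherit the synthetic S table's scale and are
  illustrative.
* Four-point bi-exponential fits are mathematically under-determined by
  design; the package reports rather than prevents the resulting
  instability.
* The vendor emulation is behavioural, not bit-exact; black-box
  internals (fit constraints, kernel convolutions) are out of reach.
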