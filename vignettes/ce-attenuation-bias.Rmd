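---
title: "Contrast-enhanced CT attenuation correction: bias model, synthetic cohort, and Deauville risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-enhanced CT attenuation correction: bias model, synthetic cohort, and Deauville risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvshift)
```

## The measurement problem

A PET image is quantitative only through its attenuation correction. Every
line of response (LOR) is corrected by the attenuation factor
$\mathrm{AF} = \exp(-\int \mu\, dl)$, with $\mu$ the 511 keV linear
attenuation coefficient taken from a CT scan. When a contrast-enhanced
diagnostic CT (CE-CT) replaces the dedicated low-dose CT (AC-CT) for this
purpose, iodinated contrast raises HU — most strongly in blood pool and liver
during the portal-venous phase — so $\mu$ is overestimated, the correction
over-compensates, and SUV values inflate multiplicatively. Long-axial-FOV
scanners accept oblique LORs (up to 52° from the transaxial plane in
ultra-high-sensitivity mode), lengthening tissue paths and potentially
amplifying the effect.

The clinically loaded quantity is not SUV itself but the SUV *ratio* of lesion
to reference tissue (aortic blood pool or liver), thresholded at 1 to assign
Deauville scores 2–4. Contrast accumulates preferentially in the reference
tissues, so SUVRs *fall* under CE-based reconstruction and borderline lesions
can change class.

## Analysis pipeline

`run_pipeline()` composes four stages, each usable on real tabular data as
well as on the synthetic cohort:

1. **Attenuation extraction** — `organ_mean_mu()` averages a μ-map over an
   organ label mask (masks are inputs; segmentation is out of scope);
   `hu_to_mu()` provides a conventional bilinear HU→μ conversion (water
   0.096 cm⁻¹, breakpoint 0 HU, bone slope 5.1·10⁻⁵ cm⁻¹/HU) for HU-space
   inputs. Only *relative* μ changes propagate downstream, so the absolute
   conversion calibration is immaterial. `infill_missing_slices()` completes
   CE volumes whose cranial coverage was spared, slice-by-slice from the AC
   volume, with an explicit provenance mask.
2. **VOI quantification** — reference regions via `spheroid_voi_mask()`
   (voxel-center membership test; deterministic, no partial-volume
   weighting), lesions via `isocontour_voi()`: the 26-connected component,
   containing the max voxel, of voxels at or above 41 % of the regional
   SUVmax (inclusive threshold — the convention had to be fixed here since
   only "41 % SUVmax threshold" is standard usage). VOIs are *copied*
   unchanged across reconstructions (`copy_voi()`), never re-segmented, so
   paired measurements share one voxel set.
3. **Paired statistics** — per-unit percent change $100(x_{CE}-x_{AC})/x_{AC}$,
   robust summaries (median, unscaled MAD, type-7 quartiles, box-plot whiskers
   at Q1 − 1.5 IQR / Q3 + 1.5 IQR clamped to the data), the Wilcoxon
   signed-rank test, and Pearson/Spearman correlations of Δμ % vs ΔSUVmax %.
4. **Deauville risk** — rule-based scores, the SUVR regression, and
   threshold-crossing probabilities (below).

## The Wilcoxon test and its one-sided floor

`wilcoxon_signed_rank()` drops zero differences, and in exact mode computes
the null distribution of the positive-rank sum over all $2^n$ sign
assignments (by the count-polynomial recursion, identical to enumeration;
ties in $|d|$ are refused in exact mode and handled by average ranks plus a
tie-corrected variance in the normal approximation). The default alternative
is one-sided *greater* for the increase tests: with $n = 21$ uniformly
positive differences the exact one-sided p is the attainable floor
$2^{-21} \approx 4.8\cdot10^{-7}$ — which is exactly the printed p-value for
both reference organs, and the reason the one-sided reading is the right
reconstruction of the analysis. The two-sided value would be
$9.5\cdot10^{-7}$.

## The misclassification model

The question "given a CE-based reading $r$, what was the AC-based class?"
motivates regressing SUVR$_{AC}$ (response) on SUVR$_{CE}$ (predictor) by
OLS — per reference organ, independently. For a new lesion at observed ratio
$r$ the AC reading is modelled as Gaussian with mean $a + br$ and the
*prediction-interval* spread

$$\mathrm{sd}(r) = s\sqrt{1 + \tfrac1n + \tfrac{(r-\bar x)^2}{S_{xx}}},$$

because the object of inference is a single lesion, not the mean response
(the confidence-band variant is exposed as a switch; the original
supplementary formula is unavailable, so this functional form is a design
choice flagged as such). Then for $r > 1$ the false-upgrade probability is
$P(\text{AC} \le 1)$ and for $r < 1$ the false-downgrade probability is
$P(\text{AC} > 1)$; the two branches are complementary at the threshold under
one fit, reproducing the published 2.5 %/97.5 % (aorta) and 16 %/84 % (liver)
boundary structure. `risk_flag()` marks ratios whose misclassification
probability exceeds α = 0.05, the "do not trust a CE-based score here" band.

Boundary conventions: SUVR exactly 1 maps to the *lower* score; the rule text
leaves the combination SUVR_aorta ≤ 1 with SUVR_liver > 1 undefined (it
requires liver uptake below blood pool) — the liver clause is given precedence
as written, yielding score 4, and the choice is tested.

## What the synthetic cohort emulates

`generate_cohort()` draws a stated world, fixed once:

* **Cohort structure**: 21 patients, 18 with ≥ 1 lesion, 66 lesions total;
  body weight log-normal (median 70 kg, σ = 0.15), injected activity
  3 MBq/kg (median ≈ 210 MBq).
* **AC-arm distributions**: per-organ SUVmax and μ log-normal, location/scale
  fitted to the published medians and quartiles (aorta SUVmax median 2.21,
  Q1 1.88, Q3 2.41; liver 2.87/2.60/3.24; lesions 5.68/2.53/12.26 — the
  lesion quartiles are near-perfectly log-symmetric, supporting the
  log-normal choice; μ medians per organ from the published attenuation
  table). Muscle and vertebral SUV levels (0.70, 1.80) are realistic FDG
  values chosen once, since only their μ values are published.
* **Bias factors**: multiplicative, log-normal, *parameterised by median* —
  the reported cohort statistics are medians of multiplicative changes, and
  the log-normal median equals $e^{\mu_{\log}}$, so the calibration constants
  are hit exactly in expectation. Medians: SUV factors aorta 1.0878, liver
  1.0786; μ factors aorta 1.1040, liver 1.049 (both published as median
  intra-patient changes), muscle 1.0071 and vertebra 1.0403 (ratio of
  published medians — the only anchor for those organs).
* **Dispersions** (not published; chosen once from the published
  increase/decrease counts and quartile spreads): SUV-factor σ 0.03 for the
  reference organs (consistent with 21/21 increases), SUVR-ratio σ 0.0375
  (chosen so P(ratio > 1) ≈ 9 %, matching the published 60/66 SUVR_aorta
  decreases), μ-factor σ per organ 0.02/0.01/0.003/0.0235 (the vertebral
  value makes a single small decrease in 21 patients — the published edge
  case — about as likely as observed).
* **SUVR coupling**: each lesion's CE/AC factor is its patient's aorta factor
  times a dedicated ratio draw with median 0.9510. Medians do not compose
  under division, so the three published medians (+8.78 % aorta, +5.80 %
  lesion, −4.90 % SUVR) are mutually inconsistent in any independent-factor
  model; this coupling reproduces the aorta and SUVR medians exactly and
  concedes the lesion marginal (which becomes +3.45 % in median). The
  alternative `lesion_coupling = "marginal"` makes the opposite trade.
  `truncate_positive` conditions every factor (and, in the coupled mode, the
  *product*) on exceeding 1 by inverse-CDF truncation, making the "increase
  in all cases" fraction exactly 100 % downstream.
* **Correlation structure**: within each organ, the patient's log μ-factor
  and log SUV-factor share a Gaussian component (ρ = 0.5), giving the pooled
  Δμ %–ΔSUV % correlation its sign and rough magnitude without claiming the
  published per-organ coefficients.

What the generator does **not** emulate: tomographic reconstruction, scatter
and randoms, scanner sensitivity profiles, registration error, partial-volume
effects, reader adjudication, and any correlation between lesion burden and
reference uptake. A green recovery test therefore establishes that the
*pipeline* is calibrated and unbiased — not that the generator is a faithful
patient model.

## Phantom mode and physics mode

`generate_phantom()` rasterises a piecewise-constant voxel patient (liver
ellipsoid, aortic tube, muscle slab, vertebral block, spherical lesions on a
64³, 4 mm grid) whose organ-mask means and lesion SUVmax recover the tabular
truth exactly with noise off — the bridge that lets the VOI and μ-map code be
tested against the generator's ground truth. Optional additive Gaussian noise
is seeded per patient. `lor_bias_field()` is the optional first-principles
mode: the per-voxel bias is the mean over LOR directions within the
acceptance angle of $\exp(\int(\mu_{CE}-\mu_{AC})\,dl)$ along the full line —
the exact over-correction ratio for a piecewise path. It integrates by
midpoint sampling at half-voxel steps with nearest-neighbour lookup and is
intended for small grids (plain-R ray marching); the default generator
applies calibrated factors directly.

## Numerical choices

* Quantiles: type 7 (linear interpolation), the common default; MAD unscaled
  (no 1.4826), configurable — whether the published MADs were scaled is
  unstated, and the printed values cannot adjudicate it.
* Exact Wilcoxon limited to ≤ 30 untied nonzero differences in the pipeline's
  `"auto"` mode (beyond that $2^{-n}$ underflows relevance and the DP vector
  grows); the normal approximation takes over for the n = 2000 recovery runs.
* Grid convention: voxel centers at index × spacing (0-based), axis order
  (x, y, z), identity orientation; co-registration is a contract enforced by
  grid-identity checks, not a computation.
* Volumes serialize to a headered plain-text format rather than NIfTI: no
  NIfTI package is part of the package's dependency footprint, and the
  format keeps fixtures text-only and diffable. The in-memory contract
  (`voxel_volume`: array + spacing + unit tag) is unchanged.
* Seeds: one master seed drives the cohort; phantom noise takes an explicit
  per-patient seed. All randomness flows through R's generator, so identical
  config + seed reproduces byte-identical tables.

## Known limitations

* The misclassification probabilities of a synthetic cohort depend on that
  cohort's fitted regression; the published boundary percentages (2.5/97.5,
  16/84) came from the clinical fit, whose parameters are not public, so only
  their structure (complementarity, monotonicity, the 1.96·sd construction)
  is testable, and the package's tests construct fits with the stated
  boundary geometry explicitly.
* The lesion Wilcoxon p of order 10⁻¹² at n = 66 depends on the unpublished
  rank pattern and is deliberately not a target.
* Percent change is not antisymmetric in its arguments; all summaries fix the
  AC arm as baseline.
* The isocontour applies the fraction to the plain regional max (no
  background subtraction), and connectivity is 26-neighbour — both stated
  conventions rather than derivable facts.
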