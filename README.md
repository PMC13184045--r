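# suvshift

Quantifying the bias that a contrast-enhanced CT introduces into PET SUV
measurements when it is used for attenuation correction — and what that bias
does to Deauville scoring of lymphoma lesions.

## The problem

PET quantification depends on an attenuation map (μ, cm⁻¹ at 511 keV) derived
from a CT scan. Clinics increasingly acquire a diagnostic contrast-enhanced CT
(CE-CT) in the same session as the low-dose attenuation-correction CT (AC-CT).
Reconstructing the PET with the CE-CT would save dose and time — but iodinated
contrast inflates HU values, hence μ, hence the attenuation factor
exp(−∫μ dl) along each line of response, and therefore the standardized
uptake values (SUV). On long-axial-FOV scanners the oblique LORs (acceptance
angles up to 52°) traverse more tissue, making the effect potentially larger.

The clinical stakes sit in the Deauville score: lymphoma response is read from
SUV ratios (SUVR) of lesion to blood pool (aortic lumen) and to liver, with a
rule threshold at 1:

* score 2 if SUVR_aorta ≤ 1
* score 3 if SUVR_aorta > 1 and SUVR_liver ≤ 1
* score 4 if SUVR_liver > 1

Contrast accumulates more in the reference tissues than in lesions, so CE-based
reconstruction inflates the denominators more than the numerators: SUVRs drop,
and lesions near the threshold can be *downgraded* (or, just above it,
represent a *false upgrade* relative to the AC-based reading).

Because the underlying patient data are not public, the package ships a
seeded synthetic cohort generator calibrated to the published cohort structure
(21 patients, 18 with lesions, 66 lesions; organ μ and SUV distributions;
multiplicative CE/AC bias factors parameterised by their medians: aorta SUVmax
+8.78 %, liver +7.86 %, aorta μ +10.4 %, per-lesion SUVR_aorta −4.90 %).
Every cohort statistic is then *recovered* by running the analysis pipeline on
synthetic data, never asserted.

## What's inside

| Module | Functions |
| --- | --- |
| Synthetic cohort & phantoms | `generator_config()`, `generate_cohort()`, `sample_bias_factor()`, `generate_phantom()`, `lor_bias_field()` |
| Attenuation maps | `hu_to_mu()`, `organ_mean_mu()`, `infill_missing_slices()`, `mu_change_table()` |
| VOI quantification | `spheroid_voi_mask()`, `isocontour_voi()` (41 % of SUVmax, 26-connected), `copy_voi()`, `voi_stats()`, `suv_from_activity()` |
| Paired statistics | `percent_change()`, `paired_summary()`, `wilcoxon_signed_rank()` (exact + normal), `correlation()`, `distribution_curves()` |
| Deauville risk | `suvr()`, `deauville_score()`, `fit_suvr_regression()`, `prediction_distribution()`, `misclassification_probability()`, `risk_flag()`, `risk_curve()`, `score_change_table()` |
| Orchestration | `run_pipeline()`, `write_report_bundle()`, CLI at `inst/cli/suvshift.R` |

The misclassification model regresses the AC-based SUVR on the observed
CE-based SUVR by ordinary least squares and treats a new lesion's AC reading
as Gaussian with the prediction-interval spread
s·√(1 + 1/n + (r − x̄)²/Sxx); the probability that the true class lay on the
other side of the threshold is a Gaussian tail probability.

## Worked example

```r
library(suvshift)
res <- run_pipeline(generator_config(seed = 1))
print(res)
#> <pipeline_result>
#>   cohort: 21 patients, 66 lesions
#>   aorta SUVmax: median change +8.51% (increase in 21/21), Wilcoxon p = 4.8e-07
#>   Deauville changes: 0 upgraded, 1 downgraded

res$suv[res$suv$unit_type == "aorta",
        c("median_ac", "median_ce", "median_percent_change", "n_increase")]
#>   median_ac median_ce median_percent_change n_increase
#> 1     2.186     2.384                 8.509         21

res$fits$aorta
#> <suvr_fit> SUVR_AC = 0.1499 + 1.0011 * SUVR_CE, residual SD 0.2697 (n = 66)
```

Reading this: in the seed-1 synthetic cohort the blood-pool SUVmax rises in
every one of the 21 patients when the CE-CT drives the attenuation correction
(median intra-patient change +8.5 %, close to the +8.78 % calibration median),
and the exact one-sided Wilcoxon signed-rank p is the enumeration floor
2⁻²¹ ≈ 4.8·10⁻⁷ — with 21 of 21 increases no smaller p is attainable. One of
the 66 lesions crosses an SUVR threshold and is downgraded by one Deauville
score. The fitted SUVR regression then yields, via
`misclassification_probability()`, the lesion-wise probability that a CE-based
reading near the threshold misrepresents the AC-based class.

The same run from the shell, with all report tables written as CSV:

```sh
Rscript inst/cli/suvshift.R run-all --seed 1 --out report/
```

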