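# hp13c — hyperpolarized ¹³C-pyruvate renal metabolic MRI quantification

Hyperpolarized (HP) [1-¹³C]pyruvate MRI watches an injected pyruvate bolus
being converted to lactate and bicarbonate in living tissue over a ~1-minute
window.  In kidney-transplant imaging the headline readout is the
**normalized lactate-to-pyruvate AUC ratio** of the renal cortex,

> ratio = (lactate AUC, summed over all timepoints) / (maximum kidney pyruvate AUC),

with bicarbonate handled the same way after a voxel-size normalization
(2 cm vs 1 cm in-plane acquisition ⇒ divide its AUC by 4).  Elevated
cortical ratios mark a shift toward anaerobic glycolysis, the metabolic
signature of allograft inflammation and fibrosis — potentially before
eGFR declines.

This package is for imaging scientists building or validating HP ¹³C
processing chains.  Because clinical HP data cannot be redistributed, every
stage runs against a **digital-kidney phantom** with known ground truth.
The package implements:

* **phantom** — gamma-variate AIF, one-way two-site exchange kinetics with
  T₁ decay and per-frame RF consumption cos(θ)^N, anterior-weighted
  8-channel complex coil profiles, correlated complex Gaussian noise, plus
  companion DWI and multi-echo ¹H series (`simulate_study()`);
* **prescan** — bolus-arrival detection against a 2× noise threshold and
  centre-frequency estimation from a FID (`detect_bolus()`,
  `estimate_frequency_offset()`);
* **recon** — noise pre-whitening (inverse Cholesky of the channel
  covariance), AUC-based coil sensitivity maps, matched-filter channel
  combination, Fermi-filtered zero-fill interpolation
  (`reconstruct_study()`, `fermi_zero_fill()`);
* **quantify** — AUC maps, mean-time ("centre of mass") timing correction
  by removal of 3–4 initial frames, voxel-size and noise-level
  normalizations, ratio maps, ROI and group statistics
  (`compute_auc_map()`, `mean_time_correct()`, `metabolite_ratio_map()`);
* **relaxometry** — voxelwise weighted log-linear ADC and R₂* fits
  (`fit_adc()`, `fit_r2star()`);
* **pipeline** — one-call orchestration from a serializable YAML config
  with full seed-level reproducibility (`study_config()`,
  `run_pipeline()`).

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate_cohort.R` … `05_report.R`) that run a six-phantom cohort
through the chain and write tables under `results/`.

## Worked example

```r
library(hp13c)

res <- run_pipeline(study_config(subject_id = "demo", seed = 1))
round(res$report_row$lac_pyr_mean, 3)   # 0.382  cortical lactate-to-pyruvate ratio
round(res$report_row$bic_pyr_mean, 3)   # 0.048  bicarbonate-to-pyruvate ratio
res$report_row$bolus_time_s             # 21     bolus detected (s after injection)
round(res$report_row$pyr_auc_snr, 1)    # 54.6   kidney pyruvate AUC SNR
round(res$report_row$adc_mm2_s, 5)      # 0.00199  cortical ADC (truth 0.002 mm^2/s)
round(res$report_row$r2star_s1, 1)      # 15.3   cortical R2* (truth 15 1/s)
```

The default phantom emulates a normally functioning allograft: its cortical
ratio (~0.38) sits in the range observed for stable transplants with normal
biopsies, the bolus trigger fires ~21 s after injection start (observed
arrival: 15–28 s), and the pyruvate AUC SNR lands inside the clinically
observed 10–60 band.  Raising the ground-truth conversion rate `kpl`
reproduces the elevated ratios of injured allografts:

```r
run_pipeline(study_config(seed = 1,
  kinetics = list(kpl = c(0.21, 0.15, 0))))$report_row$lac_pyr_mean  # ~0.54
```

Running the cohort workflow end to end:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_reconstruct.R
Rscript analysis/03_quantify_cohort.R   # per-subject + tier tables
Rscript analysis/04_relaxometry.R
Rscript analysis/05_report.R            # summary-table report + repeat-injection check
```

`results/group_summary.csv` then contains the tier means — e.g. normal
tier 0.377 (range 0.346–0.410) vs abnormal tier 0.552 (0.541–0.563) under
the shipped ground-truth rates.

## Layout

```
R/                  implementation (phantom, prescan, recon, quantify,
                    relaxometry, pipeline, NIfTI/JSON/YAML I/O)
analysis/           numbered workflow drivers writing results/
tests/testthat/     unit, property and acceptance suites with
                    independent brute-force oracles
scripts/acceptance.R  headline-quantity reproduction script
vignettes/hp13c-methods.Rmd  the full methods account: model, parameter
                    choices, numerical decisions, limitations
```
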