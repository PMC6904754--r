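# placentafbv

Estimation of **placental fractional blood volume (FBV)** from
contrast-enhanced MRI and CT in the late-gestation pregnant mouse, with a
digital phantom for end-to-end validation.

Placental FBV — the fraction of placental tissue volume occupied by
maternal blood — is a direct marker of placental vascular perfusion, of
interest for detecting placental insufficiency and fetal growth
restriction. With a *blood-pool* contrast agent (a liposomal-Gd or
liposomal-iodine nanoparticle confined to the vasculature, which does not
cross the placental barrier), tissue enhancement is proportional to blood
volume, so FBV can be read out as an enhancement ratio against pure blood
in the inferior vena cava (IVC):

```
FBV_MRI = ΔR1_P / ΔR1_IVC        R1 = 1/T1, Δ = post − pre contrast
FBV_CT  = ΔHU_P / ΔHU_IVC        HU from calibrated CT ROI means
```

T1 is estimated by the **variable flip angle (VFA / DESPOT1)** method:
spoiled-GRE images at flip angles α = [8°, 15°, 25°, 35°, 45°]
(TR = 20 ms, TE = 3.5 ms) are pooled per ROI and fit through the
linearization `S/sin α = (S/tan α)·e^(−TR/T1) + M0(1 − e^(−TR/T1))` by
ordinary least squares.

The package provides:

* `phantom_config()` / `build_phantom()` / `generate_cohort()` — a
  multi-compartment 3D phantom of the pregnant abdomen (placentae,
  amniotic sacs, IVC, maternal background) with known per-placenta blood
  fractions, simulated pre/post-contrast VFA MRI series
  (`simulate_vfa_series()`) and CT pairs (`simulate_ct_pair()`), written
  as NIfTI volumes with JSON study manifests;
* `gre_signal()`, `fit_t1_vfa()`, `fit_t1_voxelwise()` — the spoiled-GRE
  forward model and the VFA T1 estimator (ROI-mean and voxelwise);
* `compute_fbv_mri()`, `compute_fbv_ct()`, `run_study()`,
  `summarize_cohort()` — per-placenta FBV against the subject's shared
  IVC reference, with cohort summaries;
* `bland_altman()`, `wilcoxon_rank_sum()` — cross-modality agreement
  (limits of agreement at bias ± 1.96 SD of percent differences) and
  exact/approximate rank-sum tests;
* `gestation_reference()` — published E14.5/E16.5/E18.5 reference values
  (placenta and IVC T1s, FBV means) used to parameterize phantoms;
* a thin CLI (`inst/cli/placentafbv`) with `simulate`, `fit-t1`, `fbv`,
  `agree` and `report` subcommands.

## Worked example

Simulate a 3-dam E14.5 cohort (blood fractions drawn around 0.47, SNR 50
Gaussian noise), run both modality arms, and measure agreement:

```r
library(placentafbv)

cfg <- phantom_config_for_age("E14.5", f = NULL, f_mean = 0.47, f_sd = 0.06,
                              noise_model = "GAUSSIAN", snr = 50)
coh <- generate_cohort(3, cfg, "cohort_e145", seed = 1,
                       gestational_age_label = "E14.5")
est <- do.call(rbind, lapply(coh, function(s) run_study(s$manifest)))

head(est[, c("subject_id", "fpu", "modality", "fbv", "flags")], 4)
#>  subject_id fpu modality       fbv flags
#>         S01   1      MRI 0.5039158
#>         S01   2      MRI 0.5243316
#>         S01   3      MRI 0.5232538
#>         S01   4      MRI 0.4379949

summarize_cohort(est)
#>  group modality n_fpu  mean_fbv     sd_fbv
#>  E14.5       CT    23 0.4654632 0.06235534
#>  E14.5      MRI    23 0.4656179 0.06606531

paired <- pair_estimates(est[est$modality == "MRI", ],
                         est[est$modality == "CT", ])
bland_altman(paired)
#> <bland_altman_result> n = 23, bias = -0.08%, limits [-5.15%, 4.99%], 96% within
wilcoxon_rank_sum(paired$fbv_mri, paired$fbv_ct)
#> <rank_sum_result> W = 539, p = 0.9825 (NORMAL_APPROX)
```

The three dams carry 23 feto-placental units between them; both modality
arms recover the generating mean (0.47) within sampling error, their
per-FPU estimates agree with near-zero bias, and the rank-sum test finds
no modality difference — the behavior expected of two unbiased estimators
of the same quantity. On a *noiseless* phantom the recovery is exact:
both arms return the configured blood fraction to better than 10⁻⁹
relative error (see the test suite).

## Acceptance script

`scripts/acceptance.R` re-derives the headline cohort quantities from
scratch by running the installed package end-to-end: noiseless MRI round
trips at E14.5 and E18.5, a noiseless CT round trip at E14.5 (phantoms
whose per-placenta blood fractions are set to the corresponding reported
cohort means, simulated, fitted and estimated), and a noisy 3-subject
20-FPU E16.5 cohort mean (f ~ N(0.50, 0.04), SNR 50) through the full
disk pipeline. Run it from the repository root against the installed
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/placental-fbv-methods.Rmd` documents the signal model, the
linear-mixing generative assumption and what round-trip validation does
and does not establish, all defaults with rationale, and numerical edge
cases.
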