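---
title: "Methods: placental fractional blood volume from contrast-enhanced MRI and CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placental fractional blood volume from contrast-enhanced MRI and CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Placental fractional blood volume (FBV) — the fraction of placental tissue
occupied by maternal blood — is a direct readout of placental vascular
perfusion, and abnormally low FBV is a candidate early marker of placental
insufficiency and fetal growth restriction. With a *blood-pool* contrast
agent (a liposomal gadolinium or iodine nanoparticle that stays in the
vasculature and does not cross the placental barrier), tissue enhancement
reflects blood volume rather than extravasation, so FBV can be estimated
non-invasively by comparing the enhancement of placental tissue to the
enhancement of pure blood.

This package implements that estimation pipeline for the late-gestation
pregnant mouse (gestational days E14.5–E18.5, 6–10 feto-placental units
per dam, one maternal IVC as the 100%-blood reference), together with a
digital phantom that simulates the whole experiment so every estimator can
be validated by round trip against known ground truth.

## Signal model and T1 estimation

The spoiled gradient-recalled-echo (GRE) steady-state signal at flip angle
$\alpha_i$ is

$$S_{\alpha_i} = \frac{M_0\,(1 - E_1)\,e^{-TE/T2}}{1 - \cos\alpha_i\,E_1}\,
  \sin\alpha_i, \qquad E_1 = e^{-TR/T1}.$$

In the T1-weighted regime ($TE \ll T2$; here $TE = 3.5$ ms against tissue
$T2 \approx 50$ ms) the $e^{-TE/T2}$ factor is a flip-angle-independent
scale and is dropped. The variable flip angle (VFA, DESPOT1) method
acquires this signal at several flip angles with fixed TR and exploits the
linearization

$$\frac{S_{\alpha_i}}{\sin\alpha_i} =
  \frac{S_{\alpha_i}}{\tan\alpha_i}\,E_1 + M_0(1 - E_1),$$

so unweighted ordinary least squares of $S/\sin\alpha$ on $S/\tan\alpha$
gives $E_1$ as the slope, hence $T1 = -TR/\ln(\text{slope})$ and
$M_0 = \text{intercept}/(1-\text{slope})$. The estimator is *scale
invariant*: multiplying all signals by a constant leaves $T1$ unchanged
and scales $M_0$. This is why the neglected $T2$ factor (and any constant
receiver gain) does not bias $T1$ — and also why a gain change *between*
scans would silently corrupt the analysis; the pipeline cannot detect
that, it must be guaranteed by the acquisition.

FBV then follows from relaxation rates $R1 = 1/T1$ of pre/post-contrast
ROI fits,

$$\mathrm{FBV}_{MRI} = \frac{\Delta R1_P}{\Delta R1_{IVC}}, \qquad
  \mathrm{FBV}_{CT} = \frac{\Delta HU_P}{\Delta HU_{IVC}},$$

with the subject's single IVC serving every placenta of that dam. The
ROI-mean path (pool the ROI signal, then fit) is the primary estimator;
voxelwise T1 maps (`fit_t1_voxelwise()`) are provided for inspection only
and never feed FBV.

## The generative model of the phantom

The phantom assumes *fast-exchange linear mixing*: a tissue compartment
holding blood fraction $f$ changes its relaxation rate (and its CT
attenuation) by $f$ times the blood change,

$$R1_{post} = R1_{pre} + f\,\Delta R1_{blood}, \qquad
  HU_{post} = HU_{pre} + f\,\Delta HU_{blood}.$$

This is the unique tissue model under which the two ratio estimators
above are exactly unbiased, which is what makes round-trip validation
meaningful: on a noiseless phantom both estimators must return the
configured $f$ to machine precision, and the test suite asserts exactly
that (relative error below $10^{-9}$). The generator and the estimator
are therefore mutual inverses *by construction*; a green round trip
establishes that the pipeline is internally consistent and numerically
exact, not that real placental tissue obeys linear mixing.

## The stated world (defaults and why)

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| TR / TE | 20 / 3.5 | ms | the 1 T small-animal T1w-GRE protocol |
| Flip angles | 8, 15, 25, 35, 45 | deg | the acquisition's VFA schedule |
| Grid | 96³ at 0.5 | mm | 0.5 mm isotropic GRE voxels, 48 mm field |
| Placenta T1 (pre) | 1300 | ms | published E14.5 cohort mean |
| Blood T1 pre → post | 1020 → 690 | ms | published E14.5 IVC means |
| Tissue / blood T2 | 50 / 100 | ms | typical at 1 T; exercises TE≪T2 |
| Blood HU pre → post | 60 → 560 | HU | 500 HU liposomal-iodine enhancement |
| Per-placenta f | Normal(0.50, 0.05), truncated to [0,1] | — | reported cohort means 0.47–0.52, SDs 0.04–0.06 |
| FPU per dam | uniform 6–10 | — | reported litter sizes |
| IVC diameter | 2 | mm | reported vessel caliber |
| SNR | 50 | — | no SNR is published; repository choice |
| Noise | additive Gaussian, sd = peak pre-contrast signal / SNR | — | keeps the noiseless limit analytically checkable |

`gestation_reference()` exposes the published per-age T1 and FBV values;
`phantom_config_for_age()` builds a configuration from one age's row.
These defaults are stated once and are not tuned against test outcomes.

Gaussian noise is the default because its sample mean converges to the
noiseless value, making calibration checks exact; Rician noise (the
correct model for MR magnitude images, biased upward at low SNR) is
available via `noise_model = "RICIAN"` for realism studies.

Geometry is parametric, not anatomical: ellipsoidal placentae capping
ellipsoidal amniotic sacs on a ring, a cylindrical IVC, a maternal body
ellipsoid, air outside. All analysis is ROI statistics on labeled
compartments, which is exactly what the real protocol does with manually
drawn ROIs; nothing downstream depends on shape realism. What the phantom
deliberately does **not** emulate: partial-volume voxels at compartment
boundaries (compartments are homogeneous), fetal/maternal motion,
B1 inhomogeneity, imperfect spoiling, contrast washout during the scan,
and CT at its native 35 µm resolution (CT is simulated on the MRI grid;
ROI-mean ratios are grid-invariant under linear mixing). A green test
therefore validates the estimation mathematics, not robustness to these
physical effects.

## Numerical choices

* **Exact quadrant trigonometry.** Linearization uses `sinpi`/`cospi`,
  so a 90° flip angle yields $x = S\cos 90^\circ/\sin 90^\circ = 0$
  exactly rather than a division by `tan(90°)`.
* **Invalid fits are values, not errors.** Voxels or ROIs where the VFA
  fit fails (all-zero signal, slope outside $(0,1)$, $T1$ outside the
  validity window $(1, 10000)$ ms — a guard against noise-driven
  logarithms of near-1 slopes) yield `valid = FALSE`, and T1 maps carry
  the sentinel $-1$, keeping maps single-channel.
* **Enhancement guards.** An IVC rate change below $10^{-6}$ ms$^{-1}$
  (or 1 HU for CT) raises "no blood enhancement" instead of dividing;
  negative placental changes produce estimates flagged `OUT_OF_RANGE`,
  never clipped or censored — outliers are reported, as in box-plot
  presentations of per-FPU estimates.
* **Sample SD everywhere** ($n-1$), the small-cohort convention; SD is
  `NA` for singleton groups rather than 0.
* **Rank-sum test.** Exact two-sided p by full enumeration of the
  $\binom{n}{n_x}$ rank splits when the pooled tie-free sample has
  $n \le 20$; otherwise the normal approximation with midranks,
  tie-corrected variance and continuity correction (ties always route to
  the approximation — the exact null under ties is nonstandard).
  Exhaustive enumeration at $8+8$ shows the approximation's worst-case
  absolute gap from the exact p is 0.0109 (at $p \approx 0.44$); the
  property test asserts this measured bound, since 0.01 is not attainable
  by the standard approximation.
* **Bland–Altman on percent differences**, denominator the pair mean
  (standard practice), limits at bias $\pm 1.96$ sample SD of the
  percent differences. Absolute differences are returned alongside; the
  percent scale is primary because agreement for FBV is conventionally
  plotted and summarized that way.
* **Two-sided tests throughout**, with significance tiers
  $p<0.05$ (\*), $p<0.005$ (\*\*), $p<0.0005$ (\*\*\*), strict
  inequalities.

## Ratio of means is not the mean of ratios

Plugging cohort-*mean* T1s into the FBV formula does not reproduce the
cohort-mean FBV: at E14.5 the published mean T1s give
$\Delta R1_P/\Delta R1_{IVC} = 0.756$ against a reported per-FPU mean FBV
of 0.47 (at E18.5: 0.487 vs 0.52). FBV is defined per feto-placental
unit and then averaged, and the ratio is nonlinear, so the two
aggregations differ — substantially so here, which suggests wide
per-FPU spread in $\Delta R1$. The package therefore validates by
*round-trip recovery*: phantoms are built with per-FPU $f$ set to the
reported FBV means, processed end-to-end, and must return those values.
The T1-level inconsistency is documented, not resolved; it is a property
of the published summary statistics, not of this implementation.

## Design choices that were genuinely open

* **No nonlinear (Levenberg-style) VFA refinement**: the protocol
  specifies fitting via the linearization, and unweighted OLS on it is
  kept as the sole estimator for fidelity; a weighted or nonlinear pass
  would change noise propagation and is noted as an extension, not a
  default.
* **No B1 correction**: flip angles are treated as nominal, matching the
  acquisition being modeled.
* **Integer-labeled single mask file** per subject (not one binary mask
  per ROI), with the label→role/FPU table carried in the study manifest —
  the manifest already binds volumes to the mask, so the mapping lives
  with the binding.
* **Metadata sidecars.** NIfTI carries no modality/contrast-state/flip
  angle, and these are never guessed from intensities; `write_volume()`
  emits a JSON sidecar and `read_volume()` honors explicit arguments
  first, then the sidecar.
* **No resampling or registration** anywhere: all stages require
  co-registered grids, as ROI analysis on acquired grids implies.
  Shape agreement between volume and mask is checked at load time.
* **CT noise** is additive Gaussian in HU (default sd 5 HU when enabled);
  HU analysis is shift-invariant (an identical recalibration offset of
  both scans cancels in the ratio) but *not* gain-invariant — a gain
  change between pre and post scans breaks the enhancement ratio, the CT
  analogue of the receiver-gain caveat in MRI.

## Known limitations

* Estimates are maternal-side only: a blood-pool agent that does not
  cross the placental barrier cannot see fetal-side perfusion.
* The homogeneous-compartment phantom cannot probe partial-volume bias at
  the ~2 mm IVC against 0.5 mm voxels, a real concern the vessel-caliber
  geometry only gestures at.
* Absolute blood volume (mL), flow, and pharmacokinetics are out of
  scope; the agent is modeled as a steady-state blood pool.
* The real study's per-FPU counts, cross-modality p-values and
  97%-within-limits figure depend on the animal data and are not
  reproducible from simulation; the package reproduces the estimator
  mathematics and the cohort means by construction instead.
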