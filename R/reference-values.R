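#' Late-gestation pregnant-mouse reference values at 1 T
#'
#' Published cohort-level reference values for the C57BL/6 pregnant mouse
#' imaged with a liposomal blood-pool contrast agent at gestational days
#' E14.5, E16.5 and E18.5: pre/post-contrast T1 relaxation times (mean
#' and SD, ms) of placenta and IVC, the MRI- and CT-derived placental
#' fractional blood volume cohort means and SDs, and the number of
#' feto-placental units analyzed per age. These are the canonical inputs
#' for parameterizing phantoms that emulate such a study.
#'
#' Note the cohort-mean T1s are not mutually consistent with the reported
#' mean FBVs: FBV was estimated per FPU and then averaged, and a ratio of
#' cohort-mean rate changes does not equal the mean of per-FPU ratios
#' (e.g. the E14.5 means give a ratio of 0.756 against a reported mean
#' FBV of 0.47). Phantom round trips therefore set per-FPU blood
#' fractions to the reported FBV means directly.
#'
#' @return `data.frame` with one row per gestational age and columns
#'   `age`, `placenta_t1_pre`, `placenta_t1_pre_sd`, `placenta_t1_post`,
#'   `placenta_t1_post_sd`, `ivc_t1_pre`, `ivc_t1_pre_sd`, `ivc_t1_post`,
#'   `ivc_t1_post_sd` (ms), `fbv_mri_mean`, `fbv_mri_sd`, `fbv_ct_mean`,
#'   `fbv_ct_sd` (dimensionless), `n_fpu`.
#' @export
gestation_reference <- function() {
  data.frame(
    age = c("E14.5", "E16.5", "E18.5"),
    placenta_t1_pre = c(1300, 1240, 1200),
    placenta_t1_pre_sd = c(110, 70, 50),
    placenta_t1_post = c(890, 860, 720),
    placenta_t1_post_sd = c(70, 40, 40),
    ivc_t1_pre = c(1020, 1150, 1060),
    ivc_t1_pre_sd = c(60, 40, 30),
    ivc_t1_post = c(690, 600, 480),
    ivc_t1_post_sd = c(60, 40, 30),
    fbv_mri_mean = c(0.47, 0.50, 0.52),
    fbv_mri_sd = c(0.06, 0.04, 0.04),
    fbv_ct_mean = c(0.48, 0.48, 0.51),
    fbv_ct_sd = c(0.06, 0.03, 0.04),
    n_fpu = c(24L, 20L, 23L),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration matching one gestational age
#'
#' Convenience constructor: a [phantom_config()] whose blood T1s come
#' from the IVC reference row for `age` and whose per-placenta blood
#' fractions default to that age's MRI FBV cohort mean.
#'
#' @param age `"E14.5"`, `"E16.5"` or `"E18.5"`.
#' @param f Per-placenta blood fraction(s); defaults to the age's MRI
#'   cohort mean. Pass `NULL` to draw from `Normal(f_mean, f_sd)`.
#' @param ... Further arguments to [phantom_config()].
#' @return A [phantom_config()].
#' @export
phantom_config_for_age <- function(age = c("E14.5", "E16.5", "E18.5"),
                                   f = ref$fbv_mri_mean[ref$age == age],
                                   ...) {
  age <- match.arg(age)
  ref <- gestation_reference()
  row <- ref[ref$age == age, ]
  cp <- default_compartments()
  cp$placenta$t1_ms <- row$placenta_t1_pre
  cp$blood$t1_pre_ms <- row$ivc_t1_pre
  cp$blood$t1_post_ms <- row$ivc_t1_post
  force(f)
  phantom_config(f = f, compartments = cp, ...)
}
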