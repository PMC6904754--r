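# Fractional blood volume estimation.
#
# Both arms are ratio estimators against the subject's IVC (pure blood)
# reference:
#   MRI:  FBV = dR1_P / dR1_IVC,  R1 = 1/T1 from ROI-mean VFA fits
#   CT:   FBV = dHU_P / dHU_IVC,  HU from ROI means of calibrated volumes
# One IVC per dam serves every placenta of that subject. Out-of-range
# estimates (outside [0, 1]) are flagged, never clipped or censored.

DEFAULT_DR1_THRESHOLD <- 1e-6  # 1/ms; below this the IVC did not enhance
DEFAULT_DHU_THRESHOLD <- 1     # HU

#' Longitudinal relaxation rate R1 = 1/T1
#'
#' Accepts a positive T1 in milliseconds or a `t1_fit_result`; an invalid
#' fit propagates to `NA` rather than raising.
#'
#' @param t1 Positive T1 in ms, or a [fit_t1_vfa()] result.
#' @return R1 in 1/ms (`NA` for an invalid fit).
#' @export
relaxation_rate <- function(t1) {
  if (inherits(t1, "t1_fit_result")) {
    if (!isTRUE(t1$valid)) return(NA_real_)
    t1 <- t1$t1_ms
  }
  if (any(!is.finite(t1)) || any(t1 <= 0)) {
    stop("t1 must be finite and > 0", call. = FALSE)
  }
  1 / t1
}

#' Pair of pre/post-contrast T1 values for one compartment
#'
#' @param t1_pre_ms,t1_post_ms Positive T1 values, ms.
#' @param compartment `"PLACENTA"` or `"IVC"`.
#' @return An object of class `relaxometry_pair` carrying the T1s and
#'   their reciprocal rates.
#' @export
relaxometry_pair <- function(t1_pre_ms, t1_post_ms,
                             compartment = c("PLACENTA", "IVC")) {
  compartment <- match.arg(compartment)
  stopifnot(t1_pre_ms > 0, t1_post_ms > 0)
  structure(list(t1_pre_ms = t1_pre_ms, t1_post_ms = t1_post_ms,
                 r1_pre = 1 / t1_pre_ms, r1_post = 1 / t1_post_ms,
                 compartment = compartment),
            class = "relaxometry_pair")
}

fbv_estimate <- function(subject_id, fpu, modality, numerator, denominator) {
  fbv <- numerator / denominator
  data.frame(subject_id = subject_id, fpu = as.integer(fpu),
             modality = modality, fbv = fbv,
             numerator = numerator, denominator = denominator,
             flags = if (fbv < 0 || fbv > 1) "OUT_OF_RANGE" else "",
             stringsAsFactors = FALSE)
}

#' MRI fractional blood volume from placental and IVC relaxometry
#'
#' `FBV = (R1_post - R1_pre)[placenta] / (R1_post - R1_pre)[IVC]`. An IVC
#' rate change at or below `dr1_threshold` means the blood pool did not
#' enhance and is an error; a negative placental change yields an
#' estimate flagged `OUT_OF_RANGE` rather than an error.
#'
#' @param placenta,ivc [relaxometry_pair()]s.
#' @param subject_id,fpu Identifiers carried into the output row.
#' @param dr1_threshold Minimum |IVC rate change|, 1/ms.
#' @return One-row `data.frame` (`subject_id`, `fpu`, `modality`, `fbv`,
#'   `numerator`, `denominator`, `flags`).
#' @export
compute_fbv_mri <- function(placenta, ivc, subject_id = "S01", fpu = 1L,
                            dr1_threshold = DEFAULT_DR1_THRESHOLD) {
  stopifnot(inherits(placenta, "relaxometry_pair"),
            inherits(ivc, "relaxometry_pair"))
  d_ivc <- ivc$r1_post - ivc$r1_pre
  if (abs(d_ivc) <= dr1_threshold) {
    stop("no blood enhancement: |IVC delta-R1| <= ", dr1_threshold, " 1/ms",
         call. = FALSE)
  }
  d_p <- placenta$r1_post - placenta$r1_pre
  fbv_estimate(subject_id, fpu, "MRI", d_p, d_ivc)
}

#' CT fractional blood volume from a pre/post volume pair
#'
#' `FBV = (mean HU_post - mean HU_pre)[placenta] / (same)[IVC]` over the
#' given ROI labels of Hounsfield-calibrated, co-registered volumes.
#'
#' @param pre,post `CT_HU` [image_volume()]s on the same grid.
#' @param mask An [roi_mask()].
#' @param placenta_label,ivc_label Integer labels.
#' @param subject_id,fpu Identifiers carried into the output row.
#' @param dhu_threshold Minimum |IVC enhancement|, HU.
#' @return One-row `data.frame` as in [compute_fbv_mri()].
#' @export
compute_fbv_ct <- function(pre, post, mask, placenta_label, ivc_label,
                           subject_id = "S01", fpu = 1L,
                           dhu_threshold = DEFAULT_DHU_THRESHOLD) {
  stopifnot(identical(pre$modality, "CT_HU"), identical(post$modality, "CT_HU"))
  d_ivc <- roi_mean_signal(post, mask, ivc_label) -
    roi_mean_signal(pre, mask, ivc_label)
  if (abs(d_ivc) <= dhu_threshold) {
    stop("no blood enhancement: |IVC delta-HU| <= ", dhu_threshold, " HU",
         call. = FALSE)
  }
  d_p <- roi_mean_signal(post, mask, placenta_label) -
    roi_mean_signal(pre, mask, placenta_label)
  fbv_estimate(subject_id, fpu, "CT", d_p, d_ivc)
}

#' ROI-mean VFA T1 fits for every compartment of a study
#'
#' For each labeled compartment and contrast state, pools the ROI-mean
#' signal across the flip-angle series and fits T1 by the linearized VFA
#' method (the ROI-mean-then-fit protocol; voxelwise maps are a separate,
#' inspection-only path).
#'
#' @param manifest A [load_manifest()] result.
#' @return `data.frame`: `subject_id`, `label`, `role`, `fpu`,
#'   `contrast_state`, `t1_ms`, `m0`, `r_squared`, `valid`.
#' @export
fit_study_t1 <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  acq <- manifest$acquisition
  mask <- load_mask(manifest)
  lt <- manifest$label_table
  rows <- list()
  for (state in c("PRE", "POST")) {
    sel <- manifest$mr_volumes$contrast_state == state
    sub <- manifest$mr_volumes[sel, ]
    sub <- sub[match(acq$flip_angles_deg, sub$flip_angle_deg), ]
    vols <- lapply(seq_len(nrow(sub)), function(i) {
      read_volume(sub$path[i], modality = "MR_SIGNAL",
                  contrast_state = state,
                  flip_angle_deg = sub$flip_angle_deg[i])
    })
    for (r in seq_len(nrow(lt))) {
      sig <- vapply(vols, roi_mean_signal, numeric(1),
                    mask = mask, label = lt$label[r])
      fit <- fit_t1_vfa(vfa_signal_set(sig, acq))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = manifest$subject_id, label = lt$label[r],
        role = lt$role[r], fpu = lt$fpu[r], contrast_state = state,
        t1_ms = fit$t1_ms, m0 = fit$m0, r_squared = fit$r_squared,
        valid = fit$valid, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the FBV pipeline for one subject
#'
#' MRI arm: ROI-mean VFA T1 fits pre and post contrast for every placenta
#' and the subject's single IVC, then the relaxation-rate ratio per
#' placenta against the shared IVC reference. CT arm (when the manifest
#' lists CT volumes): Hounsfield enhancement ratios over the same ROIs.
#' An invalid IVC fit fails the whole subject, since every placental
#' estimate depends on it.
#'
#' @param manifest A [load_manifest()] result.
#' @param modality `"MRI"`, `"CT"`, or both.
#' @param dr1_threshold,dhu_threshold Enhancement guards, see
#'   [compute_fbv_mri()] / [compute_fbv_ct()].
#' @return `data.frame` of per-placenta estimates, one row per
#'   (placenta, modality), with the subject's gestational age label.
#' @export
run_study <- function(manifest, modality = c("MRI", "CT"),
                      dr1_threshold = DEFAULT_DR1_THRESHOLD,
                      dhu_threshold = DEFAULT_DHU_THRESHOLD) {
  stopifnot(inherits(manifest, "study_manifest"))
  modality <- match.arg(modality, several.ok = TRUE)
  lt <- manifest$label_table
  placentae <- lt[lt$role == "PLACENTA", ]
  ivc_label <- lt$label[lt$role == "IVC"]
  if (nrow(placentae) < 1L) stop("manifest has no placenta labels", call. = FALSE)
  out <- list()

  if ("MRI" %in% modality) {
    fits <- fit_study_t1(manifest)
    get_fit <- function(label, state) {
      fits[fits$label == label & fits$contrast_state == state, ]
    }
    ivc_pre <- get_fit(ivc_label, "PRE"); ivc_post <- get_fit(ivc_label, "POST")
    if (!ivc_pre$valid || !ivc_post$valid) {
      stop("subject ", manifest$subject_id,
           ": IVC T1 fit invalid; cannot form the blood reference",
           call. = FALSE)
    }
    ivc_pair <- relaxometry_pair(ivc_pre$t1_ms, ivc_post$t1_ms, "IVC")
    for (r in seq_len(nrow(placentae))) {
      p_pre <- get_fit(placentae$label[r], "PRE")
      p_post <- get_fit(placentae$label[r], "POST")
      if (!p_pre$valid || !p_post$valid) {
        warning("skipping FPU ", placentae$fpu[r], ": invalid placental fit")
        next
      }
      pair <- relaxometry_pair(p_pre$t1_ms, p_post$t1_ms, "PLACENTA")
      out[[length(out) + 1L]] <- compute_fbv_mri(
        pair, ivc_pair, subject_id = manifest$subject_id,
        fpu = placentae$fpu[r], dr1_threshold = dr1_threshold)
    }
  }

  if ("CT" %in% modality && !is.null(manifest$ct_volumes)) {
    ctv <- manifest$ct_volumes
    pre <- read_volume(ctv$path[ctv$contrast_state == "PRE"],
                       modality = "CT_HU", contrast_state = "PRE")
    post <- read_volume(ctv$path[ctv$contrast_state == "POST"],
                        modality = "CT_HU", contrast_state = "POST")
    mask <- load_mask(manifest)
    for (r in seq_len(nrow(placentae))) {
      out[[length(out) + 1L]] <- compute_fbv_ct(
        pre, post, mask, placentae$label[r], ivc_label,
        subject_id = manifest$subject_id, fpu = placentae$fpu[r],
        dhu_threshold = dhu_threshold)
    }
  }

  res <- do.call(rbind, out)
  res$gestational_age_label <- manifest$gestational_age_label
  res
}

#' Cohort summaries of FBV estimates
#'
#' Mean and sample (n-1) standard deviation of FBV per
#' (group, modality); the SD is `NA` for singleton groups.
#'
#' @param estimates `data.frame` from [run_study()] (rows may be pooled
#'   across subjects).
#' @param group Grouping vector; defaults to the gestational age label
#'   column.
#' @return `data.frame`: `group`, `modality`, `n_fpu`, `mean_fbv`,
#'   `sd_fbv`.
#' @export
summarize_cohort <- function(estimates, group = estimates$gestational_age_label) {
  stopifnot(nrow(estimates) >= 1L, length(group) == nrow(estimates))
  key <- interaction(group, estimates$modality, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    data.frame(group = as.character(group[sel][1]),
               modality = estimates$modality[sel][1],
               n_fpu = sum(sel),
               mean_fbv = mean(estimates$fbv[sel]),
               sd_fbv = if (sum(sel) >= 2L) stats::sd(estimates$fbv[sel])
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent decrease in T1 after contrast
#'
#' `100 * (pre - post) / pre`; a blood-pool agent shortens T1, so typical
#' post-contrast placental decreases are ~30-40% and IVC decreases
#' ~30-55% in late-gestation mouse studies.
#'
#' @param pre_ms,post_ms Positive T1 values, ms.
#' @return Percent change (positive = T1 decreased).
#' @export
percent_t1_change <- function(pre_ms, post_ms) {
  if (any(pre_ms <= 0) || any(post_ms <= 0)) {
    stop("T1 values must be > 0", call. = FALSE)
  }
  100 * (pre_ms - post_ms) / pre_ms
}
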