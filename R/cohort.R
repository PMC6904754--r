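# Cohort-scale simulation: several pregnant subjects, each with her own
# phantom, written to disk as NIfTI volumes plus a JSON manifest and a
# JSON ground-truth file, mirroring how a real study directory would look.

#' Simulate a cohort of pregnant subjects
#'
#' Generates `n_subjects` phantoms, simulates their pre/post-contrast VFA
#' series (and optionally CT pairs), and writes everything under
#' `out_dir/<subject_id>/`: the volumes, the label mask, a `manifest.json`
#' and a `truth.json`. Per-subject seeds are derived deterministically
#' from `seed`, so the whole cohort is reproducible from one integer.
#' FPU counts are drawn uniformly in `n_fpu_range` unless `n_fpu_per_subject`
#' pins them (a typical dam bears 6-10 feto-placental units).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [phantom_config()] template; its `n_fpu` and `seed` are
#'   overridden per subject.
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param gestational_age_label Label stamped into every manifest, e.g.
#'   `"E14.5"`.
#' @param n_fpu_range Integer length-2 range for per-subject FPU draws.
#' @param n_fpu_per_subject Optional integer vector pinning each subject's
#'   FPU count (overrides `n_fpu_range`).
#' @param acq An [acquisition_params()].
#' @param include_ct Also simulate and reference a CT pair.
#' @return List of per-subject lists with `manifest_path`, `manifest`
#'   (loaded [load_manifest()] object) and `truth`.
#' @export
generate_cohort <- function(n_subjects, config, out_dir, seed = 1L,
                            gestational_age_label = "E14.5",
                            n_fpu_range = c(6L, 10L),
                            n_fpu_per_subject = NULL,
                            acq = acquisition_params(),
                            include_ct = TRUE) {
  stopifnot(n_subjects >= 1L, inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- with_seed(seed, list(
    subject_seeds = sample.int(1073741823L, n_subjects),  # headroom for offsets
    n_fpus = if (is.null(n_fpu_per_subject)) {
      sample(seq(n_fpu_range[1], n_fpu_range[2]), n_subjects, replace = TRUE)
    } else {
      as.integer(n_fpu_per_subject)
    }
  ))
  if (length(draws$n_fpus) != n_subjects) {
    stop("n_fpu_per_subject must have length n_subjects", call. = FALSE)
  }

  lapply(seq_len(n_subjects), function(i) {
    subject_id <- sprintf("S%02d", i)
    sdir <- file.path(out_dir, subject_id)
    dir.create(sdir, showWarnings = FALSE)
    cfg <- config
    cfg$n_fpu <- draws$n_fpus[i]
    cfg$seed <- draws$subject_seeds[i]
    if (!is.null(cfg$f)) cfg$f <- rep_len(cfg$f, cfg$n_fpu)
    ph <- build_phantom(cfg)

    mask_path <- file.path(sdir, "mask.nii.gz")
    mask_vol <- image_volume(array(as.numeric(ph$mask$labels),
                                   dim = dim(ph$mask$labels)),
                             cfg$voxel_size_mm, "MR_SIGNAL")
    write_volume(mask_vol, mask_path, sidecar = FALSE)

    mr_entries <- list()
    for (state in c("PRE", "POST")) {
      series <- simulate_vfa_series(ph$mask, ph$truth, acq, state,
                                    noise_model = cfg$noise_model,
                                    snr = cfg$snr,
                                    seed = cfg$seed + match(state, c("PRE", "POST")))
      for (j in seq_along(series)) {
        alpha <- acq$flip_angles_deg[j]
        fn <- sprintf("mr_%s_fa%02d.nii.gz", tolower(state), round(alpha))
        write_volume(series[[j]], file.path(sdir, fn))
        mr_entries[[length(mr_entries) + 1L]] <-
          list(contrast_state = state, flip_angle_deg = alpha, path = fn)
      }
    }

    ct_entries <- NULL
    if (include_ct) {
      ct <- simulate_ct_pair(ph$mask, ph$truth,
                             noise_model = if (cfg$noise_model == "NONE")
                               "NONE" else "GAUSSIAN",
                             noise_hu = cfg$ct_noise_hu,
                             seed = cfg$seed + 10L)
      write_volume(ct$pre, file.path(sdir, "ct_pre.nii.gz"))
      write_volume(ct$post, file.path(sdir, "ct_post.nii.gz"))
      ct_entries <- list(
        list(contrast_state = "PRE", path = "ct_pre.nii.gz"),
        list(contrast_state = "POST", path = "ct_post.nii.gz")
      )
    }

    lt <- ph$mask$label_table
    manifest_doc <- list(
      subject_id = subject_id,
      gestational_age_label = gestational_age_label,
      acquisition = list(tr_ms = acq$tr_ms, te_ms = acq$te_ms,
                         flip_angles_deg = acq$flip_angles_deg),
      mask = "mask.nii.gz",
      labels = lapply(seq_len(nrow(lt)), function(r) {
        out <- list(label = lt$label[r], role = lt$role[r])
        if (!is.na(lt$fpu[r])) out$fpu <- lt$fpu[r]
        out
      }),
      mr_volumes = mr_entries
    )
    if (!is.null(ct_entries)) manifest_doc$ct_volumes <- ct_entries
    manifest_path <- file.path(sdir, "manifest.json")
    write_manifest_json(manifest_doc, manifest_path)

    jsonlite::write_json(
      list(compartments = ph$truth$compartments,
           delta_r1_blood = ph$truth$delta_r1_blood,
           delta_hu_blood = ph$truth$delta_hu_blood,
           f = as.list(ph$truth$f)),
      file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA
    )

    list(manifest_path = manifest_path,
         manifest = load_manifest(manifest_path),
         truth = ph$truth)
  })
}
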