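test_that("relaxation rate is the reciprocal and propagates invalid fits", {
  expect_identical(relaxation_rate(1000), 0.001)
  expect_equal(relaxation_rate(480), 2.08333333333333e-3, tolerance = 1e-12)
  expect_error(relaxation_rate(0), "> 0")

  bad_fit <- fit_t1_vfa(vfa_signal_set(rep(0, 5), acquisition_params()))
  expect_identical(relaxation_rate(bad_fit), NA_real_)
})

test_that("MRI FBV ratio behaves at its anchors and flags out-of-range", {
  ivc <- relaxometry_pair(1020, 690, "IVC")

  # no placental enhancement => 0
  expect_identical(
    compute_fbv_mri(relaxometry_pair(1300, 1300), ivc)$fbv, 0)

  # placenta identical to the IVC => pure blood, 1
  est1 <- compute_fbv_mri(relaxometry_pair(1020, 690), ivc)
  expect_equal(est1$fbv, 1, tolerance = 1e-12)
  expect_identical(est1$flags, "")

  # cohort-mean T1s at E18.5: ratio of means = 0.48736, and notably NOT
  # the per-FPU cohort mean (0.52) - ratio of means != mean of ratios
  est <- compute_fbv_mri(relaxometry_pair(1200, 720),
                         relaxometry_pair(1060, 480, "IVC"))
  expect_equal(est$fbv, 0.48735632183908, tolerance = 1e-12)

  # un-enhancing IVC is an error, not a division blow-up
  expect_error(compute_fbv_mri(relaxometry_pair(1300, 890),
                               relaxometry_pair(1020, 1020, "IVC")),
               "no blood enhancement")

  # negative placental change: flagged estimate, not an error
  neg <- compute_fbv_mri(relaxometry_pair(890, 1300), ivc)
  expect_lt(neg$fbv, 0)
  expect_identical(neg$flags, "OUT_OF_RANGE")

  # monotonicity in placental post-contrast R1
  posts <- seq(1200, 700, by = -50)
  fbvs <- vapply(posts, function(tp)
    compute_fbv_mri(relaxometry_pair(1300, tp), ivc)$fbv, numeric(1))
  expect_true(all(diff(fbvs) > 0))  # lower post T1 = higher R1 = higher FBV
})

test_that("CT FBV ratio recovers mixing fractions and is shift invariant", {
  cfg <- small_config(n_fpu = 2, f = c(0.48, 0.6))
  ph <- build_phantom(cfg)
  ct <- simulate_ct_pair(ph$mask, ph$truth)
  ivc_lab <- ivc_label_of(ph$mask)

  est <- compute_fbv_ct(ct$pre, ct$post, ph$mask, 1L, ivc_lab)
  expect_equal(est$fbv, 0.48, tolerance = 1e-12)

  # amniotic fluid as the "placenta" input: no enhancement, FBV 0
  af_lab <- ph$mask$label_table$label[
    ph$mask$label_table$role == "AMNIOTIC_FLUID"][1]
  expect_equal(compute_fbv_ct(ct$pre, ct$post, ph$mask, af_lab, ivc_lab)$fbv,
               0, tolerance = 1e-12)

  # direct ratio: dHU_P = 50, dHU_IVC = 100 -> 0.5 (synthetic two-ROI grid)
  labs <- array(0L, c(2, 2, 2)); labs[1, 1, 1] <- 1L; labs[2, 1, 1] <- 2L
  m <- roi_mask(labs, c(1, 1, 1),
                data.frame(label = 1:2, role = c("PLACENTA", "IVC"),
                           fpu = c(1L, NA)))
  mk <- function(v1, v2) {
    d <- array(0, c(2, 2, 2)); d[1, 1, 1] <- v1; d[2, 1, 1] <- v2
    image_volume(d, c(1, 1, 1), "CT_HU")
  }
  expect_equal(compute_fbv_ct(mk(10, 20), mk(60, 120), m, 1L, 2L)$fbv, 0.5,
               tolerance = 1e-12)

  # identical HU recalibration shift of both scans leaves FBV unchanged
  shift <- function(vol, s) image_volume(vol$data + s, vol$voxel_size_mm,
                                         "CT_HU")
  est_shift <- compute_fbv_ct(shift(ct$pre, 37), shift(ct$post, 37),
                              ph$mask, 1L, ivc_lab)
  expect_equal(est_shift$fbv, est$fbv, tolerance = 1e-12)

  expect_error(compute_fbv_ct(ct$pre, ct$pre, ph$mask, 1L, ivc_lab),
               "no blood enhancement")
})

test_that("run_study produces one estimate per placenta off a shared IVC", {
  td <- withr::local_tempdir()
  f_true <- c(0.42, 0.5, 0.55, 0.61)
  cfg <- small_config(n_fpu = 4, f = f_true, seed = 13)
  sub <- generate_cohort(1, cfg, td, seed = 8,
                         n_fpu_per_subject = 4L)[[1]]
  est <- run_study(sub$manifest)

  mri <- est[est$modality == "MRI", ]
  ct <- est[est$modality == "CT", ]
  expect_identical(nrow(mri), 4L)
  expect_identical(nrow(ct), 4L)
  # all placentae share the subject's single IVC denominator
  expect_identical(length(unique(mri$denominator)), 1L)

  truth_f <- unname(sub$truth$f)
  expect_equal(mri$fbv[order(mri$fpu)], truth_f, tolerance = 1e-9)
  expect_equal(ct$fbv[order(ct$fpu)], truth_f, tolerance = 1e-9)
  # the two modalities agree on the noiseless phantom
  expect_equal(mri$fbv[order(mri$fpu)], ct$fbv[order(ct$fpu)],
               tolerance = 1e-9)
})

test_that("cohort summaries use sample SD and handle singletons", {
  est <- data.frame(subject_id = "S01", fpu = 1:3, modality = "MRI",
                    fbv = c(0.4, 0.5, 0.6), numerator = 1, denominator = 2,
                    flags = "", gestational_age_label = "E14.5")
  s <- summarize_cohort(est)
  expect_equal(s$mean_fbv, 0.5)
  expect_equal(s$sd_fbv, 0.1, tolerance = 1e-12)
  expect_identical(s$n_fpu, 3L)

  s1 <- summarize_cohort(est[1, ])
  expect_equal(s1$mean_fbv, 0.4)
  expect_true(is.na(s1$sd_fbv))
})

test_that("percent T1 decreases match the reported gestational ranges", {
  expect_equal(percent_t1_change(1300, 890), 31.5384615384615,
               tolerance = 1e-10)
  expect_equal(percent_t1_change(1060, 480), 54.7169811320755,
               tolerance = 1e-10)
  expect_identical(percent_t1_change(1000, 1000), 0)
  expect_error(percent_t1_change(0, 500), "> 0")

  ref <- gestation_reference()
  pl <- percent_t1_change(ref$placenta_t1_pre, ref$placenta_t1_post)
  ivc <- percent_t1_change(ref$ivc_t1_pre, ref$ivc_t1_post)
  expect_true(all(pl >= 30 & pl <= 40))
  expect_true(all(ivc >= 30 & ivc <= 55))
})
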