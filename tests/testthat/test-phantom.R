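test_that("linear-mixing rate model behaves at its anchors", {
  # f = 0: no enhancement; f = 1: full blood enhancement
  expect_identical(post_contrast_tissue_r1(1 / 1300, 0, 123), 1 / 1300)
  expect_equal(post_contrast_tissue_r1(1 / 1300, 1, 0.01), 1 / 1300 + 0.01,
               tolerance = 1e-15)

  # hand evaluation with late-gestation blood T1s (1020 -> 690 ms), f = 0.47
  r1_post <- post_contrast_tissue_r1(1 / 1300, 0.47, 1 / 690 - 1 / 1020)
  expect_equal(r1_post, 9.89605875795134e-4, tolerance = 1e-12)
  expect_equal(1 / r1_post, 1010.50329677612, tolerance = 1e-8)

  expect_error(post_contrast_tissue_r1(-1, 0.5, 0.1), "r1_pre")
  expect_error(post_contrast_tissue_r1(1 / 1300, 1.2, 0.1), "\\[0, 1\\]")
  expect_error(post_contrast_tissue_r1(1 / 1300, 0.5, -0.1), "delta_r1_blood")
})

test_that("phantom construction honours counting, determinism and fit checks", {
  cfg <- small_config(n_fpu = 8, f = 0.5)
  ph <- build_phantom(cfg)
  lt <- ph$mask$label_table
  expect_identical(sum(lt$role == "PLACENTA"), 8L)
  expect_identical(sum(lt$role == "AMNIOTIC_FLUID"), 8L)
  expect_identical(sum(lt$role == "IVC"), 1L)

  # voxel-count contracts
  counts <- table(ph$mask$labels)
  for (lab in lt$label[lt$role == "PLACENTA"]) {
    expect_gte(counts[[as.character(lab)]], 50L)
  }
  expect_gte(counts[[as.character(ivc_label_of(ph$mask))]], 30L)

  # same config + seed => identical labels and truth
  ph2 <- build_phantom(cfg)
  expect_identical(ph2$mask$labels, ph$mask$labels)
  expect_identical(ph2$truth$compartments, ph$truth$compartments)

  # different seed with drawn f => different fractions
  cfga <- small_config(n_fpu = 4, f = NULL, seed = 1)
  cfgb <- small_config(n_fpu = 4, f = NULL, seed = 2)
  expect_false(identical(build_phantom(cfga)$truth$f,
                         build_phantom(cfgb)$truth$f))

  # geometry that cannot fit raises, not corrupts
  tiny <- phantom_config(grid_shape = c(16, 16, 16),
                         voxel_size_mm = rep(0.5, 3), n_fpu = 8, f = 0.5)
  expect_error(build_phantom(tiny), "does not fit")
})

test_that("generator and ratio estimator are mutual inverses on true values", {
  # conservation: recomputing dR1_P/dR1_IVC from the truth returns f exactly
  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    cfg <- small_config(n_fpu = n, f = runif(n), seed = i)
    truth <- build_phantom(cfg)$truth
    comp <- truth$compartments
    ivc <- comp[comp$role == "IVC", ]
    d_ivc <- 1 / ivc$t1_post_ms - 1 / ivc$t1_pre_ms
    pl <- comp[comp$role == "PLACENTA", ]
    f_rec <- (1 / pl$t1_post_ms - 1 / pl$t1_pre_ms) / d_ivc
    expect_equal(f_rec, unname(truth$f), tolerance = 1e-12)
    # CT mixing conserves f identically
    f_ct <- (pl$hu_post - pl$hu_pre) / (ivc$hu_post - ivc$hu_pre)
    expect_equal(f_ct, unname(truth$f), tolerance = 1e-12)
  }
})

test_that("amniotic fluid never enhances in either modality", {
  cfg <- small_config(n_fpu = 3, f = c(0.4, 0.5, 0.6))
  ph <- build_phantom(cfg)
  af <- ph$truth$compartments[ph$truth$compartments$role == "AMNIOTIC_FLUID", ]
  expect_identical(af$t1_pre_ms, af$t1_post_ms)
  expect_identical(af$hu_pre, af$hu_post)

  pre <- simulate_vfa_series(ph$mask, ph$truth, state = "PRE")
  post <- simulate_vfa_series(ph$mask, ph$truth, state = "POST")
  af_vox <- ph$mask$labels %in% af$label
  for (j in seq_along(pre)) {
    expect_identical(pre[[j]]$data[af_vox], post[[j]]$data[af_vox])
  }
  ct <- simulate_ct_pair(ph$mask, ph$truth)
  expect_identical(ct$pre$data[af_vox], ct$post$data[af_vox])
})

test_that("VFA simulation is seeded, reproducible and noise-calibrated", {
  cfg <- small_config(n_fpu = 2, f = 0.5)
  ph <- build_phantom(cfg)

  a <- simulate_vfa_series(ph$mask, ph$truth, noise_model = "GAUSSIAN",
                           snr = 50, seed = 123)
  b <- simulate_vfa_series(ph$mask, ph$truth, noise_model = "GAUSSIAN",
                           snr = 50, seed = 123)
  expect_identical(a[[3]]$data, b[[3]]$data)
  c2 <- simulate_vfa_series(ph$mask, ph$truth, noise_model = "GAUSSIAN",
                            snr = 50, seed = 124)
  expect_false(identical(a[[3]]$data, c2[[3]]$data))

  # Gaussian noise: large-region mean converges to the noiseless value
  clean <- simulate_vfa_series(ph$mask, ph$truth, seed = 1)
  bg <- ph$mask$labels == max(ph$mask$label_table$label)  # background label
  n_bg <- sum(bg)
  noiseless_mean <- mean(clean[[1]]$data[bg])
  sd_n <- stats::sd(a[[1]]$data[bg] - clean[[1]]$data[bg])
  expect_lt(abs(mean(a[[1]]$data[bg]) - noiseless_mean),
            5 * sd_n / sqrt(n_bg))

  # Rician magnitudes are non-negative and biased upward where signal ~ 0
  r <- simulate_vfa_series(ph$mask, ph$truth, noise_model = "RICIAN",
                           snr = 50, seed = 9)
  expect_true(all(r[[1]]$data >= 0))
  expect_gt(mean(r[[1]]$data[ph$mask$labels == 0L]), 0)
})

test_that("CT pair obeys linear mixing with the IVC as the f = 1 reference", {
  cfg <- small_config(n_fpu = 2, f = c(0.5, 0.48))
  ph <- build_phantom(cfg)
  ct <- simulate_ct_pair(ph$mask, ph$truth)
  blood_enh <- cfg$compartments$blood$hu_post - cfg$compartments$blood$hu_pre
  expect_identical(blood_enh, 500)

  pl1 <- ph$mask$labels == 1L
  expect_equal(unique(ct$post$data[pl1] - ct$pre$data[pl1]), 0.5 * 500,
               tolerance = 1e-12)
  ivc <- ph$mask$labels == ivc_label_of(ph$mask)
  expect_equal(unique(ct$post$data[ivc] - ct$pre$data[ivc]), 500,
               tolerance = 1e-12)
})

test_that("cohorts are reproducible and draw realistic litter sizes", {
  td <- withr::local_tempdir()
  cfg <- small_config(n_fpu = 2, f = NULL)
  coh <- generate_cohort(3, cfg, file.path(td, "a"), seed = 21,
                         include_ct = FALSE)
  n_fpus <- vapply(coh, function(s) length(s$truth$f), integer(1))
  expect_true(all(n_fpus >= 6 & n_fpus <= 10))
  expect_true(sum(n_fpus) >= 18 && sum(n_fpus) <= 30)

  coh2 <- generate_cohort(3, cfg, file.path(td, "b"), seed = 21,
                          include_ct = FALSE)
  expect_identical(lapply(coh, function(s) s$truth$f),
                   lapply(coh2, function(s) s$truth$f))

  one <- generate_cohort(1, cfg, file.path(td, "c"), seed = 4,
                         n_fpu_per_subject = 6L, include_ct = FALSE)
  expect_length(one, 1L)
  expect_true(file.exists(one[[1]]$manifest_path))
  expect_true(file.exists(file.path(dirname(one[[1]]$manifest_path),
                                    "truth.json")))
})
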