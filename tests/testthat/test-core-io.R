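test_that("NIfTI round trip preserves voxels, geometry and metadata", {
  td <- withr::local_tempdir()

  # constant volume, bit-exact data and header geometry
  v <- image_volume(array(7.0, c(8, 8, 8)), c(0.5, 0.5, 0.5), "MR_SIGNAL",
                    contrast_state = "PRE", flip_angle_deg = 25)
  p <- file.path(td, "const.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(v2$data, v$data)
  expect_equal(v2$voxel_size_mm, c(0.5, 0.5, 0.5), tolerance = 1e-6)
  expect_identical(v2$modality, "MR_SIGNAL")
  expect_identical(v2$contrast_state, "PRE")
  expect_equal(v2$flip_angle_deg, 25)

  # arbitrary doubles survive bit-exactly (float64 storage)
  set.seed(1)
  w <- image_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), c(0.5, 0.75, 1),
                    "CT_HU")
  pw <- file.path(td, "rand.nii")
  write_volume(w, pw)
  w2 <- read_volume(pw)
  expect_identical(w2$data, w$data)

  # T1 map sentinel voxels round-trip the marker
  t1 <- array(1000, c(4, 4, 4)); t1[1, 1, 1] <- T1_INVALID
  m <- image_volume(t1, c(1, 1, 1), "T1_MAP")
  pm <- file.path(td, "map.nii.gz")
  write_volume(m, pm)
  expect_identical(read_volume(pm)$data, t1)
})

test_that("reader rejects non-3D files, missing files, bad headers", {
  td <- withr::local_tempdir()
  expect_error(read_volume(file.path(td, "nope.nii")), "not found")

  # patch a valid file's header to claim 4D
  p <- file.path(td, "vol.nii")
  write_volume(image_volume(array(1, c(4, 4, 4)), c(1, 1, 1), "MR_SIGNAL"), p)
  bytes <- readBin(p, "raw", file.size(p))
  bytes[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")[1:2]  # dim[0]
  bytes[49:50] <- writeBin(2L, raw(), size = 2, endian = "little")[1:2]  # dim[4]
  writeBin(bytes, file.path(td, "vol4d.nii"))
  expect_error(read_volume(file.path(td, "vol4d.nii"), modality = "MR_SIGNAL"),
               "expected 3D")

  # garbage magic
  writeBin(as.raw(rep_len(seq_len(200), 400)), file.path(td, "junk.nii"))
  expect_error(read_volume(file.path(td, "junk.nii"), modality = "MR_SIGNAL"),
               "not a NIfTI")
})

test_that("phantom-generated volumes carry the configured geometry", {
  td <- withr::local_tempdir()
  cfg <- small_config(n_fpu = 1, f = 0.5)
  ph <- build_phantom(cfg)
  series <- simulate_vfa_series(ph$mask, ph$truth)
  p <- file.path(td, "fa08.nii.gz")
  write_volume(series[[1]], p)
  expect_equal(read_volume(p)$voxel_size_mm, cfg$voxel_size_mm,
               tolerance = 1e-6)
})

test_that("manifest validation is eager and names the failure", {
  td <- withr::local_tempdir()
  cfg <- small_config(n_fpu = 2, f = 0.5)
  sub <- generate_cohort(1, cfg, td, seed = 5, include_ct = FALSE)[[1]]

  man <- sub$manifest
  expect_s3_class(man, "study_manifest")
  expect_identical(sort(unique(man$mr_volumes$flip_angle_deg)),
                   c(8, 15, 25, 35, 45))
  expect_identical(nrow(man$mr_volumes), 10L)  # 5 angles x 2 states

  doc <- jsonlite::read_json(sub$manifest_path, simplifyVector = FALSE)

  # single flip angle violates the acquisition invariant
  doc1 <- doc
  doc1$acquisition$flip_angles_deg <- list(25)
  p1 <- file.path(td, "one_angle.json")
  jsonlite::write_json(doc1, p1, auto_unbox = TRUE)
  expect_error(load_manifest(p1), "2 flip angles")

  # dangling volume path is named in the error
  doc2 <- doc
  doc2$mr_volumes[[1]]$path <- "missing_file.nii.gz"
  p2 <- file.path(td, "S01", "dangling.json")
  jsonlite::write_json(doc2, p2, auto_unbox = TRUE)
  expect_error(load_manifest(p2), "missing_file.nii.gz")

  # flip angles in volume list must match the acquisition list
  doc3 <- doc
  doc3$mr_volumes[[1]]$flip_angle_deg <- 12
  p3 <- file.path(td, "S01", "mismatch.json")
  jsonlite::write_json(doc3, p3, auto_unbox = TRUE)
  expect_error(load_manifest(p3), "do not match")

  # missing required key
  doc4 <- doc
  doc4$mask <- NULL
  p4 <- file.path(td, "S01", "nokey.json")
  jsonlite::write_json(doc4, p4, auto_unbox = TRUE)
  expect_error(load_manifest(p4), "mask")
})

test_that("write_table emits deterministic full-precision CSV", {
  td <- withr::local_tempdir()
  rows <- data.frame(subject = "S01", fpu = 1:2, modality = "MRI",
                     fbv = c(0.487361612345678, 1 / 3))
  p <- file.path(td, "fbv.csv")
  write_table(rows, p)
  back <- utils::read.csv(p)
  expect_identical(names(back), c("subject", "fpu", "modality", "fbv"))
  # >= 12 significant digits survive the round trip
  expect_equal(back$fbv, rows$fbv, tolerance = 1e-12)

  # zero-row frame gives a header-only file
  p0 <- file.path(td, "empty.csv")
  write_table(rows[0, ], p0)
  expect_identical(readLines(p0), "\"subject\",\"fpu\",\"modality\",\"fbv\"")

  # byte-identical on re-write
  p2 <- file.path(td, "fbv2.csv")
  write_table(rows, p2)
  expect_identical(readLines(p), readLines(p2))
})
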