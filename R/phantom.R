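# Multi-compartment digital phantom of the pregnant mouse abdomen.
#
# Geometry is deliberately parametric, not anatomical: feto-placental
# units (FPU) sit on a ring inside a maternal-tissue body ellipsoid, each
# an amniotic-fluid sac capped radially outward by an ellipsoidal
# placenta; a ~2 mm diameter cylinder through the body center stands in
# for the inferior vena cava (IVC). ROI statistics, not anatomy, drive
# the downstream analysis.
#
# Contrast enhancement follows fast-exchange linear mixing: a tissue
# compartment holding blood fraction f gains f times the blood R1 (or HU)
# change. This is the unique tissue model under which the ratio
# estimators dR1_P/dR1_IVC and dHU_P/dHU_IVC are exactly unbiased, so
# noiseless round trips recover f to machine precision.

#' Phantom configuration
#'
#' Defaults state the imaging world of a late-gestation pregnant-mouse
#' study at 1 T: a 96^3 grid of 0.5 mm isotropic voxels, 8 FPUs, blood
#' (IVC) T1 of 1020 ms pre-contrast shortened to 690 ms by a blood-pool
#' agent, placental T1 of 1300 ms pre-contrast, and per-placenta blood
#' fractions near 0.5. CT attenuation uses a 500 HU blood enhancement.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_size_mm Numeric length-3, mm.
#' @param n_fpu Number of feto-placental units (1-10 fit the default grid).
#' @param f Per-placenta blood volume fractions in `[0, 1]`; either length
#'   `n_fpu` or length 1 (recycled). `NULL` draws from
#'   `Normal(f_mean, f_sd)` truncated to `[0, 1]`.
#' @param f_mean,f_sd Parameters of the blood-fraction draw when `f` is
#'   `NULL`.
#' @param compartments Named list of tissue properties; see Details.
#' @param noise_model `"NONE"`, `"GAUSSIAN"` or `"RICIAN"`.
#' @param snr Signal-to-noise ratio; the MR noise sd is
#'   (max noiseless pre-contrast signal)/snr.
#' @param ct_noise_hu Additive Gaussian sd for CT volumes, HU.
#' @param seed Integer seed driving every random element.
#'
#' @details `compartments` carries, per compartment:
#' * `placenta`: `t1_ms`, `t2_ms`, `m0`, `hu` (pre-contrast; post-contrast
#'   values follow from linear mixing with the per-placenta `f`),
#' * `amniotic_fluid`: `t1_ms`, `t2_ms`, `m0`, `hu` (never enhances),
#' * `background`: `t1_ms`, `t2_ms`, `m0`, `hu` (maternal tissue, f = 0),
#' * `blood`: `t1_pre_ms`, `t1_post_ms`, `t2_ms`, `m0`, `hu_pre`,
#'   `hu_post` (the IVC is pure blood, f = 1).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 96),
                           voxel_size_mm = c(0.5, 0.5, 0.5),
                           n_fpu = 8,
                           f = NULL, f_mean = 0.5, f_sd = 0.05,
                           compartments = default_compartments(),
                           noise_model = c("NONE", "GAUSSIAN", "RICIAN"),
                           snr = 50, ct_noise_hu = 5,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            n_fpu >= 1L)
  if (!is.null(f)) {
    f <- as.numeric(f)
    if (length(f) == 1L) f <- rep(f, n_fpu)
    if (length(f) != n_fpu) stop("f must have length n_fpu", call. = FALSE)
    if (any(f < 0 | f > 1)) stop("blood fractions must lie in [0, 1]", call. = FALSE)
  }
  for (cp in c("placenta", "amniotic_fluid", "background")) {
    p <- compartments[[cp]]
    if (p$t1_ms <= 0 || p$t2_ms <= 0) stop("T1 and T2 must be > 0", call. = FALSE)
  }
  b <- compartments$blood
  if (b$t1_pre_ms <= 0 || b$t1_post_ms <= 0 || b$t2_ms <= 0) {
    stop("blood T1/T2 must be > 0", call. = FALSE)
  }
  if (noise_model != "NONE" && snr <= 0) stop("snr must be > 0", call. = FALSE)
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         n_fpu = as.integer(n_fpu), f = f, f_mean = f_mean, f_sd = f_sd,
         compartments = compartments, noise_model = noise_model, snr = snr,
         ct_noise_hu = ct_noise_hu, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Default phantom tissue properties
#'
#' Pre-contrast T1s follow published late-gestation mouse values at 1 T
#' (placenta ~1300 ms, maternal blood ~1020 ms shortened to ~690 ms by a
#' liposomal blood-pool agent); T2 defaults are 50 ms for tissue and
#' 100 ms for blood so the TE << T2 fitting assumption is exercised as an
#' approximation when simulating with the full signal equation. CT blood
#' enhancement defaults to 500 HU, typical of liposomal-iodine micro-CT.
#' @return Named list of compartment property lists.
#' @export
default_compartments <- function() {
  list(
    placenta = list(t1_ms = 1300, t2_ms = 50, m0 = 1000, hu = 55),
    amniotic_fluid = list(t1_ms = 2500, t2_ms = 200, m0 = 1000, hu = 15),
    background = list(t1_ms = 900, t2_ms = 50, m0 = 800, hu = 40),
    blood = list(t1_pre_ms = 1020, t1_post_ms = 690, t2_ms = 100, m0 = 900,
                 hu_pre = 60, hu_post = 560)
  )
}

#' Post-contrast tissue relaxation rate under linear mixing
#'
#' A tissue compartment holding blood volume fraction `f` enhances by `f`
#' times the blood relaxation-rate change (fast exchange):
#' `R1_post = R1_pre + f * dR1_blood`.
#'
#' @param r1_pre Pre-contrast tissue R1, 1/ms (> 0).
#' @param f Blood volume fraction in `[0, 1]`.
#' @param delta_r1_blood Blood R1 change, 1/ms (>= 0).
#' @return Post-contrast tissue R1, 1/ms.
#' @export
post_contrast_tissue_r1 <- function(r1_pre, f, delta_r1_blood) {
  if (any(r1_pre <= 0)) stop("r1_pre must be > 0", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  if (any(delta_r1_blood < 0)) stop("delta_r1_blood must be >= 0", call. = FALSE)
  r1_pre + f * delta_r1_blood
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# voxel-center coordinates (mm) about the grid center, per axis
axis_coords <- function(n, vox) (seq_len(n) - (n + 1) / 2) * vox

# logical array: voxels inside an axis-aligned ellipsoid
ellipsoid_inside <- function(coords, center, semi) {
  dx2 <- ((coords$x - center[1]) / semi[1])^2
  dy2 <- ((coords$y - center[2]) / semi[2])^2
  dz2 <- ((coords$z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Build a digital pregnant-abdomen phantom
#'
#' Lays out `n_fpu` feto-placental units (amniotic-fluid sac capped by an
#' ellipsoidal placenta) on a ring inside a maternal body ellipsoid, with
#' a ~2 mm diameter IVC cylinder through the center, and records every
#' compartment's true pre/post-contrast properties. Deterministic given
#' `config$seed`; per-placenta blood fractions are drawn here if not
#' fixed in the config. Fails if the requested geometry does not fit the
#' grid without overlap, if any placenta gets fewer than 50 voxels, or if
#' the IVC gets fewer than 30.
#'
#' @param config A [phantom_config()].
#' @return List with elements `mask` ([roi_mask()]) and `truth`
#'   (`phantom_ground_truth`: `data.frame` `compartments` of per-label
#'   true properties plus the scalar blood deltas).
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, build_phantom_impl(config))
}

build_phantom_impl <- function(config) {
  shp <- config$grid_shape
  vox <- config$voxel_size_mm
  n_fpu <- config$n_fpu
  coords <- list(x = axis_coords(shp[1], vox[1]),
                 y = axis_coords(shp[2], vox[2]),
                 z = axis_coords(shp[3], vox[3]))
  half_extent <- shp * vox / 2

  f <- config$f
  if (is.null(f)) {
    f <- stats::rnorm(n_fpu, config$f_mean, config$f_sd)
    f <- pmin(pmax(f, 0), 1)
  }

  labels <- array(0L, dim = shp)
  # maternal body: ellipsoid filling most of the grid
  body_semi <- 0.96 * half_extent
  bg_label <- 2L * n_fpu + 2L
  inside_body <- ellipsoid_inside(coords, c(0, 0, 0), body_semi)
  labels[inside_body] <- bg_label

  # IVC: cylinder of radius 1 mm along z through the body center
  ivc_label <- 2L * n_fpu + 1L
  r2 <- outer((coords$x / 1)^2, (coords$y / 1)^2, `+`)
  ivc_xy <- r2 <= 1
  zspan <- abs(coords$z) <= 0.85 * half_extent[3]
  ivc_vox <- outer(ivc_xy, zspan, `&`)
  labels[ivc_vox] <- ivc_label

  # FPU ring: radius scaled to the grid so smaller test grids still fit
  ring_r <- 0.58 * min(half_extent[1:2])
  af_semi0 <- c(2.8, 2.8, 3.2) * min(half_extent) / 24
  pl_semi0 <- c(2.2, 2.2, 1.4) * min(half_extent) / 24
  occupied <- ivc_vox
  rows <- list()
  for (i in seq_len(n_fpu)) {
    theta <- 2 * pi * (i - 1) / n_fpu
    jit <- stats::runif(2, -0.05, 0.05)      # mild size jitter, seeded
    af_semi <- af_semi0 * (1 + jit[1])
    pl_semi <- pl_semi0 * (1 + jit[2])
    dirv <- c(cos(theta), sin(theta), 0)
    af_center <- ring_r * dirv
    pl_center <- (ring_r + af_semi[1] + pl_semi[1] + 0.4) * dirv
    af_in <- ellipsoid_inside(coords, af_center, af_semi)
    pl_in <- ellipsoid_inside(coords, pl_center, pl_semi)
    if (any(af_in & occupied) || any(pl_in & occupied) || any(af_in & pl_in)) {
      stop("phantom geometry does not fit grid (compartment overlap)",
           call. = FALSE)
    }
    pl_label <- i
    af_label <- n_fpu + i
    labels[af_in] <- af_label
    labels[pl_in] <- pl_label
    occupied <- occupied | af_in | pl_in
    if (sum(pl_in) < 50L) {
      stop("phantom geometry does not fit grid (placenta ", i,
           " has ", sum(pl_in), " voxels, need >= 50)", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = pl_label, role = "PLACENTA", fpu = i)
    rows[[length(rows) + 1L]] <- data.frame(
      label = af_label, role = "AMNIOTIC_FLUID", fpu = i)
  }
  if (sum(ivc_vox) < 30L) {
    stop("phantom geometry does not fit grid (IVC has ", sum(ivc_vox),
         " voxels, need >= 30)", call. = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(label = ivc_label, role = "IVC",
                                          fpu = NA_integer_)
  rows[[length(rows) + 1L]] <- data.frame(label = bg_label, role = "BACKGROUND",
                                          fpu = NA_integer_)
  label_table <- do.call(rbind, rows)
  mask <- roi_mask(labels, vox, label_table)

  cp <- config$compartments
  b <- cp$blood
  delta_r1_blood <- 1 / b$t1_post_ms - 1 / b$t1_pre_ms
  delta_hu_blood <- b$hu_post - b$hu_pre
  mk <- function(label, role, fpu, t1_pre, t2, m0, hu_pre, fval) {
    t1_post <- 1 / post_contrast_tissue_r1(1 / t1_pre, fval, delta_r1_blood)
    data.frame(label = label, role = role, fpu = fpu, f = fval,
               t1_pre_ms = t1_pre, t1_post_ms = t1_post, t2_ms = t2, m0 = m0,
               hu_pre = hu_pre, hu_post = hu_pre + fval * delta_hu_blood)
  }
  comp <- rbind(
    do.call(rbind, lapply(seq_len(n_fpu), function(i) {
      mk(i, "PLACENTA", i, cp$placenta$t1_ms, cp$placenta$t2_ms,
         cp$placenta$m0, cp$placenta$hu, f[i])
    })),
    do.call(rbind, lapply(seq_len(n_fpu), function(i) {
      mk(n_fpu + i, "AMNIOTIC_FLUID", i, cp$amniotic_fluid$t1_ms,
         cp$amniotic_fluid$t2_ms, cp$amniotic_fluid$m0,
         cp$amniotic_fluid$hu, 0)
    })),
    mk(ivc_label, "IVC", NA_integer_, b$t1_pre_ms, b$t2_ms, b$m0, b$hu_pre, 1),
    mk(bg_label, "BACKGROUND", NA_integer_, cp$background$t1_ms,
       cp$background$t2_ms, cp$background$m0, cp$background$hu, 0)
  )
  truth <- structure(
    list(compartments = comp,
         delta_r1_blood = delta_r1_blood,
         delta_hu_blood = delta_hu_blood,
         f = stats::setNames(f, seq_len(n_fpu))),
    class = "phantom_ground_truth"
  )
  list(mask = mask, truth = truth)
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf("<phantom_ground_truth> %d compartments, %d placentae, f = [%s]\n",
              nrow(x$compartments), length(x$f),
              paste(sprintf("%.3f", x$f), collapse = ", ")))
  invisible(x)
}

# per-label scalar field -> full grid; unlabeled voxels get `fill`
label_field <- function(mask, values_by_label, fill = 0) {
  out <- array(fill, dim = dim(mask$labels))
  for (i in seq_along(values_by_label)) {
    lab <- as.integer(names(values_by_label)[i])
    out[mask$labels == lab] <- values_by_label[i]
  }
  out
}

truth_column <- function(truth, state, which = c("t1", "hu")) {
  which <- match.arg(which)
  col <- paste0(which, if (state == "PRE") "_pre" else "_post",
                if (which == "t1") "_ms" else "")
  stats::setNames(truth$compartments[[col]], truth$compartments$label)
}

# sd of the Gaussian MR noise: peak noiseless PRE-contrast signal over snr
mr_noise_sd <- function(mask, truth, acq, snr, use_t2 = TRUE) {
  comp <- truth$compartments
  peak <- 0
  for (i in seq_len(nrow(comp))) {
    s <- gre_signal(comp$m0[i], comp$t1_pre_ms[i], acq$flip_angles_deg, acq,
                    t2_ms = if (use_t2) comp$t2_ms[i] else NULL)
    peak <- max(peak, s)
  }
  peak / snr
}

#' Simulate a variable-flip-angle spoiled-GRE series
#'
#' Evaluates the spoiled-GRE signal equation in every voxel for each flip
#' angle, using the compartment properties of the requested contrast
#' state, then adds seeded noise. By default the full signal equation
#' including the `exp(-TE/T2)` factor is used, so downstream fitting under
#' the TE << T2 simplification sees it as an approximation. Gaussian
#' noise has sd `(max noiseless pre-contrast signal)/snr`; Rician noise
#' applies that sd to both quadrature channels of a magnitude image.
#'
#' @param mask An [roi_mask()] from [build_phantom()].
#' @param truth Matching `phantom_ground_truth`.
#' @param acq An [acquisition_params()].
#' @param state `"PRE"` or `"POST"`.
#' @param noise_model `"NONE"`, `"GAUSSIAN"` or `"RICIAN"`.
#' @param snr Signal-to-noise ratio when noise is added.
#' @param seed Integer seed for the noise draw.
#' @param use_t2 Apply the T2 decay factor (default `TRUE`).
#' @return List of `MR_SIGNAL` [image_volume()]s, one per flip angle.
#' @export
simulate_vfa_series <- function(mask, truth, acq = acquisition_params(),
                                state = c("PRE", "POST"),
                                noise_model = "NONE", snr = 50, seed = 1L,
                                use_t2 = TRUE) {
  state <- match.arg(state)
  stopifnot(inherits(mask, "roi_mask"))
  comp <- truth$compartments
  present <- setdiff(unique(as.vector(mask$labels)), 0L)
  if (length(setdiff(present, comp$label))) {
    stop("mask contains labels without ground-truth properties", call. = FALSE)
  }
  t1s <- truth_column(truth, state, "t1")
  sd_noise <- if (noise_model == "NONE") 0 else
    mr_noise_sd(mask, truth, acq, snr, use_t2)
  vols <- vector("list", length(acq$flip_angles_deg))
  with_seed(seed, {
    for (j in seq_along(acq$flip_angles_deg)) {
      alpha <- acq$flip_angles_deg[j]
      per_label <- vapply(seq_len(nrow(comp)), function(i) {
        gre_signal(comp$m0[i], t1s[[as.character(comp$label[i])]], alpha, acq,
                   t2_ms = if (use_t2) comp$t2_ms[i] else NULL)
      }, numeric(1))
      names(per_label) <- comp$label
      img <- label_field(mask, per_label, fill = 0)
      if (noise_model == "GAUSSIAN") {
        img <- img + array(stats::rnorm(length(img), 0, sd_noise), dim = dim(img))
      } else if (noise_model == "RICIAN") {
        n1 <- array(stats::rnorm(length(img), 0, sd_noise), dim = dim(img))
        n2 <- array(stats::rnorm(length(img), 0, sd_noise), dim = dim(img))
        img <- sqrt((img + n1)^2 + n2^2)
      }
      vols[[j]] <- image_volume(img, mask$voxel_size_mm, "MR_SIGNAL",
                                contrast_state = state,
                                flip_angle_deg = alpha)
    }
  })
  vols
}

#' Simulate a pre/post-contrast CT pair
#'
#' Voxel values are compartment Hounsfield units; post-contrast placental
#' HU follows linear mixing (`hu_pre + f * blood enhancement`), amniotic
#' fluid and maternal background are unchanged, the IVC enhances by the
#' full blood enhancement, and unlabeled voxels are air (-1000 HU).
#'
#' @inheritParams simulate_vfa_series
#' @param noise_model `"NONE"` or `"GAUSSIAN"`.
#' @param noise_hu Gaussian sd in HU when noise is added.
#' @return List with `pre` and `post` `CT_HU` [image_volume()]s.
#' @export
simulate_ct_pair <- function(mask, truth, noise_model = "NONE",
                             noise_hu = 5, seed = 1L) {
  stopifnot(inherits(mask, "roi_mask"))
  comp <- truth$compartments
  if (any(is.na(comp$hu_pre)) || any(is.na(comp$hu_post))) {
    stop("ground truth lacks HU properties", call. = FALSE)
  }
  make <- function(state, seed_off) {
    hus <- truth_column(truth, state, "hu")
    img <- label_field(mask, hus, fill = -1000)
    if (noise_model == "GAUSSIAN") {
      img <- with_seed(seed + seed_off, {
        img + array(stats::rnorm(length(img), 0, noise_hu), dim = dim(img))
      })
    }
    image_volume(img, mask$voxel_size_mm, "CT_HU", contrast_state = state)
  }
  list(pre = make("PRE", 0L), post = make("POST", 1L))
}
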