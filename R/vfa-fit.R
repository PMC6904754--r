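# Variable flip angle (VFA / DESPOT1) T1 estimation.
#
# The spoiled-GRE signal at fixed TR and varying flip angle linearizes as
#   S/sin(a) = (S/tan(a)) * E1 + M0 (1 - E1),   E1 = e^(-TR/T1),
# so an ordinary least-squares line through the points
# (x, y) = (S/tan a, S/sin a) yields E1 as the slope and M0 from the
# intercept. The fit is unweighted, exactly as the ROI-mean protocol
# prescribes; no B1 correction is applied (flip angles are nominal).

T1_VALID_RANGE_MS <- c(1, 10000)

#' Bundle VFA signals with their acquisition
#'
#' @param signals Non-negative signal per flip angle (ROI means or a
#'   single voxel's values), ordered as `acq$flip_angles_deg`.
#' @param acq An [acquisition_params()].
#' @return An object of class `vfa_signal_set`.
#' @export
vfa_signal_set <- function(signals, acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  signals <- as.numeric(signals)
  if (length(signals) != length(acq$flip_angles_deg)) {
    stop("signals and flip angles differ in length", call. = FALSE)
  }
  if (length(signals) < 2L) stop(">= 2 flip angles required", call. = FALSE)
  if (any(!is.finite(signals)) || any(signals < 0)) {
    stop("signals must be finite and >= 0", call. = FALSE)
  }
  structure(list(flip_angles_deg = acq$flip_angles_deg, signals = signals,
                 acq = acq),
            class = "vfa_signal_set")
}

#' Linearize a VFA signal set
#'
#' Maps each (flip angle, signal) pair to the linearized coordinates
#' `y = S/sin(a)`, `x = S/tan(a)`, preserving order. At `a = 90` degrees
#' the x coordinate is exactly 0 (`S * cos / sin`, not a division by
#' `tan`), so the 90-degree point is usable.
#'
#' @param set A [vfa_signal_set()].
#' @return `data.frame` with columns `x` and `y`.
#' @export
linearize_vfa <- function(set) {
  stopifnot(inherits(set, "vfa_signal_set"))
  data.frame(x = set$signals * cos_deg(set$flip_angles_deg) /
               sin_deg(set$flip_angles_deg),
             y = set$signals / sin_deg(set$flip_angles_deg))
}

t1_fit_invalid <- function(reason) {
  structure(list(t1_ms = NA_real_, m0 = NA_real_, slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 valid = FALSE, reason = reason),
            class = "t1_fit_result")
}

#' Fit T1 and M0 by the linearized VFA method
#'
#' Unweighted ordinary least squares of `S/sin(a)` on `S/tan(a)`; the
#' slope estimates `E1 = exp(-TR/T1)` and the intercept `M0 (1 - E1)`.
#' Fits with slope outside (0, 1), a degenerate design (all x equal, e.g.
#' all-zero signals), or T1 outside the validity window (1, 10000) ms are
#' returned as invalid results carrying a reason — never as errors.
#'
#' @param set A [vfa_signal_set()].
#' @return An object of class `t1_fit_result` with fields `t1_ms`, `m0`,
#'   `slope`, `intercept`, `r_squared`, `valid`, `reason`.
#' @export
fit_t1_vfa <- function(set) {
  stopifnot(inherits(set, "vfa_signal_set"))
  pts <- linearize_vfa(set)
  x <- pts$x; y <- pts$y
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0 || !is.finite(sxx)) {
    return(t1_fit_invalid("degenerate design (all x equal)"))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  syy <- sum((y - mean(y))^2)
  r_squared <- if (syy > 0) 1 - sum(resid^2) / syy else 1
  if (!is.finite(slope) || slope <= 0 || slope >= 1) {
    out <- t1_fit_invalid("slope outside (0, 1)")
    out$slope <- slope; out$intercept <- intercept; out$r_squared <- r_squared
    return(out)
  }
  t1 <- -set$acq$tr_ms / log(slope)
  m0 <- intercept / (1 - slope)
  valid <- t1 > T1_VALID_RANGE_MS[1] && t1 < T1_VALID_RANGE_MS[2]
  structure(list(t1_ms = t1, m0 = m0, slope = slope, intercept = intercept,
                 r_squared = r_squared, valid = valid,
                 reason = if (valid) NA_character_ else
                   "T1 outside validity window"),
            class = "t1_fit_result")
}

#' @export
print.t1_fit_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<t1_fit_result> T1 = %.1f ms, M0 = %.3g, R2 = %.5f\n",
                x$t1_ms, x$m0, x$r_squared))
  } else {
    cat("<t1_fit_result> invalid:", x$reason, "\n")
  }
  invisible(x)
}

#' Mean signal over one ROI label
#'
#' @param vol An [image_volume()].
#' @param mask An [roi_mask()] on the same grid.
#' @param label Integer label to average over.
#' @return Arithmetic mean of the labeled voxels.
#' @export
roi_mean_signal <- function(vol, mask, label) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  sel <- mask$labels == label
  if (!any(sel)) stop("label ", label, " has no voxels", call. = FALSE)
  mean(vol$data[sel])
}

#' Voxelwise VFA T1 map
#'
#' Applies the linearized VFA fit independently to every voxel of a
#' co-registered flip-angle series and returns a T1 map in milliseconds.
#' Voxels whose fit is invalid (zero signal, slope outside (0, 1), T1
#' outside the validity window) are set to the [T1_INVALID] sentinel.
#' Maps are for inspection; ROI-level FBV always uses ROI-mean fits.
#'
#' @param series List of `MR_SIGNAL` [image_volume()]s, one per flip angle
#'   of `acq`, in the same order.
#' @param acq An [acquisition_params()].
#' @return A `T1_MAP` [image_volume()].
#' @export
fit_t1_voxelwise <- function(series, acq) {
  stopifnot(inherits(acq, "acquisition_params"), is.list(series))
  angles <- acq$flip_angles_deg
  if (length(series) != length(angles)) {
    stop("need one volume per flip angle", call. = FALSE)
  }
  shape <- dim(series[[1]]$data)
  for (v in series) {
    if (!identical(dim(v$data), shape)) stop("shape mismatch in series", call. = FALSE)
  }
  n <- length(angles)
  nvox <- prod(shape)
  # accumulate OLS sufficient statistics across flip angles, vectorized
  sx <- sy <- sxx <- sxy <- numeric(nvox)
  for (i in seq_len(n)) {
    s <- as.numeric(series[[i]]$data)
    x <- s * cos_deg(angles[i]) / sin_deg(angles[i])
    y <- s / sin_deg(angles[i])
    sx <- sx + x; sy <- sy + y
    sxx <- sxx + x * x; sxy <- sxy + x * y
  }
  den <- n * sxx - sx * sx
  slope <- (n * sxy - sx * sy) / den
  t1 <- -acq$tr_ms / log(slope)
  bad <- !is.finite(slope) | slope <= 0 | slope >= 1 | den <= 0 |
    !is.finite(t1) | t1 <= T1_VALID_RANGE_MS[1] | t1 >= T1_VALID_RANGE_MS[2]
  t1[bad] <- T1_INVALID
  image_volume(array(t1, dim = shape), series[[1]]$voxel_size_mm, "T1_MAP",
               contrast_state = series[[1]]$contrast_state)
}
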