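#' @keywords internal
"_PACKAGE"

MODALITIES <- c("MR_SIGNAL", "CT_HU", "T1_MAP")
CONTRAST_STATES <- c("PRE", "POST")
ROI_ROLES <- c("PLACENTA", "IVC", "AMNIOTIC_FLUID", "BACKGROUND")

#' Sentinel value marking invalid voxels in T1 maps
#'
#' T1 maps store fitted relaxation times in milliseconds; voxels where the
#' variable flip angle fit failed (zero signal, slope outside (0, 1), T1
#' outside the validity window) carry this negative sentinel instead of a
#' separate mask file.
#' @export
T1_INVALID <- -1

#' Construct a 3D image volume
#'
#' The common currency of the pipeline: a 3D scalar field with voxel
#' geometry and a modality tag. MR signal volumes are in arbitrary units,
#' CT volumes in Hounsfield units (HU, may be negative), and T1 maps in
#' milliseconds with invalid voxels set to [T1_INVALID].
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm Numeric length-3 vector of voxel edge lengths (mm).
#' @param modality One of `"MR_SIGNAL"`, `"CT_HU"`, `"T1_MAP"`.
#' @param contrast_state Optional, `"PRE"` or `"POST"`.
#' @param flip_angle_deg Optional flip angle in degrees; only meaningful
#'   (and only allowed) for `MR_SIGNAL` volumes.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_mm, modality,
                         contrast_state = NULL, flip_angle_deg = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("expected 3D volume", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel sizes must be three positive numbers", call. = FALSE)
  }
  modality <- match.arg(modality, MODALITIES)
  if (!is.null(contrast_state)) {
    contrast_state <- match.arg(contrast_state, CONTRAST_STATES)
  }
  if (!is.null(flip_angle_deg)) {
    if (modality != "MR_SIGNAL") {
      stop("flip_angle_deg is only valid for MR_SIGNAL volumes", call. = FALSE)
    }
    flip_angle_deg <- as.numeric(flip_angle_deg)
    stopifnot(length(flip_angle_deg) == 1L, is.finite(flip_angle_deg))
  }
  if (modality == "T1_MAP") {
    bad <- data < 0 & data != T1_INVALID
    if (any(bad, na.rm = TRUE)) {
      stop("T1_MAP values must be >= 0 or the invalid sentinel ", T1_INVALID,
           call. = FALSE)
    }
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, modality = modality,
         contrast_state = contrast_state, flip_angle_deg = flip_angle_deg),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s\n", x$modality,
              paste(dim(x$data), collapse = " x ")))
  cat(sprintf("  voxel size: %s mm\n", paste(format(x$voxel_size_mm), collapse = " x ")))
  if (!is.null(x$contrast_state)) cat("  contrast state:", x$contrast_state, "\n")
  if (!is.null(x$flip_angle_deg)) cat("  flip angle:", x$flip_angle_deg, "deg\n")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Construct a labeled ROI mask
#'
#' Integer label field sharing the grid of its companion volume, plus a
#' table mapping each label to a compartment role and (for placentae and
#' amniotic sacs) a feto-placental unit (FPU) index. Label 0 means
#' unlabeled. A study has exactly one IVC label (the maternal blood
#' reference) and each placenta label carries a distinct FPU index.
#'
#' @param labels 3D integer array of labels (0 = unlabeled).
#' @param voxel_size_mm Numeric length-3, mm.
#' @param label_table `data.frame` with columns `label` (integer),
#'   `role` (one of PLACENTA, IVC, AMNIOTIC_FLUID, BACKGROUND) and
#'   `fpu` (integer or NA).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, voxel_size_mm, label_table) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("expected 3D label volume", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  label_table <- as.data.frame(label_table)
  need <- c("label", "role", "fpu")
  if (!all(need %in% names(label_table))) {
    stop("label_table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  label_table$label <- as.integer(label_table$label)
  label_table$fpu <- as.integer(label_table$fpu)
  if (any(!label_table$role %in% ROI_ROLES)) {
    stop("unknown role in label_table", call. = FALSE)
  }
  if (any(duplicated(label_table$label)) || any(label_table$label == 0L)) {
    stop("labels must be unique and nonzero", call. = FALSE)
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, label_table$label)
  if (length(unknown)) {
    stop("labels present in grid but missing from label_table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_ivc <- sum(label_table$role == "IVC")
  if (n_ivc != 1L) stop("exactly one IVC label required, found ", n_ivc, call. = FALSE)
  pl <- label_table[label_table$role == "PLACENTA", ]
  if (nrow(pl) && (any(is.na(pl$fpu)) || any(duplicated(pl$fpu)))) {
    stop("each PLACENTA label needs a distinct FPU index", call. = FALSE)
  }
  structure(
    list(labels = labels, voxel_size_mm = as.numeric(voxel_size_mm),
         label_table = label_table),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d labels (%d placentae)\n",
              paste(dim(x$labels), collapse = " x "),
              nrow(x$label_table),
              sum(x$label_table$role == "PLACENTA")))
  invisible(x)
}

# labels for a role; single for IVC by construction
mask_labels <- function(mask, role) {
  mask$label_table$label[mask$label_table$role == role]
}

check_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$labels))) {
    stop("volume and mask shapes disagree", call. = FALSE)
  }
  invisible(TRUE)
}

#' Acquisition parameters for a spoiled-GRE VFA study
#'
#' Defaults follow a 1 T small-animal T1-weighted 3D GRE protocol:
#' TR = 20 ms, TE = 3.5 ms, flip angles 8, 15, 25, 35, 45 degrees.
#'
#' @param tr_ms Repetition time, ms (> 0).
#' @param te_ms Echo time, ms (>= 0).
#' @param flip_angles_deg Ordered vector of at least two distinct flip
#'   angles, each in (0, 90].
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr_ms = 20, te_ms = 3.5,
                               flip_angles_deg = c(8, 15, 25, 35, 45)) {
  tr_ms <- as.numeric(tr_ms); te_ms <- as.numeric(te_ms)
  flip_angles_deg <- as.numeric(flip_angles_deg)
  if (length(tr_ms) != 1L || !is.finite(tr_ms) || tr_ms <= 0) {
    stop("tr_ms must be a single positive number", call. = FALSE)
  }
  if (length(te_ms) != 1L || !is.finite(te_ms) || te_ms < 0) {
    stop("te_ms must be a single non-negative number", call. = FALSE)
  }
  if (length(unique(flip_angles_deg)) < 2L) {
    stop(">= 2 flip angles required", call. = FALSE)
  }
  if (any(flip_angles_deg <= 0 | flip_angles_deg > 90)) {
    stop("flip angles must lie in (0, 90] degrees", call. = FALSE)
  }
  structure(list(tr_ms = tr_ms, te_ms = te_ms,
                 flip_angles_deg = flip_angles_deg),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("<acquisition_params> TR %g ms, TE %g ms, alpha = [%s] deg\n",
              x$tr_ms, x$te_ms, paste(x$flip_angles_deg, collapse = ", ")))
  invisible(x)
}
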