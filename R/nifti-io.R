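# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader is available in the installed R stack, so the subset of
# the format this pipeline needs is implemented here directly: 348-byte
# header, single-file magic "n+1", axis-aligned geometry in pixdim/srow,
# little- or big-endian detection on read, common scalar dtypes, and
# scl_slope/scl_inter applied on read. Volumes are written as float64
# (lossless for R doubles) in little-endian order.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, open) {
  # gzfile transparently reads both plain and gzipped data
  if (grepl("\\.gz$", path) || open == "rb") gzfile(path, open) else file(path, open)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads single-file NIfTI-1 (`.nii` or `.nii.gz`). Modality, contrast
#' state and flip angle are metadata that NIfTI does not carry; they are
#' taken from the explicit arguments if given, else from a JSON sidecar
#' (`<stem>.json`) written by [write_volume()]. They are never guessed
#' from voxel intensities.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality,contrast_state,flip_angle_deg Optional metadata
#'   overriding the sidecar.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = NULL, contrast_state = NULL,
                        flip_angle_deg = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  ok3d <- ndim == 3L || (ndim > 3L && all(dims[5:(ndim + 1)] == 1L))
  if (!ok3d) {
    stop("expected 3D volume, got ", ndim, "D: ", path, call. = FALSE)
  }
  shape <- dims[2:4]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  voxel_size <- abs(pixdim[2:4])
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("non-positive voxel size in header: ", path, call. = FALSE)
  }

  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  values <- readBin(con, spec$what, n = n_vox, size = spec$size,
                    signed = spec$signed, endian = endian)
  if (length(values) != n_vox) stop("truncated voxel data: ", path, call. = FALSE)
  values <- as.numeric(values)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    values <- values * scl_slope + scl_inter
  }
  data <- array(values, dim = shape)

  meta <- list(modality = modality, contrast_state = contrast_state,
               flip_angle_deg = flip_angle_deg)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (k in names(meta)) {
      if (is.null(meta[[k]]) && !is.null(side[[k]])) meta[[k]] <- side[[k]]
    }
  }
  if (is.null(meta$modality)) {
    stop("modality not given and no sidecar found for ", path, call. = FALSE)
  }
  image_volume(data, voxel_size, meta$modality,
               contrast_state = meta$contrast_state,
               flip_angle_deg = meta$flip_angle_deg)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Writes single-file NIfTI-1 with float64 voxel data (bit-exact for R
#' doubles), voxel geometry in `pixdim` and a diagonal sform. A JSON
#' sidecar (`<stem>.json`) records modality, contrast state and flip
#' angle so that [read_volume()] can restore them.
#'
#' @param vol An [image_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = TRUE) {
  stopifnot(inherits(vol, "image_volume"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  shape <- dim(vol$data)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  end <- "little"
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = end)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = end)
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = end)
  w_raw <- function(n) writeBin(raw(n), con)
  w_char <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b, raw(n - length(b))), con)
  }

  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))  # dim
  w_f32(c(0, 0, 0))                # intent_p1..3
  w_i16(0L)                        # intent_code
  w_i16(64L)                       # datatype: float64
  w_i16(64L)                       # bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, vol$voxel_size_mm, rep(0, 4)))  # pixdim (qfac 1)
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)             # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_char(paste0("placentafbv ", vol$modality), 80L)  # descrip
  w_raw(24L)                       # aux_file
  w_i16(0L); w_i16(1L)             # qform_code, sform_code
  w_f32(rep(0, 6))                 # quatern/qoffset
  w_f32(c(vol$voxel_size_mm[1], 0, 0, 0))  # srow_x
  w_f32(c(0, vol$voxel_size_mm[2], 0, 0))  # srow_y
  w_f32(c(0, 0, vol$voxel_size_mm[3], 0))  # srow_z
  w_raw(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                        # extender
  writeBin(as.numeric(vol$data), con, size = 8L, endian = end)

  if (sidecar) {
    meta <- list(modality = vol$modality)
    if (!is.null(vol$contrast_state)) meta$contrast_state <- vol$contrast_state
    if (!is.null(vol$flip_angle_deg)) meta$flip_angle_deg <- vol$flip_angle_deg
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
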