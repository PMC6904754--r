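# Study manifests bind the volumes, mask and acquisition of one subject.
# Schema (JSON or YAML):
#   subject_id: "S1"
#   gestational_age_label: "E14.5"
#   acquisition: {tr_ms: 20, te_ms: 3.5, flip_angles_deg: [8,15,25,35,45]}
#   mask: "S1_mask.nii.gz"
#   labels: [{label: 1, role: "PLACENTA", fpu: 1}, ...]
#   mr_volumes: [{contrast_state: "PRE", flip_angle_deg: 8, path: "..."}, ...]
#   ct_volumes: [{contrast_state: "PRE", path: "..."}, ...]   # optional
# Paths are resolved relative to the manifest's directory.

#' Load and validate a study manifest
#'
#' Reads a JSON or YAML manifest describing one imaging subject: the
#' acquisition parameters, the label mask, the label table, and the
#' per-state volumes. All invariants are checked eagerly: every referenced
#' file must exist, each contrast state must list exactly the acquisition's
#' flip angles, and the label table must contain exactly one IVC.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` manifest.
#' @return An object of class `study_manifest` with resolved paths.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("manifest must be JSON or YAML, got .", ext, call. = FALSE)
  )
  need <- c("subject_id", "gestational_age_label", "acquisition", "mask",
            "labels", "mr_volumes")
  missing_keys <- setdiff(need, names(doc))
  if (length(missing_keys)) {
    stop("manifest missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  acq <- acquisition_params(
    tr_ms = doc$acquisition$tr_ms,
    te_ms = doc$acquisition$te_ms,
    flip_angles_deg = unlist(doc$acquisition$flip_angles_deg)
  )
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(root, p)
    if (!file.exists(full)) {
      stop("manifest references missing file: ", full, call. = FALSE)
    }
    full
  }
  label_table <- do.call(rbind, lapply(doc$labels, function(l) {
    data.frame(label = as.integer(l$label), role = as.character(l$role),
               fpu = if (is.null(l$fpu)) NA_integer_ else as.integer(l$fpu))
  }))
  mr <- do.call(rbind, lapply(doc$mr_volumes, function(v) {
    data.frame(contrast_state = as.character(v$contrast_state),
               flip_angle_deg = as.numeric(v$flip_angle_deg),
               path = resolve(v$path))
  }))
  for (state in unique(mr$contrast_state)) {
    got <- sort(mr$flip_angle_deg[mr$contrast_state == state])
    if (!isTRUE(all.equal(got, sort(acq$flip_angles_deg)))) {
      stop("flip angles for state ", state,
           " do not match acquisition list", call. = FALSE)
    }
  }
  ct <- NULL
  if (!is.null(doc$ct_volumes)) {
    ct <- do.call(rbind, lapply(doc$ct_volumes, function(v) {
      data.frame(contrast_state = as.character(v$contrast_state),
                 path = resolve(v$path))
    }))
  }
  structure(
    list(subject_id = as.character(doc$subject_id),
         gestational_age_label = as.character(doc$gestational_age_label),
         acquisition = acq,
         mask_path = resolve(doc$mask),
         label_table = label_table,
         mr_volumes = mr,
         ct_volumes = ct),
    class = "study_manifest"
  )
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("<study_manifest> %s (%s): %d MR volumes, %d CT volumes, %d labels\n",
              x$subject_id, x$gestational_age_label, nrow(x$mr_volumes),
              if (is.null(x$ct_volumes)) 0L else nrow(x$ct_volumes),
              nrow(x$label_table)))
  invisible(x)
}

# serialize a manifest written by the phantom cohort generator
write_manifest_json <- function(manifest_list, path) {
  jsonlite::write_json(manifest_list, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the ROI mask referenced by a manifest
#'
#' @param manifest A `study_manifest`.
#' @return An [roi_mask()].
#' @export
load_mask <- function(manifest) {
  vol <- read_volume(manifest$mask_path, modality = "MR_SIGNAL")
  roi_mask(round(vol$data), vol$voxel_size_mm, manifest$label_table)
}

#' Write records to CSV with full numeric precision
#'
#' Deterministic CSV writer for pipeline outputs: header row, no row
#' names, numbers at R's full default precision (15 significant digits).
#' Accepts a `data.frame` (possibly zero-row, giving a header-only file)
#' or a non-empty list of homogeneous records.
#'
#' @param rows `data.frame` or list of named lists.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!length(rows)) {
      stop("cannot infer columns from an empty record list; pass a data.frame",
           call. = FALSE)
    }
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}
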