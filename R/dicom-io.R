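# Domain model: CT series and radiotherapy structure sets.

#' Read a directory of CT DICOM slices into a `ct_series`
#'
#' Builds the ordered axial series: one `slice_meta` record per CT file,
#' sorted strictly by the z component of `ImagePositionPatient` (ties broken
#' by SOP instance UID). Raw stored pixel values are kept; Hounsfield units
#' are obtained lazily via [slice_hu()] using `RescaleSlope` /
#' `RescaleIntercept`.
#'
#' Files that are not DICOM, or DICOM files that are not CT images (for
#' example an RTSTRUCT living in the same tree), are skipped with a warning.
#'
#' @param directory path containing one or more CT DICOM files (searched
#'   recursively).
#' @param patient_id optional patient identifier; defaults to the
#'   `PatientID` of the first slice.
#' @return object of class `ct_series`: list with `patient_id` and `slices`
#'   (list of `slice_meta`, each holding `sop_instance_uid`, `z_position`,
#'   `rescale_slope`, `rescale_intercept`, `slice_thickness`,
#'   `pixel_spacing` (row, col mm), `image_position` (x0, y0, z0 mm) and the
#'   raw integer `pixel_array`).
#' @export
read_ct_series <- function(directory, patient_id = NULL) {
  files <- sort(list.files(directory, full.names = TRUE, recursive = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    ctsurv_abort(paste0("no files in ", directory), "ctsurv_empty_series")
  slices <- list()
  for (f in files) {
    ds <- tryCatch(dcm_read(f), ctsurv_not_dicom = function(e) {
      warning("skipping non-DICOM file: ", f, call. = FALSE)
      NULL
    })
    if (is.null(ds)) next
    if (!identical(ds$Modality, "CT") || is.null(ds$PixelData)) {
      warning("skipping non-CT DICOM file: ", f, call. = FALSE)
      next
    }
    required <- c("SOPInstanceUID", "ImagePositionPatient", "PixelSpacing",
                  "SliceThickness", "RescaleSlope", "RescaleIntercept")
    for (k in required) {
      if (is.null(ds[[k]]))
        ctsurv_abort(paste0("missing required tag ", k, " in ", f),
                     "ctsurv_missing_tag", tag = k, file = f)
    }
    slices[[length(slices) + 1L]] <- structure(list(
      sop_instance_uid  = ds$SOPInstanceUID,
      z_position        = ds$ImagePositionPatient[3],
      rescale_slope     = ds$RescaleSlope[1],
      rescale_intercept = ds$RescaleIntercept[1],
      slice_thickness   = ds$SliceThickness[1],
      pixel_spacing     = ds$PixelSpacing,       # (row, col) mm/px
      image_position    = ds$ImagePositionPatient,
      pixel_array       = .decode_pixels(ds, f)
    ), class = "slice_meta")
    if (is.null(patient_id) && !is.null(ds$PatientID))
      patient_id <- ds$PatientID
  }
  if (length(slices) == 0L)
    ctsurv_abort(paste0("no CT DICOM slices found in ", directory),
                 "ctsurv_empty_series")
  uids <- vapply(slices, `[[`, "", "sop_instance_uid")
  if (anyDuplicated(uids))
    ctsurv_abort(paste0("duplicate SOP instance UID in ", directory, ": ",
                        uids[duplicated(uids)][1]),
                 "ctsurv_duplicate_uid")
  z <- vapply(slices, `[[`, 0, "z_position")
  slices <- slices[order(z, uids)]
  sp <- vapply(slices, function(s) s$pixel_spacing, numeric(2))
  th <- vapply(slices, `[[`, 0, "slice_thickness")
  if (max(sp) - min(sp) > 1e-6 || max(th) - min(th) > 1e-6)
    warning("slices do not share pixel spacing / thickness", call. = FALSE)
  structure(list(patient_id = patient_id %||% NA_character_, slices = slices),
            class = "ct_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hounsfield units for one slice
#'
#' Applies the linear rescale `slope * stored + intercept`.
#'
#' @param slice a `slice_meta` record from a [read_ct_series()] result.
#' @return numeric matrix of HU values.
#' @export
slice_hu <- function(slice) {
  slice$rescale_slope * slice$pixel_array + slice$rescale_intercept
}

#' Read an RTSTRUCT file into a `structure_set`
#'
#' Collects every ROI named in `StructureSetROISequence` and groups the
#' contours of `ROIContourSequence` under it (matched by ROI number). Each
#' contour records the `ReferencedSOPInstanceUID` of the first
#' `ContourImageSequence` item and its mm vertex triplets. ROI names are
#' whitespace-stripped. An ROI declared but carrying no contours is kept
#' with an empty contour list (with a warning); a contour without an image
#' reference gets `referenced_sop_uid = NA` and can be matched to a slice
#' geometrically by [gtv1_slice_uids()].
#'
#' @param rtstruct_file path to an RTSTRUCT DICOM file.
#' @return object of class `structure_set`: list with `patient_id` and
#'   `rois`, a named list mapping ROI name to a list of contours
#'   (`referenced_sop_uid`, `points_mm` n x 3 matrix).
#' @export
read_structure_set <- function(rtstruct_file) {
  ds <- dcm_read(rtstruct_file)
  roi_names <- character(0)
  roi_numbers <- integer(0)
  for (item in ds$StructureSetROISequence %||% list()) {
    roi_names <- c(roi_names, trimws(item$ROIName %||% ""))
    roi_numbers <- c(roi_numbers, item$ROINumber %||% NA_integer_)
  }
  if (anyDuplicated(roi_names))
    warning("duplicate ROI names in ", rtstruct_file, call. = FALSE)
  rois <- stats::setNames(vector("list", length(roi_names)), roi_names)
  for (i in seq_along(rois)) rois[[i]] <- list()
  for (item in ds$ROIContourSequence %||% list()) {
    num <- item$ReferencedROINumber %||% NA_integer_
    j <- match(num, roi_numbers)
    if (is.na(j)) {
      warning("contour set references unknown ROI number ", num, call. = FALSE)
      next
    }
    contours <- lapply(item$ContourSequence %||% list(), function(cs) {
      uid <- NA_character_
      cis <- cs$ContourImageSequence
      if (!is.null(cis) && length(cis) >= 1L &&
          !is.null(cis[[1]]$ReferencedSOPInstanceUID))
        uid <- cis[[1]]$ReferencedSOPInstanceUID
      pts <- matrix(cs$ContourData %||% numeric(0), ncol = 3L, byrow = TRUE)
      list(referenced_sop_uid = uid, points_mm = pts)
    })
    rois[[j]] <- contours
  }
  empty <- names(rois)[vapply(rois, length, 0L) == 0L]
  if (length(empty))
    warning("ROI(s) declared without contours: ",
            paste(empty, collapse = ", "), call. = FALSE)
  structure(list(patient_id = ds$PatientID %||% NA_character_, rois = rois),
            class = "structure_set")
}

#' SOP instance UIDs of the slices carrying the primary tumor ROI
#'
#' Intersects the series' slice UIDs with the UIDs referenced by the GTV-1
#' contours, deduplicates (several contours may sit on one slice), and
#' returns them in z-position order. Contours lacking an image reference are
#' matched to the nearest slice by z, accepted when within half a slice
#' thickness (with a warning). Contours referencing UIDs absent from the
#' series are dropped with a warning.
#'
#' @param series a `ct_series`.
#' @param ss a `structure_set`.
#' @param roi_name ROI to look up; exact match after whitespace strip, or a
#'   regular expression when `regex = TRUE` (real structure sets show naming
#'   drift).
#' @param regex interpret `roi_name` as a regular expression.
#' @return character vector of SOP instance UIDs in z order.
#' @export
gtv1_slice_uids <- function(series, ss, roi_name = "GTV-1", regex = FALSE) {
  nm <- names(ss$rois)
  hit <- if (regex) grep(roi_name, nm) else which(nm == roi_name)
  if (length(hit) == 0L)
    ctsurv_abort(paste0("ROI '", roi_name, "' absent for patient ",
                        ss$patient_id, "; patient excluded"),
                 "ctsurv_no_gtv1", patient_id = ss$patient_id)
  contours <- ss$rois[[hit[1]]]
  series_uids <- vapply(series$slices, `[[`, "", "sop_instance_uid")
  z <- vapply(series$slices, `[[`, 0, "z_position")
  thick <- series$slices[[1]]$slice_thickness
  uids <- vapply(contours, function(ct) {
    if (!is.na(ct$referenced_sop_uid)) return(ct$referenced_sop_uid)
    if (nrow(ct$points_mm) == 0L) return(NA_character_)
    # geometry-only contour: nearest slice by z, within half a thickness
    cz <- ct$points_mm[1, 3]
    j <- which.min(abs(z - cz))
    if (abs(z[j] - cz) <= thick / 2) {
      warning("contour without image reference matched to slice by z (",
              signif(cz, 6), " mm)", call. = FALSE)
      series_uids[j]
    } else NA_character_
  }, "")
  uids <- uids[!is.na(uids)]
  missing <- setdiff(uids, series_uids)
  if (length(missing))
    warning(length(missing), " contour reference(s) not found in series; dropped",
            call. = FALSE)
  keep <- intersect(series_uids, uids)          # series (z) order, deduplicated
  keep[order(z[match(keep, series_uids)])]
}

#' Per-ROI contour counts of a structure set
#'
#' The number of contour polygons filed under each ROI name (one contour per
#' slice per region; a slice with two regions contributes two).
#'
#' @param ss a `structure_set`.
#' @return data.frame with columns `roi_name`, `contour_count`.
#' @export
structure_inventory <- function(ss) {
  data.frame(roi_name = names(ss$rois) %||% character(0),
             contour_count = vapply(ss$rois, length, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write per-patient structure inventories as TSV
#'
#' @param inventories named list of [structure_inventory()] tables, keyed by
#'   patient id (or a single table plus `patient_id`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_inventory_tsv <- function(inventories, path) {
  rows <- do.call(rbind, lapply(names(inventories), function(pid) {
    inv <- inventories[[pid]]
    if (nrow(inv) == 0L) return(NULL)
    cbind(patient_id = pid, inv)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ct_series <- function(x, ...) {
  cat("<ct_series> patient", x$patient_id, "-", length(x$slices), "slices\n")
  if (length(x$slices)) {
    z <- vapply(x$slices, `[[`, 0, "z_position")
    cat("  z:", signif(min(z), 6), "..", signif(max(z), 6), "mm; thickness",
        x$slices[[1]]$slice_thickness, "mm; pixel spacing",
        paste(signif(x$slices[[1]]$pixel_spacing, 4), collapse = " x "), "mm\n")
  }
  invisible(x)
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> patient", x$patient_id, "-", length(x$rois), "ROI(s)\n")
  inv <- structure_inventory(x)
  if (nrow(inv)) {
    for (i in seq_len(nrow(inv)))
      cat("  ", inv$roi_name[i], ": ", inv$contour_count[i], " contour(s)\n",
          sep = "")
  }
  invisible(x)
}
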