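# End-to-end per-patient convenience wrapper.

#' Process one patient from DICOM to a model-ready input stack
#'
#' Runs the full preprocessing chain: read the CT series and structure set,
#' locate the GTV-1 slices, rasterize the masks, run segmentation QC
#' (laterality selection, area-collapse repair, mislabel flagging against
#' the lung ROIs when present), select the slice window around the largest
#' tumor area, and build the normalized input stack.
#'
#' @param patient_dir directory holding the patient's CT slices and
#'   RTSTRUCT file (searched recursively).
#' @param depth slices in the model input (default 5).
#' @param variant `"full_slice"` (resized whole slices) or `"roi_crop"`
#'   (tumor-centred crops).
#' @param size output in-plane size; defaults to 240 for `full_slice` and
#'   128 for `roi_crop`.
#' @param tau QC area-collapse threshold.
#' @return list with `stack` (an `input_stack`), `qc` (a `qc_report`),
#'   `gtv1_slice_num`, `series`, `structures`, and `masks` (the repaired
#'   `tumor_mask_stack`).
#' @export
process_patient <- function(patient_dir, depth = 5L,
                            variant = c("full_slice", "roi_crop"),
                            size = NULL, tau = 0.5) {
  variant <- match.arg(variant)
  size <- size %||% if (variant == "full_slice") c(240L, 240L) else c(128L, 128L)
  rt_files <- list.files(patient_dir, recursive = TRUE, full.names = TRUE)
  # the RTSTRUCT sits in the same tree; muffle the reader's skip warning
  series <- withCallingHandlers(
    read_ct_series(patient_dir),
    warning = function(w) {
      if (grepl("non-CT DICOM", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss <- NULL
  for (f in rt_files) {
    ds <- tryCatch(dcm_read(f), error = function(e) NULL)
    if (!is.null(ds) && identical(ds$Modality, "RTSTRUCT")) {
      ss <- read_structure_set(f)
      break
    }
  }
  if (is.null(ss))
    ctsurv_abort(paste0("no RTSTRUCT found under ", patient_dir),
                 "ctsurv_no_rtstruct")
  masks <- build_mask_stack(series, ss)
  lung_masks <- .lung_union_masks(series, ss, masks)
  qc <- run_qc(masks, tau = tau, lung_masks = lung_masks)
  uids <- select_slices(qc$stack, depth)
  stack <- if (variant == "full_slice")
    build_full_slice_stack(series, uids, size)
  else
    build_roi_crop_stack(series, qc$stack, uids, size)
  list(stack = stack, qc = qc$report,
       gtv1_slice_num = length(qc$stack$masks),
       series = series, structures = ss, masks = qc$stack)
}

# Union of both lung ROIs per GTV slice, for the mislabel heuristic.
.lung_union_masks <- function(series, ss, masks) {
  lungs <- intersect(c("Lung-Left", "Lung-Right"), names(ss$rois))
  if (length(lungs) == 0L) return(NULL)
  series_uids <- vapply(series$slices, `[[`, "", "sop_instance_uid")
  out <- list()
  for (m in masks$masks) {
    sl <- series$slices[[match(m$sop_uid, series_uids)]]
    acc <- matrix(FALSE, nrow(sl$pixel_array), ncol(sl$pixel_array))
    for (roi in lungs) {
      for (ct in ss$rois[[roi]]) {
        if (identical(ct$referenced_sop_uid, m$sop_uid))
          acc <- acc | rasterize_contour(ct, sl)$mask
      }
    }
    out[[m$sop_uid]] <- acc
  }
  out
}
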