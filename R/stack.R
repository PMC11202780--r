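# Model-input construction: choose the tumor-slice window around the
# largest-area slice, oversample thin tumors, resize / crop, normalize.

#' Choose the input-window slices around the largest tumor area
#'
#' Picks `depth` tumor-containing slices centred (when possible) on the
#' slice with the largest tumor area; at the ends of the tumor range the
#' window shifts so every selected slice still contains tumor. Area ties go
#' to the lower z index. When fewer than `depth` tumor slices exist, the
#' available ones are duplicated with [oversample_slices()].
#'
#' @param stack a `tumor_mask_stack` (z-ordered).
#' @param depth number of slices in the model input (default 5).
#' @return character vector of `depth` SOP instance UIDs in z order.
#' @export
select_slices <- function(stack, depth = 5L) {
  if (length(stack$masks) == 0L)
    ctsurv_abort("empty mask stack", "ctsurv_empty_stack")
  areas <- vapply(stack$masks, `[[`, 0L, "area_px")
  uids <- vapply(stack$masks, `[[`, "", "sop_uid")
  tumor <- which(areas > 0L)
  if (length(tumor) == 0L)
    ctsurv_abort("no tumor-containing slices", "ctsurv_empty_stack")
  t_uids <- uids[tumor]
  n <- length(t_uids)
  if (n < depth) return(oversample_slices(t_uids, depth))
  k <- which.max(areas[tumor])          # ties -> lower z (which.max is first)
  start <- k - (depth - 1L) %/% 2L
  start <- max(1L, min(start, n - depth + 1L))
  t_uids[start:(start + depth - 1L)]
}

#' Oversample a short slice list to the target depth
#'
#' Duplicates the edge slices alternately -- first an extra copy of the last
#' slice, then of the first -- until the list reaches `depth`, preserving
#' the original order (so a single slice becomes `depth` copies of itself).
#'
#' @param uids character vector, `1 <= length(uids) < depth`.
#' @param depth target length.
#' @return character vector of length `depth`.
#' @export
oversample_slices <- function(uids, depth = 5L) {
  stopifnot(length(uids) >= 1L, length(uids) < depth)
  head_extra <- 0L; tail_extra <- 0L
  while (length(uids) + head_extra + tail_extra < depth) {
    if (tail_extra <= head_extra) tail_extra <- tail_extra + 1L
    else head_extra <- head_extra + 1L
  }
  c(rep(uids[1], head_extra), uids, rep(uids[length(uids)], tail_extra))
}

.resize_bilinear <- function(mat, out_rows, out_cols) {
  img <- EBImage::resize(EBImage::Image(mat), w = out_rows, h = out_cols,
                         filter = "bilinear", antialias = TRUE)
  as.matrix(img)
}

.new_input_stack <- function(patient_id, volume, source_uids, variant) {
  structure(list(patient_id = patient_id, volume = volume,
                 source_uids = source_uids, variant = variant,
                 depth = length(source_uids)),
            class = "input_stack")
}

#' Build a full-slice normalized input stack
#'
#' Each selected slice is byte-normalized ([dicom_to_byte_image()]), resized
#' to `size` with bilinear interpolation, and scaled into `[0, 1]`; slices
#' are stacked in z order.
#'
#' @param series a `ct_series`.
#' @param uids SOP instance UIDs from [select_slices()] (repeats allowed).
#' @param size output in-plane size, default `c(240, 240)`.
#' @return object of class `input_stack` with `volume`
#'   (`size[1] x size[2] x depth`, values in `[0, 1]`), `source_uids`,
#'   `variant = "full_slice"`.
#' @export
build_full_slice_stack <- function(series, uids, size = c(240L, 240L)) {
  series_uids <- vapply(series$slices, `[[`, "", "sop_instance_uid")
  vol <- array(0, dim = c(size[1], size[2], length(uids)))
  for (i in seq_along(uids)) {
    j <- match(uids[i], series_uids)
    if (is.na(j))
      ctsurv_abort(paste0("uid not in series: ", uids[i]), "ctsurv_missing_uid")
    byte <- suppressWarnings(dicom_to_byte_image(series$slices[[j]]$pixel_array))
    vol[, , i] <- .resize_bilinear(byte, size[1], size[2]) / 255
  }
  vol[vol < 0] <- 0; vol[vol > 1] <- 1   # guard bilinear over/undershoot
  .new_input_stack(series$patient_id, vol, uids, "full_slice")
}

#' Build a tumor-centred cropped input stack
#'
#' Crops each selected slice to `crop` pixels centred on the midpoint of the
#' minimum rectangle around the tumor mask. The window is clamped inside the
#' image when possible and zero-padded when the image is smaller than the
#' crop. A slice whose mask is empty falls back to the centre of the
#' largest-area slice's bounding box (logged via message).
#'
#' @param series a `ct_series`.
#' @param masks a `tumor_mask_stack` covering the selected uids.
#' @param uids SOP instance UIDs from [select_slices()].
#' @param crop output size, default `c(128L, 128L)`.
#' @return an `input_stack` with `variant = "roi_crop"`, values in `[0, 1]`.
#' @export
build_roi_crop_stack <- function(series, masks, uids, crop = c(128L, 128L)) {
  series_uids <- vapply(series$slices, `[[`, "", "sop_instance_uid")
  mask_uids <- vapply(masks$masks, `[[`, "", "sop_uid")
  areas <- vapply(masks$masks, `[[`, 0L, "area_px")
  fallback_bbox <- masks$masks[[which.max(areas)]]$bbox
  vol <- array(0, dim = c(crop[1], crop[2], length(uids)))
  for (i in seq_along(uids)) {
    j <- match(uids[i], series_uids)
    if (is.na(j))
      ctsurv_abort(paste0("uid not in series: ", uids[i]), "ctsurv_missing_uid")
    mi <- match(uids[i], mask_uids)
    bbox <- if (!is.na(mi) && masks$masks[[mi]]$area_px > 0L)
      masks$masks[[mi]]$bbox
    else {
      message("empty mask on slice ", uids[i],
              "; using largest-area slice bbox centre")
      fallback_bbox
    }
    byte <- suppressWarnings(dicom_to_byte_image(series$slices[[j]]$pixel_array))
    vol[, , i] <- .crop_centered(byte, bbox, crop) / 255
  }
  .new_input_stack(series$patient_id, vol, uids, "roi_crop")
}

# Crop `crop` pixels centred on the bbox midpoint; clamp the window into the
# image, zero-pad where the image is smaller than the crop.
.crop_centered <- function(mat, bbox, crop) {
  H <- nrow(mat); W <- ncol(mat)
  cr <- round((bbox["row_min"] + bbox["row_max"]) / 2)
  cc <- round((bbox["col_min"] + bbox["col_max"]) / 2)
  r0 <- max(1L, min(cr - crop[1] %/% 2L, H - crop[1] + 1L))
  c0 <- max(1L, min(cc - crop[2] %/% 2L, W - crop[2] + 1L))
  out <- matrix(0, crop[1], crop[2])
  rr <- r0:min(H, r0 + crop[1] - 1L)
  cc2 <- c0:min(W, c0 + crop[2] - 1L)
  out[seq_along(rr), seq_along(cc2)] <- mat[rr, cc2]
  out
}

#' Persist an input stack as plain text with a JSON sidecar
#'
#' Writes the volume as one TSV per slice plus a JSON sidecar recording
#' patient, variant and source slices, so stacks can be inspected or
#' reloaded without binary formats.
#'
#' @param stack an `input_stack`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_input_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(stack$depth))
    utils::write.table(stack$volume[, , i],
                       file.path(dir, sprintf("slice_%02d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(patient_id = stack$patient_id,
                            variant = stack$variant,
                            depth = stack$depth,
                            source_uids = stack$source_uids),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.input_stack <- function(x, ...) {
  d <- dim(x$volume)
  cat("<input_stack>", x$variant, "patient", x$patient_id, "-",
      paste(d, collapse = " x "), "in [0,1]\n")
  invisible(x)
}
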