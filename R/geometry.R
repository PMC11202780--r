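# Contour geometry: mm -> pixel transform, polygon rasterization, byte
# normalization. Pixel coordinates are 0-based in the patient-plane frame
# (x along columns, y along rows); R matrix indices are 1-based, so pixel
# (r, c) has center (x = c - 1, y = r - 1).

#' Millimeter to pixel coordinate transform
#'
#' Affine transform of in-plane patient coordinates to fractional pixel
#' coordinates: `x_pixel = (x_mm - x0) / xs`, `y_pixel = (y_mm - y0) / ys`.
#' Rounding is deferred to rasterization.
#'
#' @param point_mm numeric length-2 `(x, y)` in mm, or an n x 2 matrix.
#' @param image_position `(x0, y0)` mm reference point of the image frame
#'   (first two components of `ImagePositionPatient`).
#' @param pixel_spacing `(xs, ys)` mm per pixel along x (columns) and y
#'   (rows). Note DICOM `PixelSpacing` stores (row, col) = (ys, xs).
#' @return fractional pixel coordinates, same shape as `point_mm`.
#' @export
mm_to_pixel <- function(point_mm, image_position, pixel_spacing) {
  if (any(pixel_spacing <= 0))
    ctsurv_abort("pixel spacing must be positive", "ctsurv_bad_spacing")
  if (is.matrix(point_mm)) {
    cbind((point_mm[, 1] - image_position[1]) / pixel_spacing[1],
          (point_mm[, 2] - image_position[2]) / pixel_spacing[2])
  } else {
    c((point_mm[1] - image_position[1]) / pixel_spacing[1],
      (point_mm[2] - image_position[2]) / pixel_spacing[2])
  }
}

# Even-odd polygon fill over pixel centers, vectorized over the polygon's
# bounding box. A pixel is set when its center is strictly inside (even-odd
# ray cast) or on the boundary (within eps of an edge segment).
.fill_polygon <- function(px, py, nrow, ncol, eps = 1e-9) {
  mask <- matrix(FALSE, nrow, ncol)
  n <- length(px)
  if (n < 3L) return(mask)
  r0 <- max(1L, floor(min(py)) + 1L); r1 <- min(nrow, ceiling(max(py)) + 1L)
  c0 <- max(1L, floor(min(px)) + 1L); c1 <- min(ncol, ceiling(max(px)) + 1L)
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  gy <- rep(rows - 1, times = length(cols))   # pixel-center y per grid point
  gx <- rep(cols - 1, each = length(rows))
  inside <- integer(length(gx))
  on_edge <- logical(length(gx))
  x2v <- c(px[-1], px[1]); y2v <- c(py[-1], py[1])
  for (j in seq_len(n)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- x2v[j]; y2 <- y2v[j]
    if (y1 != y2) {
      crosses <- (y1 > gy) != (y2 > gy)
      xint <- x1 + (gy - y1) * (x2 - x1) / (y2 - y1)
      inside <- inside + as.integer(crosses & (gx < xint))
    }
    # distance from grid point to segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      d2 <- (gx - x1)^2 + (gy - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((gx - x1) * dx + (gy - y1) * dy) / L2))
      d2 <- (gx - x1 - t * dx)^2 + (gy - y1 - t * dy)^2
    }
    on_edge <- on_edge | (d2 <= eps * eps)
  }
  mask[rows, cols] <- matrix((inside %% 2L == 1L) | on_edge,
                             nrow = length(rows))
  mask
}

.mask_stats <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) {
    return(list(area_px = 0L, bbox = NULL, centroid_px = NULL))
  }
  list(area_px = nrow(w),
       bbox = c(row_min = min(w[, 1]), col_min = min(w[, 2]),
                row_max = max(w[, 1]), col_max = max(w[, 2])),
       centroid_px = c(row = mean(w[, 1]), col = mean(w[, 2])))
}

.new_tumor_mask <- function(sop_uid, mask) {
  st <- .mask_stats(mask)
  structure(list(sop_uid = sop_uid, mask = mask, area_px = st$area_px,
                 bbox = st$bbox, centroid_px = st$centroid_px),
            class = "tumor_mask")
}

#' Rasterize a mm contour onto a slice grid
#'
#' Transforms the contour vertices with [mm_to_pixel()] (using the slice's
#' `ImagePositionPatient` and `PixelSpacing`) and fills the polygon with the
#' even-odd rule over pixel centers; boundary pixels are included. A
#' degenerate contour (< 3 distinct points) yields an empty mask with a
#' warning. Several contours on one slice can be combined with
#' [union_masks()].
#'
#' @param contour a contour from a [read_structure_set()] result (fields
#'   `referenced_sop_uid`, `points_mm`).
#' @param slice_meta the `slice_meta` of the slice the contour lives on.
#' @return object of class `tumor_mask`: `sop_uid`, logical `mask` matrix
#'   matching the slice's pixel array, `area_px`, inclusive `bbox`
#'   `(row_min, col_min, row_max, col_max)` (1-based), and `centroid_px`.
#' @export
rasterize_contour <- function(contour, slice_meta) {
  pts <- contour$points_mm
  dims <- dim(slice_meta$pixel_array)
  distinct <- unique(round(pts[, 1:2, drop = FALSE], 9))
  if (nrow(distinct) < 3L) {
    warning("degenerate contour (<3 distinct points); empty mask", call. = FALSE)
    return(.new_tumor_mask(contour$referenced_sop_uid,
                           matrix(FALSE, dims[1], dims[2])))
  }
  xs <- slice_meta$pixel_spacing[2]  # column spacing
  ys <- slice_meta$pixel_spacing[1]  # row spacing
  pp <- mm_to_pixel(pts[, 1:2, drop = FALSE],
                    slice_meta$image_position[1:2], c(xs, ys))
  mask <- .fill_polygon(pp[, 1], pp[, 2], dims[1], dims[2])
  .new_tumor_mask(contour$referenced_sop_uid, mask)
}

#' Union of tumor masks on one slice
#'
#' Used when a slice carries more than one contour of the same ROI
#' (multi-region tumors): the masks are OR-ed and the area / bounding box /
#' centroid recomputed.
#'
#' @param masks list of `tumor_mask` objects sharing one `sop_uid`.
#' @return a single `tumor_mask`.
#' @export
union_masks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  m <- Reduce(`|`, lapply(masks, `[[`, "mask"))
  .new_tumor_mask(masks[[1]]$sop_uid, m)
}

#' Rasterize the GTV-1 masks of a patient into a z-ordered stack
#'
#' For each slice returned by [gtv1_slice_uids()], rasterizes all of that
#' slice's contours and unions them into one mask.
#'
#' @param series a `ct_series`.
#' @param ss a `structure_set`.
#' @inheritParams gtv1_slice_uids
#' @return object of class `tumor_mask_stack`: `patient_id` plus `masks`, a
#'   z-ordered list of `tumor_mask` objects (one per GTV-1 slice).
#' @export
build_mask_stack <- function(series, ss, roi_name = "GTV-1", regex = FALSE) {
  uids <- gtv1_slice_uids(series, ss, roi_name, regex)
  nm <- names(ss$rois)
  hit <- if (regex) grep(roi_name, nm)[1] else which(nm == roi_name)[1]
  contours <- ss$rois[[hit]]
  series_uids <- vapply(series$slices, `[[`, "", "sop_instance_uid")
  masks <- lapply(uids, function(u) {
    sl <- series$slices[[match(u, series_uids)]]
    cs <- Filter(function(ct) identical(ct$referenced_sop_uid, u) ||
                   (is.na(ct$referenced_sop_uid) && nrow(ct$points_mm) > 0 &&
                    abs(ct$points_mm[1, 3] - sl$z_position) <= sl$slice_thickness / 2),
                 contours)
    mm <- lapply(cs, rasterize_contour, slice_meta = sl)
    um <- union_masks(mm)
    um$sop_uid <- u
    um
  })
  structure(list(patient_id = series$patient_id, masks = masks),
            class = "tumor_mask_stack")
}

#' Normalize a stored-value image to byte range
#'
#' Min-max normalization of a DICOM pixel array to integers in `[0, 255]`:
#' `round((dcm - min) / (max - min) * 255)`. With `strict = TRUE` the
#' denominator is `max(dcm)` alone (the historical convention this mirrors),
#' clipped into `[0, 255]`; that variant over- or under-shoots whenever the
#' minimum is nonzero, so the range-normalizing default is recommended. A
#' constant image maps to all zeros with a warning (division guard).
#'
#' @param pixel_array numeric matrix of stored values (or HU).
#' @param strict use the `max`-only denominator.
#' @return integer matrix with values in `[0, 255]`.
#' @export
dicom_to_byte_image <- function(pixel_array, strict = FALSE) {
  lo <- min(pixel_array); hi <- max(pixel_array)
  if (hi == lo) {
    warning("constant pixel array; returning zeros", call. = FALSE)
    return(matrix(0L, nrow(pixel_array), ncol(pixel_array)))
  }
  denom <- if (strict) hi else hi - lo
  if (denom == 0) {
    warning("zero dynamic range under strict normalization; returning zeros",
            call. = FALSE)
    return(matrix(0L, nrow(pixel_array), ncol(pixel_array)))
  }
  out <- round((pixel_array - lo) / denom * 255)
  out <- pmin(255, pmax(0, out))
  matrix(as.integer(out), nrow(pixel_array), ncol(pixel_array))
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("<tumor_mask>", x$sop_uid, "- area", x$area_px, "px")
  if (!is.null(x$bbox))
    cat("; bbox [", paste(x$bbox, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' @export
print.tumor_mask_stack <- function(x, ...) {
  cat("<tumor_mask_stack> patient", x$patient_id, "-", length(x$masks),
      "GTV slices; areas:",
      paste(vapply(x$masks, `[[`, 0L, "area_px"), collapse = " "), "\n")
  invisible(x)
}
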