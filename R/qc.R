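# Segmentation quality control: three defect classes are handled --
# mislabeled tumors (flagged only), area collapses from inter-slice
# interpolation artifacts (repaired by shape-based interpolation), and
# multi-region slices (reduced to the dominant laterality).

#' Detect sudden area collapses in a mask stack
#'
#' An interior slice is flagged when its tumor area drops below `tau` times
#' the smaller of its two neighbors' areas. Natural cranio-caudal tapering
#' is monotone toward the tumor ends, so it never triggers this rule; a
#' near-collapsed slice sandwiched between two large ones does. First and
#' last slices are never flagged.
#'
#' @param stack a `tumor_mask_stack`.
#' @param tau ratio threshold in (0, 1); default 0.5.
#' @return character vector of flagged SOP instance UIDs.
#' @export
detect_area_jumps <- function(stack, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  areas <- vapply(stack$masks, `[[`, 0L, "area_px")
  n <- length(areas)
  if (n < 3L) return(character(0))
  i <- 2:(n - 1)
  flagged <- i[areas[i] < tau * pmin(areas[i - 1], areas[i + 1])]
  vapply(stack$masks[flagged], `[[`, "", "sop_uid")
}

.signed_distance <- function(mask) {
  m <- mask * 1
  inside <- EBImage::distmap(m)
  outside <- EBImage::distmap(1 - m)
  as.matrix(inside) - as.matrix(outside)
}

#' Shape-based interpolation between two masks
#'
#' Reconstructs the shape halfway between two binary masks by averaging
#' their signed Euclidean distance transforms and thresholding at zero. For
#' nested shapes (the usual tumor taper) the result lies between the two
#' neighbors; for identical neighbors it reproduces them exactly. If one
#' neighbor is empty the non-empty one is copied.
#'
#' @param prev,nxt `tumor_mask` objects of identical shape.
#' @return interpolated `tumor_mask` (the `sop_uid` is left `NA`; callers
#'   assign the repaired slice's uid).
#' @export
interpolate_mask <- function(prev, nxt) {
  if (!identical(dim(prev$mask), dim(nxt$mask)))
    ctsurv_abort("mask shapes differ", "ctsurv_shape_mismatch")
  if (prev$area_px == 0L && nxt$area_px == 0L)
    ctsurv_abort("both neighbors empty; cannot interpolate", "ctsurv_empty_neighbors")
  if (prev$area_px == 0L) return(.new_tumor_mask(NA_character_, nxt$mask))
  if (nxt$area_px == 0L) return(.new_tumor_mask(NA_character_, prev$mask))
  sdt <- (.signed_distance(prev$mask) + .signed_distance(nxt$mask)) / 2
  .new_tumor_mask(NA_character_, sdt > 0)
}

.component_table <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.matrix(lab)
  k <- max(lab)
  if (k == 0L) return(NULL)
  do.call(rbind, lapply(seq_len(k), function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    data.frame(component = i, area = nrow(w),
               row = mean(w[, 1]), col = mean(w[, 2]))
  }))
}

# Dominant side of a stack: larger summed area across all slices, split at
# the image vertical midline; ties broken by the side of the largest single
# connected component anywhere in the stack (then left).
.dominant_side <- function(history) {
  mid <- ncol(history$masks[[1]]$mask) / 2
  left <- 0; right <- 0
  best_area <- -1; best_side <- "left"
  for (m in history$masks) {
    ct <- .component_table(m$mask)
    if (is.null(ct)) next
    sides <- ifelse(ct$col <= mid, "left", "right")
    left <- left + sum(ct$area[sides == "left"])
    right <- right + sum(ct$area[sides == "right"])
    j <- which.max(ct$area)
    if (ct$area[j] > best_area) {
      best_area <- ct$area[j]; best_side <- sides[j]
    }
  }
  if (left > right) "left" else if (right > left) "right" else best_side
}

#' Keep only the dominant-laterality components of a mask
#'
#' For a slice showing more than one tumor region, keeps the connected
#' components whose centroids lie on the patient's dominant side -- the side
#' (split at the image vertical midline) with the larger summed tumor area
#' across the whole stack. Single-component masks are returned unchanged.
#' A summed-area tie goes to the side holding the largest single component.
#'
#' @param mask a `tumor_mask`.
#' @param history the patient's full `tumor_mask_stack`.
#' @return a `tumor_mask` restricted to the dominant side.
#' @export
select_laterality <- function(mask, history) {
  ct <- .component_table(mask$mask)
  if (is.null(ct) || nrow(ct) < 2L) return(mask)
  side <- .dominant_side(history)
  mid <- ncol(mask$mask) / 2
  keep <- if (side == "left") ct$component[ct$col <= mid]
          else ct$component[ct$col > mid]
  if (length(keep) == 0L) return(mask)  # nothing on dominant side: leave as is
  lab <- as.matrix(EBImage::bwlabel(mask$mask * 1))
  out <- .new_tumor_mask(mask$sop_uid, matrix(lab %in% keep, nrow(lab)))
  out
}

#' Run segmentation QC over a patient's mask stack
#'
#' Applies, in order: laterality selection on multi-region slices (flag
#' `multi_tumor`), area-collapse detection at threshold `tau` with repair by
#' [interpolate_mask()] between the nearest unflagged neighbors (flag
#' `area_jump`), and -- when lung masks are supplied -- a mislabel heuristic
#' flagging slices whose tumor centroid falls outside both lungs (flag
#' `mislabel`, never repaired: the defect cannot be verified
#' automatically). The operation is idempotent: a clean or repaired stack
#' passes through unchanged, and repair never changes the number of tumor
#' slices.
#'
#' @param stack a `tumor_mask_stack`.
#' @param tau area-collapse threshold, see [detect_area_jumps()].
#' @param lung_masks optional named list mapping SOP instance UID to a
#'   logical matrix of the union of both lung ROIs on that slice.
#' @return list with `stack` (repaired `tumor_mask_stack`) and `report`, a
#'   `qc_report` holding `flags` (data.frame `sop_uid`, `error_class`,
#'   `detail`) and `repaired` (uids).
#' @export
run_qc <- function(stack, tau = 0.5, lung_masks = NULL) {
  flags <- data.frame(sop_uid = character(0), error_class = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  add_flag <- function(uid, cls, detail) {
    flags[nrow(flags) + 1L, ] <<- list(uid, cls, detail)
  }
  masks <- stack$masks
  # 1) multi-region slices -> dominant laterality
  for (i in seq_along(masks)) {
    ct <- .component_table(masks[[i]]$mask)
    if (!is.null(ct) && nrow(ct) >= 2L) {
      fixed <- select_laterality(masks[[i]], stack)
      if (fixed$area_px != masks[[i]]$area_px)
        add_flag(masks[[i]]$sop_uid, "multi_tumor",
                 sprintf("%d components; kept dominant side", nrow(ct)))
      masks[[i]] <- fixed
    }
  }
  work <- structure(list(patient_id = stack$patient_id, masks = masks),
                    class = "tumor_mask_stack")
  # 2) area collapses -> shape interpolation between nearest clean neighbors
  jump_uids <- detect_area_jumps(work, tau)
  uids <- vapply(masks, `[[`, "", "sop_uid")
  bad <- uids %in% jump_uids
  repaired <- character(0)
  for (i in which(bad)) {
    lo <- max(which(!bad[seq_len(i - 1L)]))
    hi <- i + min(which(!bad[(i + 1L):length(bad)]))
    rep_mask <- interpolate_mask(masks[[lo]], masks[[hi]])
    rep_mask$sop_uid <- uids[i]
    masks[[i]] <- rep_mask
    add_flag(uids[i], "area_jump",
             sprintf("area below %.2f of neighbors; repaired by interpolation", tau))
    repaired <- c(repaired, uids[i])
  }
  # 3) mislabel heuristic (flag only)
  if (!is.null(lung_masks)) {
    for (m in masks) {
      lm <- lung_masks[[m$sop_uid]]
      if (is.null(lm) || is.null(m$centroid_px)) next
      r <- round(m$centroid_px[1]); c <- round(m$centroid_px[2])
      if (!isTRUE(lm[r, c]))
        add_flag(m$sop_uid, "mislabel", "tumor centroid outside both lungs")
    }
  }
  out <- structure(list(patient_id = stack$patient_id, masks = masks),
                   class = "tumor_mask_stack")
  report <- structure(list(patient_id = stack$patient_id, flags = flags,
                           repaired = repaired), class = "qc_report")
  list(stack = out, report = report)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(report, path) {
  df <- report$flags
  df <- cbind(patient_id = rep(report$patient_id, nrow(df)), df,
              repaired = df$sop_uid %in% report$repaired)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> patient", x$patient_id, "-", nrow(x$flags), "flag(s),",
      length(x$repaired), "repaired\n")
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}
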