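# Synthetic cohort generator: fully self-contained DICOM CT series +
# RTSTRUCT structure sets + clinical CSV + ground-truth manifest, emulating
# the structure of a radiotherapy NSCLC cohort so the whole pipeline is
# testable offline. Tumors are ellipsoids polygonized per slice; anatomy
# (body, lungs, cord) is analytic; survival is Weibull with log-scale
# linear in the tumor's slice extent (longer cranio-caudal extent, shorter
# survival).

#' Specification for a synthetic cohort
#'
#' @param n_patients number of patients.
#' @param slices_range range of per-patient slice counts (real cohorts run
#'   75-297; the default is scaled down so fixtures stay fast).
#' @param gtv1_range range of GTV-1 slice counts (2-97 at full scale).
#' @param image_size in-plane pixels (512 at full scale; 128 keeps fixtures
#'   small while exercising the same mm-to-pixel geometry).
#' @param pixel_spacing mm per pixel (row = col), default 0.977.
#' @param slice_thickness mm between slices, default 3.0.
#' @param n_vertices vertices per polygonized contour (32 keeps the
#'   cross-section area error under 5 percent).
#' @param roi_set ROI names to emit besides GTV-1.
#' @param survival_params list `shape`, `b0`, `b1` of the Weibull survival
#'   model `T ~ Weibull(shape, scale = exp(b0 + b1 * slice_count))`.
#' @param censoring_rate expected fraction of censored patients (0.114
#'   mirrors the reference cohort).
#' @param noise_sd HU noise added to the CT images.
#' @param patients optional list of per-patient overrides (by index):
#'   `n_slices`, `gtv1_block = c(lo, hi)` (slice indices), `side`,
#'   `errors` (subset of `"area_jump"`, `"multi_tumor"`, `"mislabel"`),
#'   `roi_counts` (named contour counts for non-GTV-1 ROIs),
#'   `geometry_only` (omit image references from GTV-1 contours).
#' @param seed RNG seed; the emitted tree is byte-identical for a fixed
#'   spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_patients = 5L, slices_range = c(12L, 20L),
                         gtv1_range = c(3L, 9L), image_size = 128L,
                         pixel_spacing = 0.977, slice_thickness = 3.0,
                         n_vertices = 32L,
                         roi_set = c("Lung-Left", "Lung-Right", "Spinal-Cord"),
                         survival_params = list(shape = 1.3, b0 = 7.0,
                                                b1 = -0.12),
                         censoring_rate = 0.114, noise_sd = 15,
                         patients = NULL, seed = 1L) {
  structure(as.list(environment()), class = "fixture_spec")
}

.ellipse_poly <- function(cx, cy, a, b, z, n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + a * cos(t), cy + b * sin(t), z)
}

# Fixed anatomy in mm (image frame centred at 0): body, lungs, spinal cord.
.anatomy <- list(
  body = c(0, 0, 55, 50),
  lung_left = c(-27, -5, 17, 28),   # patient right on image left by x sign
  lung_right = c(27, -5, 17, 28),
  cord = c(0, 38, 5, 5)
)

.in_ellipse <- function(xg, yg, e) {
  ((xg - e[1]) / e[3])^2 + ((yg - e[2]) / e[4])^2 <= 1
}

#' Survival and censoring generator
#'
#' Draws survival times from a Weibull whose log scale is linear in the
#' tumor slice extent (negative coefficient: thicker tumors, shorter
#' survival). Censoring is Bernoulli at `censoring_rate`; a censored
#' patient reports a uniform fraction of the true survival time as
#' follow-up.
#'
#' @param tumor_extent vector of GTV-1 slice counts.
#' @param params list `shape`, `b0`, `b1`.
#' @param censoring_rate probability a patient is censored.
#' @param seed optional seed.
#' @return data.frame `survival_time` (days, >= 1), `deadstatus_event`.
#' @export
survival_generator <- function(tumor_extent,
                               params = list(shape = 1.3, b0 = 7.0,
                                             b1 = -0.12),
                               censoring_rate = 0.114, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tumor_extent)
  tt <- stats::rweibull(n, shape = params$shape,
                        scale = exp(params$b0 + params$b1 * tumor_extent))
  cens <- stats::rbinom(n, 1L, censoring_rate)
  fu <- tt * stats::runif(n, 0.15, 0.95)
  data.frame(survival_time = pmax(1, round(ifelse(cens == 1L, fu, tt))),
             deadstatus_event = 1L - cens)
}

#' Shrink one GTV-1 contour to emulate an interpolation artifact
#'
#' Scales the contour of the given GTV-1 slice about its centroid,
#' producing the sudden area collapse the QC stage must detect; the
#' original contour is kept in the patient's manifest entry as repair
#' ground truth. The slice must be interior to the GTV-1 block.
#'
#' @param patient an internal patient fixture (element of a generated
#'   cohort before writing, as produced inside [make_cohort()]).
#' @param slice_index index within the patient's GTV-1 slice list.
#' @param shrink_factor linear scale factor in (0, 1]; 1 is a no-op.
#' @return the modified patient fixture.
#' @export
inject_area_jump <- function(patient, slice_index, shrink_factor = 0.2) {
  k <- length(patient$gtv1)
  if (slice_index <= 1L || slice_index >= k)
    ctsurv_abort("area-jump injection requires an interior GTV-1 slice",
                 "ctsurv_bad_injection")
  if (shrink_factor == 1) return(patient)
  regions <- patient$gtv1[[slice_index]]$regions
  patient$manifest$injected$area_jump <- list(
    gtv_index = slice_index,
    slice_index = patient$gtv1[[slice_index]]$slice,
    shrink_factor = shrink_factor,
    original_regions = lapply(regions, function(m) unname(as.vector(t(m))))
  )
  patient$gtv1[[slice_index]]$regions <- lapply(regions, function(pts) {
    cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
    cbind(cx + (pts[, 1] - cx) * shrink_factor,
          cy + (pts[, 2] - cy) * shrink_factor, pts[, 3])
  })
  patient
}

.gen_patient <- function(spec, idx, pid, ov) {
  ov <- ov %||% list()
  n_slices <- ov$n_slices %||%
    sample(spec$slices_range[1]:spec$slices_range[2], 1L)
  thick <- spec$slice_thickness
  z0 <- -500 + round(stats::runif(1, 0, 50))
  z <- z0 + (seq_len(n_slices) - 1L) * thick
  if (!is.null(ov$gtv1_block)) {
    lo <- as.integer(ov$gtv1_block[1]); hi <- as.integer(ov$gtv1_block[2])
  } else {
    k <- sample(spec$gtv1_range[1]:min(spec$gtv1_range[2], n_slices - 2L), 1L)
    lo <- sample(2L:(n_slices - k), 1L)
    hi <- lo + k - 1L
  }
  k <- hi - lo + 1L
  # ellipsoid centre/extent chosen so exactly slices lo..hi intersect it
  c_ax <- 1.5 * k
  cz <- if (k %% 2L == 1L) z[lo + (k - 1L) %/% 2L] else z[lo + k %/% 2L - 1L] + 1.5
  errors <- ov$errors %||% character(0)
  side <- ov$side %||% sample(c("left", "right"), 1L)
  lung <- if (side == "left") .anatomy$lung_left else .anatomy$lung_right
  if ("mislabel" %in% errors) {
    cx <- 0; cy <- 42   # outside both lungs, inside the body
  } else {
    cx <- lung[1] + stats::runif(1, -4, 4)
    cy <- lung[2] + stats::runif(1, -6, 6)
  }
  ab <- stats::runif(2, 9, 16)
  gtv1 <- lapply(lo:hi, function(s) {
    rz <- sqrt(max(0, 1 - ((z[s] - cz) / c_ax)^2))
    list(slice = s,
         regions = list(.ellipse_poly(cx, cy, ab[1] * rz, ab[2] * rz, z[s],
                                      spec$n_vertices)))
  })
  if ("multi_tumor" %in% errors) {
    other <- if (side == "left") .anatomy$lung_right else .anatomy$lung_left
    for (i in seq_along(gtv1)) {
      s <- gtv1[[i]]$slice
      rz <- sqrt(max(0, 1 - ((z[s] - cz) / c_ax)^2))
      gtv1[[i]]$regions <- c(gtv1[[i]]$regions, list(
        .ellipse_poly(other[1], other[2], 0.55 * ab[1] * rz,
                      0.55 * ab[2] * rz, z[s], spec$n_vertices)))
    }
  }
  px_area <- spec$pixel_spacing^2
  primary_areas_px <- vapply(gtv1, function(g) {
    rz <- sqrt(max(0, 1 - ((z[g$slice] - cz) / c_ax)^2))
    pi * ab[1] * ab[2] * rz^2 / px_area
  }, 0)
  p <- list(
    idx = idx, patient_id = pid, n_slices = n_slices, z = z,
    gtv1 = gtv1, side = side, errors = errors,
    geometry_only = isTRUE(ov$geometry_only),
    roi_counts = ov$roi_counts,
    manifest = list(
      patient_id = pid, n_slices = n_slices,
      gtv1_slice_count = k, gtv1_slices = lo:hi,
      tumor_center_mm = c(cx, cy, cz),
      tumor_semiaxes_mm = c(ab[1], ab[2], c_ax),
      side = side,
      expected_areas_px = primary_areas_px,
      errors = as.list(errors),
      injected = list()
    )
  )
  if ("area_jump" %in% errors) {
    mid <- (k %/% 2L) + 1L
    p <- inject_area_jump(p, mid, ov$shrink_factor %||% 0.2)
  }
  p
}

.patient_uids <- function(idx, n_slices) {
  base <- paste0("1.2.826.0.1.3680043.9999.", idx)
  list(study = paste0(base, ".1"),
       series = paste0(base, ".2"),
       slices = paste0(base, ".3.", seq_len(n_slices)),
       rtstruct = paste0(base, ".4"))
}

.ct_pixels <- function(spec, p, s) {
  npx <- spec$image_size
  x0 <- -npx * spec$pixel_spacing / 2
  xg_v <- x0 + (seq_len(npx) - 1L) * spec$pixel_spacing
  xg <- matrix(xg_v, npx, npx, byrow = TRUE)   # columns are x
  yg <- matrix(xg_v, npx, npx)                 # rows are y
  hu <- matrix(-1000, npx, npx)
  hu[.in_ellipse(xg, yg, .anatomy$body)] <- 0
  hu[.in_ellipse(xg, yg, .anatomy$lung_left)] <- -800
  hu[.in_ellipse(xg, yg, .anatomy$lung_right)] <- -800
  hu[.in_ellipse(xg, yg, .anatomy$cord)] <- 40
  gi <- which(vapply(p$gtv1, function(g) g$slice == s, TRUE))
  if (length(gi) == 1L) {
    for (pts in p$gtv1[[gi]]$regions) {
      cxr <- mean(pts[, 1]); cyr <- mean(pts[, 2])
      a <- (max(pts[, 1]) - min(pts[, 1])) / 2
      b <- (max(pts[, 2]) - min(pts[, 2])) / 2
      if (a > 0 && b > 0)
        hu[.in_ellipse(xg, yg, c(cxr, cyr, a, b))] <- 60
    }
  }
  hu <- hu + matrix(stats::rnorm(npx * npx, sd = spec$noise_sd), npx)
  matrix(as.integer(pmax(-1024, pmin(3071, round(hu)))), npx, npx)
}

.write_ct_slice <- function(path, spec, pid, uids, s, z_s, pixels) {
  npx <- spec$image_size
  x0 <- -npx * spec$pixel_spacing / 2
  dcm_write(path, .dcm_uid$ct_image, uids$slices[s], list(
    SOPClassUID = .dcm_uid$ct_image,
    SOPInstanceUID = uids$slices[s],
    Modality = "CT",
    PatientName = pid, PatientID = pid,
    StudyInstanceUID = uids$study, SeriesInstanceUID = uids$series,
    InstanceNumber = s,
    ImagePositionPatient = c(x0, x0, z_s),
    ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
    SliceLocation = z_s,
    SliceThickness = spec$slice_thickness,
    PixelSpacing = c(spec$pixel_spacing, spec$pixel_spacing),
    SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
    Rows = npx, Columns = npx,
    BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
    PixelRepresentation = 1L,
    RescaleIntercept = -1024, RescaleSlope = 1,
    # pixel data row-major: transpose the column-major R matrix
    PixelData = as.integer(t(pixels + 1024L))
  ))
}

# Build contour items for a non-tumor ROI: `count` contours spread over the
# slices (one per slice, extras added as second regions on early slices).
.roi_contours <- function(roi, count, spec, p, uids) {
  e <- switch(roi,
    "Lung-Left" = .anatomy$lung_left, "Lung-Right" = .anatomy$lung_right,
    "Spinal-Cord" = .anatomy$cord, "Esophagus" = c(0, 20, 4, 4),
    "GTV-2" = c(.anatomy$lung_right[1], 15, 6, 6))
  n_s <- p$n_slices
  slices <- rep(seq_len(n_s), length.out = max(count, 0L))
  lapply(seq_len(count), function(j) {
    s <- slices[j]
    off <- if (j > n_s) 0.7 else 1           # extras: shrunken second region
    list(uid = uids$slices[s],
         pts = .ellipse_poly(e[1], e[2], e[3] * off, e[4] * off,
                             p$z[s], min(spec$n_vertices, 16L)))
  })
}

.write_rtstruct <- function(path, spec, p, uids) {
  rois <- list()
  counts <- p$roi_counts
  for (roi in spec$roi_set) {
    cnt <- if (!is.null(counts) && roi %in% names(counts)) counts[[roi]]
           else if (roi %in% c("Lung-Left", "Lung-Right")) p$n_slices
           else if (roi == "Spinal-Cord") p$n_slices
           else 0L
    if (cnt > 0L) rois[[roi]] <- .roi_contours(roi, cnt, spec, p, uids)
  }
  rois[["GTV-1"]] <- do.call(c, lapply(p$gtv1, function(g) {
    lapply(g$regions, function(pts)
      list(uid = if (p$geometry_only) NULL else uids$slices[g$slice],
           pts = pts))
  }))
  roi_names <- names(rois)
  ssr <- lapply(seq_along(roi_names), function(i)
    list(ROINumber = i, ROIName = roi_names[i]))
  rcs <- lapply(seq_along(roi_names), function(i) {
    cs <- lapply(rois[[i]], function(ct) {
      item <- list(ContourGeometricType = "CLOSED_PLANAR",
                   NumberOfContourPoints = nrow(ct$pts),
                   ContourData = as.vector(t(ct$pts)))
      if (!is.null(ct$uid))
        item$ContourImageSequence <- list(list(
          ReferencedSOPClassUID = .dcm_uid$ct_image,
          ReferencedSOPInstanceUID = ct$uid))
      item
    })
    list(ReferencedROINumber = i, ContourSequence = cs)
  })
  dcm_write(path, .dcm_uid$rtstruct, uids$rtstruct, list(
    SOPClassUID = .dcm_uid$rtstruct,
    SOPInstanceUID = uids$rtstruct,
    Modality = "RTSTRUCT",
    PatientName = p$patient_id, PatientID = p$patient_id,
    StudyInstanceUID = uids$study,
    StructureSetLabel = "SYNTHETIC",
    StructureSetROISequence = ssr,
    ROIContourSequence = rcs
  ))
}

#' Generate a synthetic cohort on disk
#'
#' Emits, per patient, a folder `CT/` of axial DICOM slices and
#' `RTSTRUCT/rtstruct.dcm`, plus a cohort-level `clinical.csv` (reference
#' column names) and `manifest.json` holding the ground truth (GTV-1 slice
#' counts and indices, analytic per-slice areas, injected-error locations
#' with pre-corruption contours, survival truth). Output is reproducible:
#' the same spec yields a byte-identical tree.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
make_cohort <- function(spec, dir) {
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = spec$seed, patients = list())
  clin <- NULL
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("SYN-%03d", i)
    ov <- if (!is.null(spec$patients) && length(spec$patients) >= i)
      spec$patients[[i]] else NULL
    p <- .gen_patient(spec, i, pid, ov)
    uids <- .patient_uids(i, p$n_slices)
    ct_dir <- file.path(dir, pid, "CT")
    dir.create(ct_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, pid, "RTSTRUCT"), showWarnings = FALSE)
    for (s in seq_len(p$n_slices))
      .write_ct_slice(file.path(ct_dir, sprintf("ct_%03d.dcm", s)),
                      spec, pid, uids, s, p$z[s], .ct_pixels(spec, p, s))
    .write_rtstruct(file.path(dir, pid, "RTSTRUCT", "rtstruct.dcm"),
                    spec, p, uids)
    sv <- survival_generator(p$manifest$gtv1_slice_count,
                             spec$survival_params, spec$censoring_rate)
    p$manifest$survival_time <- sv$survival_time
    p$manifest$deadstatus_event <- sv$deadstatus_event
    manifest$patients[[pid]] <- p$manifest
    clin <- rbind(clin, data.frame(
      PatientID = pid,
      age = round(stats::rnorm(1, 68, 9), 1),
      `clinical.T.Stage` = sample(1:4, 1L),
      `Clinical.N.Stage` = sample(0:3, 1L),
      `Clinical.M.Stage` = sample(0:1, 1L, prob = c(0.9, 0.1)),
      `Overall.Stage` = sample(c("I", "II", "IIIa", "IIIb"), 1L),
      Histology = sample(c("adenocarcinoma", "large cell",
                           "squamous cell carcinoma", "nos"), 1L),
      gender = sample(c("male", "female"), 1L),
      `Survival.time` = sv$survival_time,
      `deadstatus.event` = sv$deadstatus_event,
      check.names = FALSE, stringsAsFactors = FALSE
    ))
  }
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a cohort manifest
#'
#' @param dir a [make_cohort()] output directory.
#' @return the manifest list.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
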