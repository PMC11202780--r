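# Segmentation QC: area-collapse detection, shape interpolation,
# laterality selection, full QC pass.

test_that("area-collapse detection flags interior drops only", {
  mk <- function(areas) mask_stack(lapply(seq_along(areas), function(i)
    mk_square_mask(paste0("u", i), round(sqrt(areas[i])))))
  # a near-collapsed slice between two large neighbors
  st <- mask_stack(list(mk_square_mask("u1", 14),   # 196 px
                        mk_square_mask("u2", 4),    # 16 px
                        mk_square_mask("u3", 14)))
  expect_identical(detect_area_jumps(st, 0.5), "u2")
  # monotone growth never triggers
  st2 <- mk(c(50, 100, 150))
  expect_length(detect_area_jumps(st2, 0.5), 0L)
  # two separate collapses both flagged; ends never flagged
  st3 <- mask_stack(list(mk_square_mask("u1", 14), mk_square_mask("u2", 4),
                         mk_square_mask("u3", 15), mk_square_mask("u4", 4),
                         mk_square_mask("u5", 14)))
  expect_identical(detect_area_jumps(st3, 0.5), c("u2", "u4"))
  expect_length(detect_area_jumps(mask_stack(list(mk_square_mask("a", 3),
                                                  mk_square_mask("b", 3))),
                                  0.5), 0L)
})

test_that("shape interpolation reduces to neighbors for identical or empty input", {
  d <- disk_mask(64, 12)
  same <- interpolate_mask(d, d)
  expect_identical(same$mask, d$mask)
  empty <- ctsurv:::.new_tumor_mask("e", matrix(FALSE, 64, 64))
  expect_identical(interpolate_mask(empty, d)$mask, d$mask)
  expect_identical(interpolate_mask(d, empty)$mask, d$mask)
  expect_error(interpolate_mask(empty, empty), class = "ctsurv_empty_neighbors")
})

test_that("interpolating concentric disks recovers the mid-radius disk", {
  a <- disk_mask(64, 10)
  b <- disk_mask(64, 20)
  mid <- interpolate_mask(a, b)
  want <- disk_mask(64, 15)
  expect_gt(dice(mid$mask, want$mask), 0.95)
  expect_true(mid$area_px > a$area_px && mid$area_px < b$area_px)
})

test_that("laterality selection keeps the dominant side deterministically", {
  bi <- function(l_side, r_side, uid = "u") {
    m <- matrix(FALSE, 64, 64)
    m[20:(19 + l_side), 10:(9 + l_side)] <- TRUE      # left of midline (col 32)
    m[20:(19 + r_side), 40:(39 + r_side)] <- TRUE
    ctsurv:::.new_tumor_mask(uid, m)
  }
  # right side dominates the stack's summed area
  hist_r <- mask_stack(list(bi(10, 20), bi(10, 20), bi(10, 20)))
  kept <- select_laterality(hist_r$masks[[1]], hist_r)
  w <- which(kept$mask, arr.ind = TRUE)
  expect_true(all(w[, 2] > 32))
  expect_identical(kept$area_px, 400L)
  # single component passes through unchanged
  single <- mk_square_mask("s", 5)
  expect_identical(select_laterality(single, mask_stack(list(single))), single)
  # summed-area tie resolves to the side of the largest single component
  tie <- mask_stack(list(bi(14, 14)))  # equal sums, equal largest: left wins
  kept2 <- select_laterality(tie$masks[[1]], tie)
  expect_true(all(which(kept2$mask, arr.ind = TRUE)[, 2] <= 32))
  tie2 <- mask_stack(list(bi(10, 14), bi(14, 10)))  # sums tie, largest on right
  kept3 <- select_laterality(tie2$masks[[1]], tie2)
  expect_true(all(which(kept3$mask, arr.ind = TRUE)[, 2] > 32))
})

test_that("run_qc leaves clean stacks untouched and is idempotent", {
  co <- cached_cohort("basic", fixture_spec(n_patients = 2, seed = 7))
  series <- read_ct_series(file.path(co$dir, "SYN-001", "CT"))
  ss <- read_structure_set(file.path(co$dir, "SYN-001", "RTSTRUCT",
                                     "rtstruct.dcm"))
  masks <- build_mask_stack(series, ss)
  r1 <- run_qc(masks)
  expect_identical(nrow(r1$report$flags), 0L)
  expect_identical(lapply(r1$stack$masks, `[[`, "mask"),
                   lapply(masks$masks, `[[`, "mask"))
  r2 <- run_qc(r1$stack)
  expect_identical(nrow(r2$report$flags), 0L)
})

test_that("run_qc repairs injected collapses and keeps the slice count", {
  dir <- file.path(tempdir(), "ctsurv-qc1")
  unlink(dir, recursive = TRUE)
  man <- make_cohort(fixture_spec(n_patients = 1, gtv1_range = c(7, 9),
                                  seed = 3,
                                  patients = list(list(errors = "area_jump"))),
                     dir)
  m <- man$patients[["SYN-001"]]
  series <- read_ct_series(file.path(dir, "SYN-001", "CT"))
  ss <- read_structure_set(file.path(dir, "SYN-001", "RTSTRUCT", "rtstruct.dcm"))
  masks <- build_mask_stack(series, ss)
  qc <- run_qc(masks)
  inj <- m$injected$area_jump
  uid_inj <- masks$masks[[inj$gtv_index]]$sop_uid
  expect_identical(qc$report$repaired, uid_inj)
  # every repaired uid carries an area_jump flag (report invariant)
  expect_true(all(qc$report$repaired %in%
                  qc$report$flags$sop_uid[qc$report$flags$error_class == "area_jump"]))
  expect_identical(length(qc$stack$masks), length(masks$masks))
  # repaired mask close to the pre-corruption ground truth
  orig_pts <- matrix(unlist(inj$original_regions[[1]]), ncol = 3, byrow = TRUE)
  orig <- rasterize_contour(list(referenced_sop_uid = NA, points_mm = orig_pts),
                            series$slices[[inj$slice_index]])
  expect_gt(dice(orig$mask, qc$stack$masks[[inj$gtv_index]]$mask), 0.9)
  # second pass finds nothing (idempotence on repaired stacks)
  expect_identical(nrow(run_qc(qc$stack)$report$flags), 0L)
})

test_that("bilateral fixtures lose the secondary side on every slice", {
  dir <- file.path(tempdir(), "ctsurv-qc2")
  unlink(dir, recursive = TRUE)
  man <- make_cohort(fixture_spec(n_patients = 1, seed = 9,
                                  patients = list(list(errors = "multi_tumor",
                                                       side = "left"))),
                     dir)
  series <- read_ct_series(file.path(dir, "SYN-001", "CT"))
  ss <- read_structure_set(file.path(dir, "SYN-001", "RTSTRUCT", "rtstruct.dcm"))
  masks <- build_mask_stack(series, ss)
  expect_true(all(vapply(masks$masks, function(m)
    max(EBImage::bwlabel(m$mask * 1)) >= 2, TRUE)))
  qc <- run_qc(masks)
  expect_true(all(qc$report$flags$error_class == "multi_tumor"))
  expect_identical(nrow(qc$report$flags), length(masks$masks))
  mid <- 64  # 128-px fixtures: midline column
  for (m in qc$stack$masks) {
    expect_equal(max(EBImage::bwlabel(m$mask * 1)), 1)
    expect_true(all(which(m$mask, arr.ind = TRUE)[, 2] <= mid))
  }
})

test_that("mislabeled tumors are flagged but never altered", {
  dir <- file.path(tempdir(), "ctsurv-qc3")
  unlink(dir, recursive = TRUE)
  make_cohort(fixture_spec(n_patients = 1, seed = 21,
                           patients = list(list(errors = "mislabel"))), dir)
  r <- process_patient(file.path(dir, "SYN-001"))
  expect_true("mislabel" %in% r$qc$flags$error_class)
  expect_length(r$qc$repaired, 0L)
})
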