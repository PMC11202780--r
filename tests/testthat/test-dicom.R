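# DICOM codec and CT / RTSTRUCT ingestion.

test_that("written CT files round-trip through the reader", {
  co <- cached_cohort("basic", fixture_spec(n_patients = 2, seed = 7))
  series <- read_ct_series(file.path(co$dir, "SYN-001", "CT"))
  man <- co$manifest$patients[["SYN-001"]]
  expect_s3_class(series, "ct_series")
  expect_length(series$slices, man$n_slices)
  s1 <- series$slices[[1]]
  expect_identical(s1$slice_thickness, 3.0)
  expect_identical(s1$pixel_spacing, c(0.977, 0.977))
  expect_identical(dim(s1$pixel_array), c(128L, 128L))
  z <- vapply(series$slices, `[[`, 0, "z_position")
  expect_true(all(diff(z) > 0))
  expect_equal(diff(z), rep(3, man$n_slices - 1L))
  # HU conversion applies slope/intercept lazily
  hu <- slice_hu(s1)
  expect_equal(hu, s1$pixel_array * 1 + (-1024))
})

test_that("reader sorts slices by z regardless of file order and skips junk", {
  co <- cached_cohort("basic", fixture_spec(n_patients = 2, seed = 7))
  src <- file.path(co$dir, "SYN-002", "CT")
  shuffled <- file.path(tempdir(), "shuffled-ct")
  unlink(shuffled, recursive = TRUE)
  dir.create(shuffled)
  files <- list.files(src, full.names = TRUE)
  set.seed(42)
  for (i in sample(seq_along(files)))
    file.copy(files[i], file.path(shuffled, sprintf("zz_%s.dcm",
                                                    substr(tools::md5sum(files[i]), 1, 8))))
  writeLines("not a dicom file", file.path(shuffled, "README.txt"))
  expect_warning(series <- read_ct_series(shuffled), "non-DICOM")
  z <- vapply(series$slices, `[[`, 0, "z_position")
  expect_true(all(diff(z) > 0))
  expect_length(series$slices, co$manifest$patients[["SYN-002"]]$n_slices)
})

test_that("missing required tags and duplicate UIDs are structured errors", {
  d <- file.path(tempdir(), "bad-ct")
  unlink(d, recursive = TRUE); dir.create(d)
  # a CT missing SliceThickness
  dcm_write(file.path(d, "a.dcm"), ctsurv:::.dcm_uid$ct_image, "1.2.3.1", list(
    SOPClassUID = ctsurv:::.dcm_uid$ct_image, SOPInstanceUID = "1.2.3.1",
    Modality = "CT", PatientID = "X",
    ImagePositionPatient = c(0, 0, 0), PixelSpacing = c(1, 1),
    RescaleIntercept = 0, RescaleSlope = 1,
    Rows = 4L, Columns = 4L, BitsAllocated = 16L, BitsStored = 16L,
    HighBit = 15L, PixelRepresentation = 0L,
    PixelData = rep(0L, 16)
  ))
  err <- tryCatch(read_ct_series(d), error = identity)
  expect_s3_class(err, "ctsurv_missing_tag")
  expect_match(conditionMessage(err), "SliceThickness")
  expect_match(conditionMessage(err), "a\\.dcm")
  # duplicate SOP UIDs
  d2 <- file.path(tempdir(), "dup-ct")
  unlink(d2, recursive = TRUE); dir.create(d2)
  for (f in c("a.dcm", "b.dcm"))
    dcm_write(file.path(d2, f), ctsurv:::.dcm_uid$ct_image, "1.2.3.9", list(
      SOPClassUID = ctsurv:::.dcm_uid$ct_image, SOPInstanceUID = "1.2.3.9",
      Modality = "CT", PatientID = "X", SliceThickness = 3,
      ImagePositionPatient = c(0, 0, 0), PixelSpacing = c(1, 1),
      RescaleIntercept = 0, RescaleSlope = 1,
      Rows = 4L, Columns = 4L, BitsAllocated = 16L, BitsStored = 16L,
      HighBit = 15L, PixelRepresentation = 0L, PixelData = rep(0L, 16)
    ))
  expect_error(read_ct_series(d2), class = "ctsurv_duplicate_uid")
})

test_that("structure sets expose every declared ROI with grouped contours", {
  co <- cached_cohort("basic", fixture_spec(n_patients = 2, seed = 7))
  man <- co$manifest$patients[["SYN-001"]]
  ss <- read_structure_set(file.path(co$dir, "SYN-001", "RTSTRUCT",
                                     "rtstruct.dcm"))
  expect_setequal(names(ss$rois),
                  c("Lung-Left", "Lung-Right", "Spinal-Cord", "GTV-1"))
  inv <- structure_inventory(ss)
  expect_identical(inv$contour_count[inv$roi_name == "GTV-1"],
                   man$gtv1_slice_count)
  expect_identical(inv$contour_count[inv$roi_name == "Lung-Left"],
                   man$n_slices)
  # inventory invariant under contour order permutation
  set.seed(1)
  ss2 <- ss
  ss2$rois <- lapply(ss2$rois, function(cs) cs[sample(length(cs))])
  expect_identical(structure_inventory(ss2)$contour_count, inv$contour_count)
})

test_that("an RTSTRUCT with zero ROIs yields an empty map, declared-but-empty ROIs warn", {
  p <- file.path(tempdir(), "empty-rs.dcm")
  dcm_write(p, ctsurv:::.dcm_uid$rtstruct, "1.2.9", list(
    SOPClassUID = ctsurv:::.dcm_uid$rtstruct, SOPInstanceUID = "1.2.9",
    Modality = "RTSTRUCT", PatientID = "X",
    StructureSetROISequence = list(), ROIContourSequence = list()
  ))
  ss <- read_structure_set(p)
  expect_length(ss$rois, 0L)
  expect_identical(nrow(structure_inventory(ss)), 0L)
  p2 <- file.path(tempdir(), "declared-rs.dcm")
  dcm_write(p2, ctsurv:::.dcm_uid$rtstruct, "1.2.10", list(
    SOPClassUID = ctsurv:::.dcm_uid$rtstruct, SOPInstanceUID = "1.2.10",
    Modality = "RTSTRUCT", PatientID = "X",
    StructureSetROISequence = list(list(ROINumber = 1L, ROIName = "GTV-1")),
    ROIContourSequence = list()
  ))
  expect_warning(ss2 <- read_structure_set(p2), "without contours")
  expect_identical(names(ss2$rois), "GTV-1")
  expect_length(ss2$rois[["GTV-1"]], 0L)
})

test_that("GTV-1 slice UIDs are the z-ordered series intersection, deduplicated", {
  co <- cached_cohort("basic", fixture_spec(n_patients = 2, seed = 7))
  series <- read_ct_series(file.path(co$dir, "SYN-001", "CT"))
  ss <- read_structure_set(file.path(co$dir, "SYN-001", "RTSTRUCT",
                                     "rtstruct.dcm"))
  man <- co$manifest$patients[["SYN-001"]]
  uids <- gtv1_slice_uids(series, ss)
  series_uids <- vapply(series$slices, `[[`, "", "sop_instance_uid")
  expect_length(uids, man$gtv1_slice_count)
  expect_true(all(uids %in% series_uids))
  expect_identical(match(uids, series_uids), as.integer(man$gtv1_slices))
  # a contour referencing a foreign UID is dropped with a warning
  ss_bad <- ss
  ss_bad$rois[["GTV-1"]][[1]]$referenced_sop_uid <- "1.999.not.in.series"
  expect_warning(uids2 <- gtv1_slice_uids(series, ss_bad), "not found")
  expect_length(uids2, man$gtv1_slice_count - 1L)
  # two contours on one slice count once
  ss_dup <- ss
  ss_dup$rois[["GTV-1"]] <- c(ss_dup$rois[["GTV-1"]],
                              ss_dup$rois[["GTV-1"]][1])
  expect_identical(gtv1_slice_uids(series, ss_dup), uids)
  # absence of the ROI is a structured exclusion error
  ss_none <- ss
  names(ss_none$rois)[names(ss_none$rois) == "GTV-1"] <- "GTV-9"
  expect_error(gtv1_slice_uids(series, ss_none), class = "ctsurv_no_gtv1")
  expect_length(gtv1_slice_uids(series, ss_none, roi_name = "^GTV",
                                regex = TRUE), man$gtv1_slice_count)
})

test_that("geometry-only contours fall back to nearest-z matching", {
  dir <- file.path(tempdir(), "ctsurv-geomonly")
  unlink(dir, recursive = TRUE)
  man <- make_cohort(fixture_spec(n_patients = 1, seed = 13,
                                  patients = list(list(geometry_only = TRUE))),
                     dir)
  series <- read_ct_series(file.path(dir, "SYN-001", "CT"))
  ss <- read_structure_set(file.path(dir, "SYN-001", "RTSTRUCT",
                                     "rtstruct.dcm"))
  expect_true(all(is.na(vapply(ss$rois[["GTV-1"]], `[[`, "",
                               "referenced_sop_uid"))))
  w <- capture_warnings(uids <- gtv1_slice_uids(series, ss))
  expect_true(all(grepl("matched to slice by z", w)))  # one per contour
  expect_length(uids, man$patients[["SYN-001"]]$gtv1_slice_count)
})

test_that("the writer's output is readable by an independent DICOM implementation", {
  co <- cached_cohort("basic", fixture_spec(n_patients = 2, seed = 7))
  ct <- list.files(file.path(co$dir, "SYN-001", "CT"), full.names = TRUE)[3]
  rs <- file.path(co$dir, "SYN-001", "RTSTRUCT", "rtstruct.dcm")
  script <- tempfile(fileext = ".py")
  out_implicit <- tempfile(fileext = ".dcm")
  writeLines(c(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.SOPInstanceUID)",
    "print(float(ds.SliceThickness)); print(float(ds.PixelSpacing[0]))",
    "print(int(ds.pixel_array.sum()))",
    "rs = pydicom.dcmread(sys.argv[2])",
    "print(','.join(r.ROIName for r in rs.StructureSetROISequence))",
    "# re-encode the CT as implicit VR little endian",
    "ds.file_meta.TransferSyntaxUID = pydicom.uid.ImplicitVRLittleEndian",
    "ds.is_implicit_VR = True; ds.is_little_endian = True",
    "ds.save_as(sys.argv[3], enforce_file_format=True)"
  ), script)
  res <- system2("python", c(script, ct, rs, out_implicit), stdout = TRUE)
  ours <- dcm_read(ct)
  expect_identical(res[1], ours$SOPInstanceUID)
  expect_equal(as.numeric(res[2]), ours$SliceThickness)
  expect_equal(as.numeric(res[3]), ours$PixelSpacing[1])
  px <- ctsurv:::.decode_pixels(ours)   # stored values, no rescale applied
  expect_identical(as.numeric(res[4]), as.numeric(sum(px)))
  expect_identical(res[5], "Lung-Left,Lung-Right,Spinal-Cord,GTV-1")
  # and our reader parses the implicit-VR re-encoding identically
  imp <- dcm_read(out_implicit)
  expect_identical(imp$SOPInstanceUID, ours$SOPInstanceUID)
  expect_identical(ctsurv:::.decode_pixels(imp), px)
})
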