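#' @useDynLib ctsurv, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal DICOM Part-10 codec. Covers exactly the attributes a radiotherapy
# CT + RTSTRUCT pipeline needs (image geometry, rescale, pixel data, and the
# structure-set sequences); explicit and implicit VR little endian on read,
# explicit VR little endian on write. Compressed transfer syntaxes are out
# of scope and rejected.

.dcm_dict <- local({
  d <- rbind(
    c(0x0002L, 0x0000L, "UL", "FileMetaInformationGroupLength"),
    c(0x0002L, 0x0001L, "OB", "FileMetaInformationVersion"),
    c(0x0002L, 0x0002L, "UI", "MediaStorageSOPClassUID"),
    c(0x0002L, 0x0003L, "UI", "MediaStorageSOPInstanceUID"),
    c(0x0002L, 0x0010L, "UI", "TransferSyntaxUID"),
    c(0x0002L, 0x0012L, "UI", "ImplementationClassUID"),
    c(0x0008L, 0x0016L, "UI", "SOPClassUID"),
    c(0x0008L, 0x0018L, "UI", "SOPInstanceUID"),
    c(0x0008L, 0x0060L, "CS", "Modality"),
    c(0x0008L, 0x1150L, "UI", "ReferencedSOPClassUID"),
    c(0x0008L, 0x1155L, "UI", "ReferencedSOPInstanceUID"),
    c(0x0010L, 0x0010L, "PN", "PatientName"),
    c(0x0010L, 0x0020L, "LO", "PatientID"),
    c(0x0018L, 0x0050L, "DS", "SliceThickness"),
    c(0x0020L, 0x000DL, "UI", "StudyInstanceUID"),
    c(0x0020L, 0x000EL, "UI", "SeriesInstanceUID"),
    c(0x0020L, 0x0013L, "IS", "InstanceNumber"),
    c(0x0020L, 0x0032L, "DS", "ImagePositionPatient"),
    c(0x0020L, 0x0037L, "DS", "ImageOrientationPatient"),
    c(0x0020L, 0x1041L, "DS", "SliceLocation"),
    c(0x0028L, 0x0002L, "US", "SamplesPerPixel"),
    c(0x0028L, 0x0004L, "CS", "PhotometricInterpretation"),
    c(0x0028L, 0x0010L, "US", "Rows"),
    c(0x0028L, 0x0011L, "US", "Columns"),
    c(0x0028L, 0x0030L, "DS", "PixelSpacing"),
    c(0x0028L, 0x0100L, "US", "BitsAllocated"),
    c(0x0028L, 0x0101L, "US", "BitsStored"),
    c(0x0028L, 0x0102L, "US", "HighBit"),
    c(0x0028L, 0x0103L, "US", "PixelRepresentation"),
    c(0x0028L, 0x1052L, "DS", "RescaleIntercept"),
    c(0x0028L, 0x1053L, "DS", "RescaleSlope"),
    c(0x3006L, 0x0002L, "SH", "StructureSetLabel"),
    c(0x3006L, 0x0016L, "SQ", "ContourImageSequence"),
    c(0x3006L, 0x0020L, "SQ", "StructureSetROISequence"),
    c(0x3006L, 0x0022L, "IS", "ROINumber"),
    c(0x3006L, 0x0026L, "LO", "ROIName"),
    c(0x3006L, 0x0039L, "SQ", "ROIContourSequence"),
    c(0x3006L, 0x0040L, "SQ", "ContourSequence"),
    c(0x3006L, 0x0042L, "CS", "ContourGeometricType"),
    c(0x3006L, 0x0046L, "IS", "NumberOfContourPoints"),
    c(0x3006L, 0x0050L, "DS", "ContourData"),
    c(0x3006L, 0x0084L, "IS", "ReferencedROINumber"),
    c(0x7FE0L, 0x0010L, "OW", "PixelData")
  )
  df <- data.frame(group = strtoi(d[, 1]), elem = strtoi(d[, 2]),
                   vr = d[, 3], keyword = d[, 4], stringsAsFactors = FALSE)
  df$key <- sprintf("%04X%04X", df$group, df$elem)
  df
})

.dcm_uid <- list(
  explicit_le = "1.2.840.10008.1.2.1",
  implicit_le = "1.2.840.10008.1.2",
  ct_image    = "1.2.840.10008.5.1.4.1.1.2",
  rtstruct    = "1.2.840.10008.5.1.4.1.1.481.3",
  implementation = "1.2.826.0.1.3680043.9.7433.1"
)

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

ctsurv_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ctsurv_error")))
}

.u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}
.u32 <- function(buf, pos) {
  # read as double to survive lengths >= 2^31
  v <- readBin(buf[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 4294967296
  v
}

.enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.pad_even <- function(r, pad_byte) {
  if (length(r) %% 2L == 1L) c(r, pad_byte) else r
}

.encode_value <- function(vr, value) {
  switch(vr,
    UI = .pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0L)),
    LO = , SH = , CS = , PN = , DA = , TM = , ST =
      .pad_even(charToRaw(paste(value, collapse = "\\")), charToRaw(" ")),
    DS = .pad_even(charToRaw(paste(vapply(value, .fmt_ds, ""), collapse = "\\")),
                   charToRaw(" ")),
    IS = .pad_even(charToRaw(paste(as.integer(value), collapse = "\\")),
                   charToRaw(" ")),
    US = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = .enc_u32(value),
    OB = .pad_even(as.raw(value), as.raw(0L)),
    OW = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    stop("unsupported VR for writing: ", vr)
  )
}

.fmt_ds <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  if (nchar(s) > 16L) s <- substr(s, 1L, 16L)
  s
}

.encode_element <- function(group, elem, vr, body) {
  head <- c(.enc_u16(group), .enc_u16(elem))
  if (vr %in% .long_vrs) {
    c(head, charToRaw(vr), as.raw(c(0L, 0L)), .enc_u32(length(body)), body)
  } else {
    c(head, charToRaw(vr), .enc_u16(length(body)), body)
  }
}

# Encode a dataset given as a named list keyword -> value; SQ values are
# unnamed lists of item datasets (named lists again). Elements are emitted
# in ascending tag order, as DICOM requires.
.encode_dataset <- function(elements) {
  kw <- names(elements)
  rows <- match(kw, .dcm_dict$keyword)
  if (anyNA(rows)) stop("unknown DICOM keyword(s): ",
                        paste(kw[is.na(rows)], collapse = ", "))
  ord <- order(.dcm_dict$group[rows], .dcm_dict$elem[rows])
  parts <- lapply(ord, function(i) {
    r <- rows[i]; vr <- .dcm_dict$vr[r]
    if (vr == "SQ") {
      items <- lapply(elements[[i]], function(item) {
        body <- .encode_dataset(item)
        c(.enc_u16(0xFFFEL), .enc_u16(0xE000L), .enc_u32(length(body)), body)
      })
      body <- do.call(c, c(items, list(raw(0))))
    } else {
      body <- .encode_value(vr, elements[[i]])
    }
    .encode_element(.dcm_dict$group[r], .dcm_dict$elem[r], vr, body)
  })
  do.call(c, c(parts, list(raw(0))))
}

#' Write a DICOM Part-10 file (explicit VR little endian)
#'
#' Low-level writer used by the synthetic cohort generator. `elements` is a
#' named list mapping DICOM keywords (the subset this package knows) to
#' values; sequence attributes take an unnamed list of item datasets.
#'
#' @param path output file path.
#' @param sop_class_uid,sop_instance_uid media-storage identifiers for the
#'   file meta group.
#' @param elements named list of dataset attributes.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
dcm_write <- function(path, sop_class_uid, sop_instance_uid, elements) {
  meta <- list(
    FileMetaInformationVersion = c(0L, 1L),
    MediaStorageSOPClassUID    = sop_class_uid,
    MediaStorageSOPInstanceUID = sop_instance_uid,
    TransferSyntaxUID          = .dcm_uid$explicit_le,
    ImplementationClassUID     = .dcm_uid$implementation
  )
  meta_raw <- .encode_dataset(meta)
  grplen <- .encode_element(0x0002L, 0x0000L, "UL", .enc_u32(length(meta_raw)))
  body <- .encode_dataset(elements)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), grplen, meta_raw, body), con)
  invisible(path)
}

.decode_value <- function(vr, bytes) {
  txt <- function() {
    b <- bytes  # strip trailing NUL/space padding before conversion
    while (length(b) && (b[length(b)] == as.raw(0L) || b[length(b)] == as.raw(0x20L)))
      b <- b[-length(b)]
    rawToChar(b)
  }
  switch(vr,
    UI = , LO = , SH = , CS = , PN = , DA = , TM = , ST =
      strsplit(txt(), "\\", fixed = TRUE)[[1]],
    DS = as.numeric(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
    US = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 endian = "little", signed = FALSE),
    UL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    OB = bytes,
    OW = bytes,  # decoded by the caller, which knows PixelRepresentation
    bytes
  )
}

# Parse one dataset from buf[pos..end]; returns list(elements, pos).
# stop_at_item_delim: used when parsing undefined-length sequence items.
.parse_dataset <- function(buf, pos, end, explicit, stop_at_item_delim = FALSE) {
  out <- list()
  while (pos <= end) {
    group <- .u16(buf, pos); elem <- .u16(buf, pos + 2L); pos <- pos + 4L
    if (group == 0xFFFEL) {  # delimitation items
      len <- .u32(buf, pos); pos <- pos + 4L
      if (elem == 0xE00DL && stop_at_item_delim) break
      if (elem == 0xE0DDL) break
      next
    }
    key <- sprintf("%04X%04X", group, elem)
    row <- match(key, .dcm_dict$key)
    if (explicit) {
      vr <- rawToChar(buf[pos:(pos + 1L)]); pos <- pos + 2L
      if (vr %in% .long_vrs) {
        len <- .u32(buf, pos + 2L); pos <- pos + 6L
      } else {
        len <- .u16(buf, pos); pos <- pos + 2L
      }
    } else {
      len <- .u32(buf, pos); pos <- pos + 4L
      vr <- if (!is.na(row)) .dcm_dict$vr[row] else "UN"
    }
    undefined <- (len == 4294967295)
    if (vr == "SQ" || (undefined && vr == "UN")) {
      sq_end <- if (undefined) end else pos + len - 1L
      items <- list()
      while (pos <= sq_end) {
        ig <- .u16(buf, pos); ie <- .u16(buf, pos + 2L)
        ilen <- .u32(buf, pos + 4L); pos <- pos + 8L
        if (ig == 0xFFFEL && ie == 0xE0DDL) break
        if (!(ig == 0xFFFEL && ie == 0xE000L))
          ctsurv_abort("malformed sequence item", "ctsurv_dicom_parse")
        if (ilen == 4294967295) {
          r <- .parse_dataset(buf, pos, sq_end, explicit, stop_at_item_delim = TRUE)
        } else {
          r <- .parse_dataset(buf, pos, pos + ilen - 1L, explicit)
          r$pos <- pos + ilen
        }
        items[[length(items) + 1L]] <- r$elements
        pos <- r$pos
      }
      if (!is.na(row)) out[[.dcm_dict$keyword[row]]] <- items
    } else {
      if (undefined)
        ctsurv_abort("undefined-length non-sequence element (encapsulated pixel data?) not supported",
                     "ctsurv_dicom_parse")
      bytes <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      if (!is.na(row)) out[[.dcm_dict$keyword[row]]] <- .decode_value(vr, bytes)
    }
  }
  list(elements = out, pos = pos)
}

#' Read a DICOM Part-10 file
#'
#' Parses the file meta group and main dataset (explicit or implicit VR
#' little endian) into a named list keyed by DICOM keyword. Attributes
#' outside this package's dictionary are skipped. `PixelData` is returned as
#' raw bytes; [read_ct_series()] decodes it using `BitsAllocated` /
#' `PixelRepresentation`.
#'
#' @param path DICOM file path.
#' @return named list of attributes, with the file meta group in
#'   `attr(, "meta")`.
#' @keywords internal
#' @export
dcm_read <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140)
    ctsurv_abort(paste0("not a DICOM file: ", path), "ctsurv_not_dicom")
  buf <- readBin(path, raw(), n = n)
  if (rawToChar(buf[129:132]) != "DICM")
    ctsurv_abort(paste0("not a DICOM file (missing DICM magic): ", path),
                 "ctsurv_not_dicom")
  pos <- 133L
  # file meta group is always explicit VR LE; (0002,0000) gives its length
  grp <- .u16(buf, pos); el <- .u16(buf, pos + 2L)
  if (grp != 0x0002L || el != 0x0000L)
    ctsurv_abort(paste0("missing file meta group length: ", path),
                 "ctsurv_dicom_parse")
  meta_len <- .u32(buf, pos + 8L)
  pos <- pos + 12L
  meta <- .parse_dataset(buf, pos, pos + meta_len - 1L, explicit = TRUE)$elements
  pos <- pos + meta_len
  ts <- meta$TransferSyntaxUID
  if (is.null(ts)) ts <- .dcm_uid$explicit_le
  if (!ts %in% c(.dcm_uid$explicit_le, .dcm_uid$implicit_le))
    ctsurv_abort(paste0("unsupported transfer syntax ", ts, " in ", path),
                 "ctsurv_dicom_parse")
  ds <- .parse_dataset(buf, pos, n, explicit = (ts == .dcm_uid$explicit_le))$elements
  attr(ds, "meta") <- meta
  ds
}

# Decode OW pixel bytes into an integer matrix (Rows x Columns), honouring
# PixelRepresentation (two's complement when 1).
.decode_pixels <- function(ds, path = "<dataset>") {
  for (k in c("PixelData", "Rows", "Columns", "BitsAllocated")) {
    if (is.null(ds[[k]]))
      ctsurv_abort(paste0("missing required tag ", k, " in ", path),
                   "ctsurv_missing_tag", tag = k, file = path)
  }
  if (ds$BitsAllocated != 16L)
    ctsurv_abort(paste0("only 16-bit pixel data supported (", path, ")"),
                 "ctsurv_dicom_parse")
  v <- readBin(ds$PixelData, "integer", n = length(ds$PixelData) / 2L,
               size = 2L, endian = "little", signed = FALSE)
  if (isTRUE(ds$PixelRepresentation == 1L)) {
    v <- ifelse(v > 32767L, v - 65536L, v)
  }
  # DICOM pixel data is row-major (row by row); R matrices are column-major
  matrix(v, nrow = ds$Rows, ncol = ds$Columns, byrow = TRUE)
}
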