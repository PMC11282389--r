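# Minimal DICOM Part 10 reader/writer (explicit VR little endian).
#
# The conversion pipeline is header-driven: it never touches pixel values
# beyond skipping them. Only the explicit-VR little-endian transfer syntax
# (1.2.840.10008.1.2.1) is parsed; files in other transfer syntaxes are
# quarantined by the ingest layer rather than mis-read.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

# VRs whose on-disk form uses a 2-byte reserved field and 4-byte length.
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' DICOM tag dictionary used by the package
#'
#' The subset of the DICOM data dictionary this package reads and writes:
#' file-meta tags, patient identifiers (for de-identification), and the
#' study/series attributes stored in the imaging tables.
#'
#' @return A data.frame with columns `group`, `element` (integers),
#'   `vr` and `keyword`.
#' @export
dicom_dictionary <- function() {
  d <- rbind(
    c(0x0002, 0x0000, "UL", "FileMetaInformationGroupLength"),
    c(0x0002, 0x0001, "OB", "FileMetaInformationVersion"),
    c(0x0002, 0x0002, "UI", "MediaStorageSOPClassUID"),
    c(0x0002, 0x0003, "UI", "MediaStorageSOPInstanceUID"),
    c(0x0002, 0x0010, "UI", "TransferSyntaxUID"),
    c(0x0002, 0x0012, "UI", "ImplementationClassUID"),
    c(0x0008, 0x0016, "UI", "SOPClassUID"),
    c(0x0008, 0x0018, "UI", "SOPInstanceUID"),
    c(0x0008, 0x0020, "DA", "StudyDate"),
    c(0x0008, 0x0060, "CS", "Modality"),
    c(0x0008, 0x0070, "LO", "Manufacturer"),
    c(0x0008, 0x103E, "LO", "SeriesDescription"),
    c(0x0010, 0x0010, "PN", "PatientName"),
    c(0x0010, 0x0020, "LO", "PatientID"),
    c(0x0010, 0x0030, "DA", "PatientBirthDate"),
    c(0x0010, 0x0040, "CS", "PatientSex"),
    c(0x0010, 0x1000, "LO", "OtherPatientIDs"),
    c(0x0010, 0x1040, "LO", "PatientAddress"),
    c(0x0010, 0x2154, "SH", "PatientTelephoneNumbers"),
    c(0x0018, 0x0015, "CS", "BodyPartExamined"),
    c(0x0018, 0x0024, "SH", "SequenceName"),
    c(0x0018, 0x0050, "DS", "SliceThickness"),
    c(0x0018, 0x5100, "CS", "PatientPosition"),
    c(0x0020, 0x000D, "UI", "StudyInstanceUID"),
    c(0x0020, 0x000E, "UI", "SeriesInstanceUID"),
    c(0x0020, 0x0011, "IS", "SeriesNumber"),
    c(0x0020, 0x0060, "CS", "Laterality"),
    c(0x0028, 0x0002, "US", "SamplesPerPixel"),
    c(0x0028, 0x0004, "CS", "PhotometricInterpretation"),
    c(0x0028, 0x0010, "US", "Rows"),
    c(0x0028, 0x0011, "US", "Columns"),
    c(0x0028, 0x0100, "US", "BitsAllocated"),
    c(0x0028, 0x0101, "US", "BitsStored"),
    c(0x0028, 0x0102, "US", "HighBit"),
    c(0x0028, 0x0103, "US", "PixelRepresentation"),
    c(0x0028, 0x1050, "DS", "WindowCenter"),
    c(0x0028, 0x1051, "DS", "WindowWidth"),
    c(0x7FE0, 0x0010, "OW", "PixelData")
  )
  data.frame(
    group = strtoi(d[, 1]), element = strtoi(d[, 2]),
    vr = d[, 3], keyword = d[, 4], stringsAsFactors = FALSE
  )
}

.dicom_dict_env <- new.env(parent = emptyenv())

.dict <- function() {
  if (is.null(.dicom_dict_env$dict)) {
    d <- dicom_dictionary()
    d$key <- paste(d$group, d$element)
    .dicom_dict_env$dict <- d
    .dicom_dict_env$by_keyword <- stats::setNames(seq_len(nrow(d)), d$keyword)
  }
  .dicom_dict_env$dict
}

.uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.encode_value <- function(vr, value) {
  if (vr %in% c("US")) {
    return(writeBin(as.integer(value), raw(), size = 2, endian = "little"))
  }
  if (vr %in% c("UL")) {
    return(writeBin(as.integer(value), raw(), size = 4, endian = "little"))
  }
  if (vr %in% c("OB", "OW")) {
    v <- as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0))
    return(v)
  }
  v <- charToRaw(enc2utf8(paste(value, collapse = "\\")))
  if (length(v) %% 2L == 1L) {
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  v
}

.encode_element <- function(group, element, vr, value) {
  payload <- .encode_value(vr, value)
  hdr <- c(.uint16(group), .uint16(element), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0, 0)), .uint32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("value too long for short-form VR ", vr)
    c(hdr, .uint16(length(payload)), payload)
  }
}

#' Write a DICOM Part 10 file
#'
#' Serializes a named list of DICOM attributes (names are dictionary
#' keywords) into a Part 10 file in explicit VR little endian, with a
#' conformant file meta group and, unless supplied, a tiny 8x8 monochrome
#' pixel payload so that the file is a complete composite object.
#'
#' @param path Output file path.
#' @param elements Named list, keyword -> value. `SOPInstanceUID`,
#'   `StudyInstanceUID` and `SeriesInstanceUID` are required.
#' @param pixel_rows,pixel_cols Dimensions of the generated pixel payload.
#' @return `path`, invisibly.
#' @export
dicom_write <- function(path, elements, pixel_rows = 8L, pixel_cols = 8L) {
  dict <- .dict()
  for (req in c("SOPInstanceUID", "StudyInstanceUID", "SeriesInstanceUID")) {
    if (is.null(elements[[req]])) stop("missing required element ", req)
  }
  defaults <- list(
    SOPClassUID = SOP_CLASS_SECONDARY_CAPTURE,
    SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
    Rows = pixel_rows, Columns = pixel_cols,
    BitsAllocated = 8L, BitsStored = 8L, HighBit = 7L, PixelRepresentation = 0L
  )
  for (k in names(defaults)) {
    if (is.null(elements[[k]])) elements[[k]] <- defaults[[k]]
  }
  # The payload is kept at pixel_rows x pixel_cols regardless of the Rows /
  # Columns header attributes: the pipeline is header-driven and never
  # decodes pixels, and fixtures must stay desk-scale.
  if (is.null(elements$PixelData)) {
    elements$PixelData <- as.raw(seq_len(pixel_rows * pixel_cols) %% 256L)
  }

  idx <- .dicom_dict_env$by_keyword[names(elements)]
  if (anyNA(idx)) {
    stop("keywords not in package dictionary: ",
         paste(names(elements)[is.na(idx)], collapse = ", "))
  }
  rows <- dict[idx, ]
  ord <- order(rows$group, rows$element)
  body <- raw(0)
  for (i in ord) {
    if (rows$group[i] == 0x0002) next  # file meta is built below
    body <- c(body, .encode_element(rows$group[i], rows$element[i],
                                    rows$vr[i], elements[[rows$keyword[i]]]))
  }

  meta_elems <- c(
    .encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .encode_element(0x0002, 0x0002, "UI", elements$SOPClassUID),
    .encode_element(0x0002, 0x0003, "UI", elements$SOPInstanceUID),
    .encode_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    .encode_element(0x0002, 0x0012, "UI", "2.25.8412963")
  )
  meta <- c(.encode_element(0x0002, 0x0000, "UL", length(meta_elems)), meta_elems)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

#' Read the header of a DICOM Part 10 file
#'
#' Parses the file meta group and the explicit-VR little-endian data set,
#' returning dictionary-known attributes as strings. Pixel data is skipped,
#' never loaded. Files that are not Part 10, or use a transfer syntax other
#' than explicit VR little endian, raise an error of class
#' `icdm_dicom_error` (the ingest layer turns these into quarantine
#' records).
#'
#' @param path File to read.
#' @return Named list: `values` (named character vector of attribute
#'   strings), `transfer_syntax`, `path`.
#' @export
dicom_read <- function(path) {
  n_file <- file.info(path)$size
  if (is.na(n_file) || n_file < 140) {
    stop(.dicom_error(path, "file too small to be DICOM Part 10"))
  }
  buf <- readBin(path, "raw", n = n_file)
  if (rawToChar(buf[129:132]) != "DICM") {
    stop(.dicom_error(path, "missing DICM magic"))
  }
  dict <- .dict()
  pos <- 133L
  values <- character(0)
  transfer_syntax <- NA_character_

  read_u16 <- function(p) {
    as.integer(buf[p]) + 256L * as.integer(buf[p + 1L])
  }
  read_u32 <- function(p) {
    as.integer(buf[p]) + 256 * as.integer(buf[p + 1L]) +
      65536 * as.integer(buf[p + 2L]) + 16777216 * as.integer(buf[p + 3L])
  }

  while (pos + 7L <= n_file + 1L && pos + 7L <= length(buf) + 1L) {
    group <- read_u16(pos)
    element <- read_u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop(.dicom_error(path, sprintf(
        "unparseable VR at offset %d (implicit VR or corrupt stream)", pos - 1L)))
    }
    if (vr %in% .long_vrs) {
      len <- read_u32(pos + 8L)
      data_start <- pos + 12L
    } else {
      len <- read_u16(pos + 6L)
      data_start <- pos + 8L
    }
    if (len == 4294967295) {
      stop(.dicom_error(path, "undefined-length element not supported"))
    }
    if (group == 0x7FE0 && element == 0x0010) break  # stop before pixels
    if (data_start + len - 1L > length(buf)) {
      stop(.dicom_error(path, "truncated element"))
    }
    hit <- which(dict$group == group & dict$element == element)
    if (length(hit) == 1L && !(vr %in% c("SQ", "UN"))) {
      kw <- dict$keyword[hit]
      raw_val <- if (len > 0) buf[data_start:(data_start + len - 1L)] else raw(0)
      val <- if (vr == "US") {
        paste(readBin(raw_val, "integer", n = len %/% 2L, size = 2,
                      signed = FALSE, endian = "little"), collapse = "\\")
      } else if (vr == "UL") {
        paste(readBin(raw_val, "integer", n = len %/% 4L, size = 4,
                      endian = "little"), collapse = "\\")
      } else if (vr %in% c("OB", "OW", "OF")) {
        NA_character_
      } else {
        while (length(raw_val) && raw_val[length(raw_val)] == as.raw(0)) {
          raw_val <- raw_val[-length(raw_val)]
        }
        sub(" +$", "", rawToChar(raw_val))
      }
      if (!is.na(val)) {
        values[[kw]] <- val
        if (kw == "TransferSyntaxUID") transfer_syntax <- val
      }
    }
    pos <- data_start + len
    if (group > 0x0002 && !is.na(transfer_syntax) &&
        transfer_syntax != TRANSFER_SYNTAX_EXPLICIT_LE) {
      stop(.dicom_error(path, paste("unsupported transfer syntax", transfer_syntax)))
    }
  }
  if (is.na(transfer_syntax)) {
    stop(.dicom_error(path, "no TransferSyntaxUID in file meta"))
  }
  list(values = values, transfer_syntax = transfer_syntax, path = path)
}

.dicom_error <- function(path, reason) {
  structure(
    class = c("icdm_dicom_error", "error", "condition"),
    list(message = sprintf("%s: %s", path, reason), call = NULL, path = path,
         reason = reason)
  )
}
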