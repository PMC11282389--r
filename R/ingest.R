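# Directory scanning, configured header extraction (nonempty tags only),
# de-identification, and grouping of instances into the study/series
# hierarchy. Malformed files are quarantined, never fatal: an archive-scale
# ETL must survive dirty input.

#' Default DICOM tag extraction configuration
#'
#' Covers the attributes stored in the imaging tables plus the study date,
#' the instance UIDs and the patient identifier. `level` is `"study"`,
#' `"series"` (persisted as EAV rows) or `"aux"` (used by the pipeline but
#' not persisted as a series attribute).
#'
#' @return A data.frame with columns `keyword`, `attribute`, `class`
#'   (`numeric`, `coded`, `text`, `date`), `level`.
#' @export
default_tag_config <- function() {
  e <- rbind(
    c("Modality", "modality", "coded", "study"),
    c("Manufacturer", "manufacturer", "text", "study"),
    c("StudyDate", "study_date", "date", "study"),
    c("SliceThickness", "slice_thickness", "numeric", "series"),
    c("Rows", "rows", "numeric", "series"),
    c("Columns", "columns", "numeric", "series"),
    c("WindowCenter", "window_center", "numeric", "series"),
    c("WindowWidth", "window_width", "numeric", "series"),
    c("BodyPartExamined", "body_part_examined", "coded", "series"),
    c("Laterality", "laterality", "coded", "series"),
    c("PatientPosition", "patient_position", "coded", "series"),
    c("SeriesDescription", "series_description", "text", "series"),
    c("SeriesNumber", "series_number", "numeric", "aux"),
    c("SequenceName", "sequence_name", "text", "aux"),
    c("PatientID", "patient_id", "text", "aux")
  )
  cfg <- data.frame(keyword = e[, 1], attribute = e[, 2], class = e[, 3],
                    level = e[, 4], stringsAsFactors = FALSE)
  validate_tag_config(cfg)
  cfg
}

#' Validate a tag configuration
#' @param cfg A tag-config data.frame.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_tag_config <- function(cfg) {
  stopifnot(all(c("keyword", "attribute", "class", "level") %in% names(cfg)))
  if (anyDuplicated(cfg$attribute)) stop("tag config: duplicate attribute names")
  bad_class <- setdiff(cfg$class, c("numeric", "coded", "text", "date"))
  if (length(bad_class)) stop("tag config: unknown value class ", bad_class)
  series_attrs <- cfg$attribute[cfg$level == "series"]
  unknown <- setdiff(series_attrs, names(series_attribute_registry()))
  if (length(unknown)) {
    stop("tag config: series-level attributes not in registry: ",
         paste(unknown, collapse = ", "))
  }
  invisible(cfg)
}

#' Scan a directory tree for DICOM files
#'
#' @param root Directory to scan.
#' @param pattern Filename regex for candidate files (case-insensitive).
#' @return Character vector of paths in deterministic lexicographic order,
#'   with attribute `n_skipped` counting non-matching files.
#' @export
scan_directory <- function(root, pattern = "\\.dcm$") {
  if (!dir.exists(root)) stop("directory does not exist: ", root)
  all_files <- list.files(root, recursive = TRUE, full.names = TRUE)
  hits <- all_files[grepl(pattern, all_files, ignore.case = TRUE)]
  hits <- sort(hits, method = "radix")
  structure(hits, n_skipped = length(all_files) - length(hits))
}

.quarantine <- function(file, reason) {
  structure(list(file_path = file, reason = reason), class = "icdm_quarantine")
}

#' Is this object a quarantine record?
#' @param x Object to test.
#' @export
is_quarantined <- function(x) inherits(x, "icdm_quarantine")

.numeric_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

#' Read configured header attributes from one DICOM file
#'
#' Extracts exactly the configured tags that are present and nonempty,
#' preserving raw strings verbatim. A numeric/date-class value that fails
#' validation is kept as text and recorded as a warning on the record.
#' Unreadable files and files missing Study/SeriesInstanceUID come back as
#' quarantine records.
#'
#' @param file Path to a DICOM Part 10 file.
#' @param config Tag configuration, by default [default_tag_config()].
#' @return A header record (list: `file_path`, `study_uid`, `series_uid`,
#'   `sop_uid`, `values`, `pixel_free`, `warnings`, `deidentified`) or a
#'   quarantine record.
#' @export
read_headers <- function(file, config = default_tag_config()) {
  h <- tryCatch(dicom_read(file), icdm_dicom_error = function(e) e)
  if (inherits(h, "icdm_dicom_error")) return(.quarantine(file, h$reason))
  raw_vals <- h$values
  getv <- function(k) if (k %in% names(raw_vals)) raw_vals[[k]] else NA_character_
  if (.is_blank(getv("StudyInstanceUID")) ||
      .is_blank(getv("SeriesInstanceUID"))) {
    return(.quarantine(file, "missing StudyInstanceUID or SeriesInstanceUID"))
  }
  values <- character(0)
  warns <- character(0)
  for (i in seq_len(nrow(config))) {
    kw <- config$keyword[i]
    val <- getv(kw)
    if (is.na(val) || !nzchar(val)) next  # nonempty-only rule
    cls <- config$class[i]
    if (cls == "numeric" && !grepl(.numeric_re, trimws(val))) {
      warns <- c(warns, sprintf("%s: value %s fails numeric validation, kept as text",
                                config$attribute[i], val))
    }
    if (cls == "date" && !grepl("^\\d{8}$", trimws(val))) {
      warns <- c(warns, sprintf("%s: value %s fails DICOM DA validation, kept as text",
                                config$attribute[i], val))
    }
    values[[config$attribute[i]]] <- val
  }
  list(file_path = file,
       study_uid = getv("StudyInstanceUID"),
       series_uid = getv("SeriesInstanceUID"),
       sop_uid = getv("SOPInstanceUID"),
       values = values, pixel_free = TRUE, warnings = warns,
       deidentified = FALSE)
}

# header attributes treated as protected health information
.phi_attributes <- c("patient_name", "patient_birth_date", "patient_address",
                     "patient_telephone_numbers", "other_patient_ids",
                     "patient_sex")

#' Keyed one-way pseudonym for a patient identifier
#' @param patient_id Source identifier.
#' @param salt Secret salt; same salt + id always yields the same pseudonym.
#' @return A pseudonym string (`"P"` + 12 hex digits).
#' @export
pseudonymize <- function(patient_id, salt) {
  paste0("P", toupper(substr(digest::digest(paste0(salt, "|pid|", patient_id),
                                            algo = "sha256"), 1, 12)))
}

#' Deterministic remapping of a DICOM UID
#'
#' Maps a UID into the 2.25 (UUID-derived) namespace through a keyed hash,
#' so UIDs are consistent within a run but unlinkable to the originals.
#'
#' @param uid Source UID.
#' @param salt Secret salt.
#' @return A remapped UID string.
#' @export
remap_uid <- function(uid, salt) {
  hx <- digest::digest(paste0(salt, "|uid|", uid), algo = "sha256")
  bytes <- strtoi(substring(hx, seq(1, 23, 2), seq(2, 24, 2)), 16L)
  paste0("2.25.1", paste(sprintf("%03d", bytes), collapse = ""))
}

#' De-identify a header record
#'
#' Removes PHI attributes, replaces the patient identifier with a keyed
#' pseudonym, and remaps all instance UIDs. Idempotent: a record already
#' de-identified is returned unchanged.
#'
#' @param record A header record from [read_headers()].
#' @param salt Secret salt string.
#' @return The de-identified record.
#' @export
deidentify <- function(record, salt) {
  if (isTRUE(record$deidentified)) return(record)
  record$values <- record$values[setdiff(names(record$values), .phi_attributes)]
  if ("patient_id" %in% names(record$values) &&
      !is.na(record$values[["patient_id"]])) {
    record$values[["patient_id"]] <- pseudonymize(record$values[["patient_id"]], salt)
  }
  record$study_uid <- remap_uid(record$study_uid, salt)
  record$series_uid <- remap_uid(record$series_uid, salt)
  if (!is.na(record$sop_uid)) record$sop_uid <- remap_uid(record$sop_uid, salt)
  record$deidentified <- TRUE
  record
}

#' Group header records into the study/series hierarchy
#'
#' @param records List of (de-identified) header records.
#' @return Nested named list: `study_uid -> series_uid -> list of records`.
#'   The partition is exact: every record lands in exactly one group.
#' @export
group_series <- function(records) {
  if (!length(records)) return(list())
  study_uids <- vapply(records, `[[`, "", "study_uid")
  out <- list()
  for (su in sort(unique(study_uids), method = "radix")) {
    recs <- records[study_uids == su]
    series_uids <- vapply(recs, `[[`, "", "series_uid")
    grp <- list()
    for (se in sort(unique(series_uids), method = "radix")) {
      grp[[se]] <- recs[series_uids == se]
    }
    out[[su]] <- grp
  }
  out
}

#' Rule-based folder names for series
#'
#' Builds descriptive folder names by joining modality, plane, weighting,
#' contrast and low-dose tokens, with numeric suffixes on collisions.
#'
#' @param series_info A data.frame with columns `series_uid`, `modality`,
#'   `plane`, `weighting`, `contrast_enhanced`, `low_dose` (one row per
#'   series, e.g. from [classify_description()] results).
#' @return Named character vector: series_uid -> folder name.
#' @export
organize_folders <- function(series_info) {
  plane_tok <- c(axial = "AXIAL", coronal = "COR", sagittal = "SAG")
  nm <- vapply(seq_len(nrow(series_info)), function(i) {
    s <- series_info[i, ]
    toks <- s$modality
    if (s$plane %in% names(plane_tok)) toks <- c(toks, plane_tok[[s$plane]])
    if (s$weighting %in% c("T1", "T2")) toks <- c(toks, s$weighting)
    if (isTRUE(s$contrast_enhanced)) toks <- c(toks, "CE")
    if (isTRUE(s$low_dose)) toks <- c(toks, "LOWDOSE")
    paste(toks, collapse = "_")
  }, "")
  dup <- nm[duplicated(nm)]
  for (d in unique(dup)) {
    idx <- which(nm == d)
    nm[idx] <- paste0(d, "_", seq_along(idx))
  }
  stats::setNames(nm, series_info$series_uid)
}
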