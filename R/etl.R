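# ETL: grouped header records + semantics + concept mappings -> the four
# imaging tables, with linkage of each study to its imaging order in
# PROCEDURE_OCCURRENCE.

#' Bundle of mapping resources used by the ETL
#' @param vocabulary,concept_map,crosswalk,registry See the vocabulary
#'   accessors; all default to the shipped synthetic fixtures / a fresh
#'   registry.
#' @return A list used as the `ctx` argument of the ETL functions.
#' @export
mapping_context <- function(vocabulary = load_vocabulary(),
                            concept_map = load_concept_map(),
                            crosswalk = load_radlex_crosswalk(),
                            registry = concept_registry()) {
  list(vocabulary = vocabulary, concept_map = concept_map,
       crosswalk = crosswalk, registry = registry)
}

.val_get <- function(values, name) {
  if (name %in% names(values)) values[[name]] else NA_character_
}

.first_value <- function(records, attribute) {
  for (r in records) {
    v <- .val_get(r$values, attribute)
    if (!is.na(v) && nzchar(v)) return(v)
  }
  NA_character_
}

.da_to_iso <- function(da) {
  if (is.na(da) || !grepl("^\\d{8}$", da)) return(NA_character_)
  sprintf("%s-%s-%s", substr(da, 1, 4), substr(da, 5, 6), substr(da, 7, 8))
}

#' Build an IMAGING_STUDY row from one study group
#'
#' `number_of_series` counts the distinct series in the group,
#' `number_of_instances` the files; the study modality is the modal (most
#' frequent) series modality.
#'
#' @param study_group Named list series_uid -> list of header records.
#' @param ctx Mapping context from [mapping_context()].
#' @param person_id OMOP person id the study belongs to.
#' @param imaging_study_id Surrogate key to assign.
#' @return Named list (an imaging_study row).
#' @export
build_study <- function(study_group, ctx, person_id, imaging_study_id = 1L) {
  stopifnot(length(study_group) > 0)
  all_recs <- unlist(study_group, recursive = FALSE)
  uids <- unique(vapply(all_recs, `[[`, "", "study_uid"))
  if (length(uids) != 1) {
    stop("conflicting study_uid values within one study group: ",
         paste(uids, collapse = ", "))
  }
  series_modalities <- vapply(study_group, function(recs) {
    m <- .first_value(recs, "modality")
    if (is.na(m)) "UNKNOWN" else m
  }, "")
  tab <- sort(table(series_modalities), decreasing = TRUE)
  modality <- names(tab)[1]
  list(
    imaging_study_id = imaging_study_id,
    person_id = person_id,
    procedure_occurrence_id = NA_integer_,
    study_uid = uids,
    study_date = .da_to_iso(.first_value(all_recs, "study_date")),
    modality_concept_id = modality_to_procedure_concept(modality,
                                                        ctx$concept_map,
                                                        ctx$registry),
    modality_source_value = modality,
    manufacturer_source_value = .first_value(all_recs, "manufacturer"),
    number_of_series = length(study_group),
    number_of_instances = length(all_recs)
  )
}

.series_numeric_attrs <- c("slice_thickness", "window_center", "window_width",
                           "rows", "columns")
.series_coded_attrs <- c("body_part_examined", "laterality", "patient_position")
.series_units <- c(slice_thickness = "mm")

#' Build the EAV rows for one series
#'
#' One IMAGING_SERIES row per present attribute, values taken from the
#' first instance (cross-instance disagreement is logged, not fatal). A
#' number-of-instances row is always emitted; a BB/non-BB row only for MR.
#'
#' @param series_records List of header records of one series.
#' @param ctx Mapping context.
#' @param imaging_study_id Owning study key.
#' @param row_id_start First surrogate row id to use.
#' @param lexicon Token lexicon for Black-Blood detection.
#' @return A list: `rows` (data.frame of EAV rows) and `disagreements`
#'   (character vector describing cross-instance conflicts).
#' @export
build_series_eav <- function(series_records, ctx, imaging_study_id,
                             row_id_start = 1L, lexicon = default_lexicon()) {
  stopifnot(length(series_records) > 0)
  reg <- series_attribute_registry()
  first <- series_records[[1]]
  series_uid <- first$series_uid
  series_number <- suppressWarnings(as.integer(.first_value(series_records,
                                                            "series_number")))
  disagreements <- character(0)
  eav_attrs <- intersect(names(reg), c(.series_numeric_attrs,
                                       .series_coded_attrs,
                                       "series_description"))
  for (a in eav_attrs) {
    vals <- unique(stats::na.omit(vapply(series_records, function(r) {
      .val_get(r$values, a)
    }, "")))
    if (length(vals) > 1) {
      disagreements <- c(disagreements, sprintf(
        "%s/%s: %d distinct values across instances, first kept",
        series_uid, a, length(vals)))
    }
  }

  rows <- list()
  add <- function(attr, value_as_number = NA_real_,
                  value_as_concept_id = NA_integer_,
                  value_source_value = NA_character_,
                  unit_source_value = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      imaging_series_row_id = row_id_start + length(rows),
      imaging_study_id = imaging_study_id,
      series_uid = series_uid,
      series_number = if (is.na(series_number)) NA_integer_ else series_number,
      series_concept_id = reg[[attr]],
      value_as_number = value_as_number,
      value_as_concept_id = value_as_concept_id,
      value_source_value = value_source_value,
      unit_source_value = unit_source_value,
      stringsAsFactors = FALSE)
  }

  vals <- first$values
  for (a in .series_numeric_attrs) {
    raw <- .val_get(vals, a)
    if (is.na(raw) || !nzchar(raw)) next
    num <- suppressWarnings(as.numeric(raw))
    add(a, value_as_number = num, value_source_value = raw,
        unit_source_value = if (a %in% names(.series_units)) .series_units[[a]]
                            else NA_character_)
  }
  for (a in .series_coded_attrs) {
    raw <- .val_get(vals, a)
    if (is.na(raw) || !nzchar(raw)) next
    m <- map_value(a, raw, ctx$concept_map, ctx$registry, ctx$crosswalk)
    add(a, value_as_concept_id = m$concept_id, value_source_value = raw)
  }
  desc <- .val_get(vals, "series_description")
  if (!is.na(desc) && nzchar(desc)) {
    add("series_description", value_source_value = desc)
  }
  add("number_of_instances", value_as_number = length(series_records),
      value_source_value = as.character(length(series_records)))
  modality <- .first_value(series_records, "modality")
  bb <- detect_bb(modality, desc, .val_get(vals, "sequence_name"), lexicon)
  if (!is.na(bb)) {
    add("bb_non_bb", value_as_concept_id = bb_concept(bb),
        value_source_value = bb)
  }
  list(rows = do.call(rbind, rows), disagreements = disagreements)
}

#' Link a study to its PROCEDURE_OCCURRENCE imaging order
#'
#' A candidate procedure has the same person, the same date, and a
#' procedure concept equal to the study's modality-mapped procedure
#' concept. Ties are broken by lowest procedure_occurrence_id. With no
#' candidate the link stays absent and a warning is attached.
#'
#' @param study An imaging_study row (named list or one-row data.frame).
#' @param procedures PROCEDURE_OCCURRENCE data.frame.
#' @return Integer procedure_occurrence_id or `NA` (with attribute
#'   `warning` set).
#' @export
link_procedure <- function(study, procedures) {
  cand <- procedures[procedures$person_id == study$person_id &
                       procedures$procedure_concept_id == study$modality_concept_id &
                       procedures$procedure_date == study$study_date, ,
                     drop = FALSE]
  if (!nrow(cand)) {
    return(structure(NA_integer_,
                     warning = sprintf("study %s: no matching procedure",
                                       study$study_uid)))
  }
  min(cand$procedure_occurrence_id)
}

#' Build FILEPATH rows for a set of instance files
#'
#' One row per file; size from the filesystem, format from the extension
#' lowercased. Files that vanished between scan and ingest are quarantined.
#'
#' @param files Character vector of file paths.
#' @param entity_ids Integer vector: owning imaging_study_id per file.
#' @param id_start First surrogate key.
#' @return List: `rows` (data.frame), `quarantine` (list).
#' @export
build_filepaths <- function(files, entity_ids, id_start = 1L) {
  stopifnot(length(files) == length(entity_ids))
  info <- file.info(files)
  gone <- is.na(info$size)
  quarantine <- lapply(which(gone), function(i) {
    .quarantine(files[i], "file vanished before FILEPATH ingest")
  })
  keep <- which(!gone)
  rows <- data.frame(
    filepath_id = id_start + seq_along(keep) - 1L,
    entity_kind = "study",
    entity_id = entity_ids[keep],
    file_path = files[keep],
    file_size_bytes = as.numeric(info$size[keep]),
    file_format = tolower(tools::file_ext(files[keep])),
    stringsAsFactors = FALSE)
  list(rows = rows, quarantine = quarantine)
}

#' Ingest an annotation export table
#'
#' Expects columns `study_uid`, `series_uid`, `lesion_id`, `measure`
#' (`volume`, `long_axis`, `surface`), `value`, `text`, `tool`. Each row
#' yields a numeric measure row; the lesion's annotation-text and
#' annotation-system rows are emitted once per lesion. Rows with unknown
#' study_uid or malformed numeric values are quarantined.
#'
#' @param export A data.frame (the delimited export, already read).
#' @param study_map Named integer vector: study_uid -> imaging_study_id.
#' @param id_start First surrogate key.
#' @return List: `rows` (imaging_annotation data.frame), `quarantine`.
#' @export
ingest_annotations <- function(export, study_map, id_start = 1L) {
  need <- c("study_uid", "series_uid", "lesion_id", "measure", "value",
            "text", "tool")
  stopifnot(all(need %in% names(export)))
  reg <- annotation_attribute_registry()
  rows <- list()
  quarantine <- list()
  seen_text <- character(0)   # "study|lesion" keys already given text/system rows
  add <- function(study_id, series_uid, lesion_id, concept,
                  value_as_number = NA_real_, value_source_value = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      imaging_annotation_row_id = id_start + length(rows),
      imaging_study_id = study_id, series_uid = series_uid,
      lesion_id = lesion_id, annotation_concept_id = concept,
      value_as_number = value_as_number, value_as_concept_id = NA_integer_,
      value_source_value = value_source_value, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(export))) {
    r <- export[i, ]
    key_uid <- as.character(r$study_uid)
    sid <- if (key_uid %in% names(study_map)) study_map[[key_uid]] else NA_integer_
    if (is.na(sid)) {
      quarantine[[length(quarantine) + 1L]] <-
        .quarantine(sprintf("annotation row %d", i),
                    sprintf("unknown study_uid %s", r$study_uid))
      next
    }
    if (!r$measure %in% c("volume", "long_axis", "surface")) {
      quarantine[[length(quarantine) + 1L]] <-
        .quarantine(sprintf("annotation row %d", i),
                    sprintf("unknown measure %s", r$measure))
      next
    }
    num <- suppressWarnings(as.numeric(r$value))
    if (is.na(num)) {
      quarantine[[length(quarantine) + 1L]] <-
        .quarantine(sprintf("annotation row %d", i),
                    sprintf("malformed numeric value %s", r$value))
      next
    }
    add(sid, r$series_uid, r$lesion_id, reg[[r$measure]],
        value_as_number = num, value_source_value = as.character(r$value))
    key <- paste(sid, r$lesion_id)
    if (!key %in% seen_text) {
      if (!is.na(r$text) && nzchar(r$text)) {
        add(sid, r$series_uid, r$lesion_id, reg[["annotation_text"]],
            value_source_value = r$text)
      }
      if (!is.na(r$tool) && nzchar(r$tool)) {
        add(sid, r$series_uid, r$lesion_id, reg[["annotation_system"]],
            value_source_value = r$tool)
      }
      seen_text <- c(seen_text, key)
    }
  }
  list(rows = if (length(rows)) do.call(rbind, rows)
              else .empty_table("imaging_annotation"),
       quarantine = quarantine)
}

#' Run the full ETL over a DICOM directory
#'
#' scan -> read -> de-identify -> group -> classify -> map -> populate.
#' Patients absent from `person_map` receive generated person rows (with a
#' log entry).
#'
#' @param dicom_dir Directory of DICOM files.
#' @param salt De-identification salt.
#' @param ctx Mapping context; defaults to the shipped fixtures.
#' @param person_map Optional data.frame (`person_source_value`,
#'   `person_id`, optionally `birth_date`); source values are pseudonyms.
#' @param procedures Optional PROCEDURE_OCCURRENCE data.frame for linkage.
#' @param annotations Optional annotation export data.frame.
#' @param config Tag configuration.
#' @param lexicon Token lexicon.
#' @return A list: `db` (an `icdm_db`), `quarantine`, `log` (character).
#' @export
run_etl <- function(dicom_dir, salt = "icdm", ctx = mapping_context(),
                    person_map = NULL, procedures = NULL, annotations = NULL,
                    config = default_tag_config(),
                    lexicon = default_lexicon()) {
  files <- scan_directory(dicom_dir)
  log <- sprintf("scanned %d DICOM candidates (%d non-matching files skipped)",
                 length(files), attr(files, "n_skipped"))
  records <- lapply(files, read_headers, config = config)
  quarantine <- Filter(is_quarantined, records)
  records <- Filter(Negate(is_quarantined), records)
  records <- lapply(records, deidentify, salt = salt)
  groups <- group_series(records)
  log <- c(log, sprintf("grouped %d records into %d studies, %d quarantined",
                        length(records), length(groups), length(quarantine)))

  db <- icdm_db(vocabulary = ctx$vocabulary)
  if (!is.null(person_map)) {
    db$person <- data.frame(
      person_id = person_map$person_id,
      person_source_value = person_map$person_source_value,
      birth_date = if ("birth_date" %in% names(person_map))
        person_map$birth_date else NA_character_,
      stringsAsFactors = FALSE)
  }
  next_person <- if (nrow(db$person)) max(db$person$person_id) + 1L else 1L

  study_rows <- list()
  series_rows <- list()
  file_rows <- list()
  study_map <- integer(0)
  series_row_id <- 1L
  filepath_id <- 1L

  for (i in seq_along(groups)) {
    study_uid <- names(groups)[i]
    grp <- groups[[i]]
    all_recs <- unlist(grp, recursive = FALSE)
    pseud <- .first_value(all_recs, "patient_id")
    pid <- db$person$person_id[match(pseud, db$person$person_source_value)]
    if (is.na(pseud)) pid <- NA_integer_
    if (length(pid) == 0 || is.na(pid)) {
      pid <- next_person
      db$person <- rbind(db$person, data.frame(
        person_id = pid,
        person_source_value = if (is.na(pseud)) sprintf("UNRESOLVED-%d", pid)
                              else pseud,
        birth_date = NA_character_, stringsAsFactors = FALSE))
      next_person <- next_person + 1L
      log <- c(log, sprintf("study %s: patient not in person map, person %d generated",
                            study_uid, pid))
    }
    st <- build_study(grp, ctx, person_id = pid, imaging_study_id = i)
    if (!is.null(procedures) && nrow(procedures)) {
      linked <- link_procedure(st, procedures)
      if (is.na(linked)) log <- c(log, attr(linked, "warning"))
      st$procedure_occurrence_id <- as.integer(linked)
    }
    study_rows[[i]] <- as.data.frame(st, stringsAsFactors = FALSE)
    study_map[[study_uid]] <- i
    for (se in names(grp)) {
      eav <- build_series_eav(grp[[se]], ctx, imaging_study_id = i,
                              row_id_start = series_row_id, lexicon = lexicon)
      series_rows[[length(series_rows) + 1L]] <- eav$rows
      series_row_id <- series_row_id + nrow(eav$rows)
      if (length(eav$disagreements)) log <- c(log, eav$disagreements)
    }
    fps <- vapply(all_recs, `[[`, "", "file_path")
    fp <- build_filepaths(fps, rep(i, length(fps)), id_start = filepath_id)
    filepath_id <- filepath_id + nrow(fp$rows)
    file_rows[[length(file_rows) + 1L]] <- fp$rows
    quarantine <- c(quarantine, fp$quarantine)
  }

  if (length(study_rows)) db$imaging_study <- do.call(rbind, study_rows)
  if (length(series_rows)) db$imaging_series <- do.call(rbind, series_rows)
  if (length(file_rows)) db$filepath <- do.call(rbind, file_rows)
  if (!is.null(procedures)) db$procedure_occurrence <- procedures

  if (!is.null(annotations) && nrow(annotations)) {
    ann <- ingest_annotations(annotations, study_map)
    db$imaging_annotation <- ann$rows
    quarantine <- c(quarantine, ann$quarantine)
    log <- c(log, sprintf("ingested %d annotation EAV rows, %d quarantined",
                          nrow(ann$rows), length(ann$quarantine)))
  }
  log <- c(log, sprintf("ETL complete: %d studies, %d series EAV rows, %d filepath rows",
                        nrow(db$imaging_study), nrow(db$imaging_series),
                        nrow(db$filepath)))
  list(db = db, quarantine = quarantine, log = log, study_map = study_map)
}
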