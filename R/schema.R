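# The imaging CDM extension schema: four tables added to an OMOP CDM
# instance, plus a mini vocabulary table. IMAGING_SERIES and
# IMAGING_ANNOTATION use an entity-attribute-value layout so new series or
# annotation attributes become rows, not columns.

ICDM_TABLES <- c("imaging_study", "imaging_series", "imaging_annotation", "filepath")

#' Registry of series-level EAV attributes
#'
#' The attributes a series row may describe. `series_concept_id` in
#' IMAGING_SERIES must name one of these.
#' @return Named integer vector, attribute name -> concept id.
#' @export
series_attribute_registry <- function() {
  c(slice_thickness = 91000001L, rows = 91000002L, columns = 91000003L,
    window_center = 91000004L, window_width = 91000005L,
    body_part_examined = 91000006L, laterality = 91000007L,
    patient_position = 91000008L, series_description = 91000009L,
    number_of_instances = 91000010L, bb_non_bb = 91000011L)
}

#' Registry of annotation EAV measures
#' @return Named integer vector, measure name -> concept id.
#' @export
annotation_attribute_registry <- function() {
  c(annotation_system = 91000012L, annotation_text = 91000013L,
    volume = 91000014L, long_axis = 91000015L, surface = 91000016L)
}

# column -> abstract type; abstract types are mapped per SQL dialect
.icdm_fields <- list(
  imaging_study = data.frame(
    name = c("imaging_study_id", "person_id", "procedure_occurrence_id",
             "study_uid", "study_date", "modality_concept_id",
             "modality_source_value", "manufacturer_source_value",
             "number_of_series", "number_of_instances"),
    type = c("id", "id", "id", "text", "date", "int", "text", "text",
             "int", "int"),
    required = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ),
  imaging_series = data.frame(
    name = c("imaging_series_row_id", "imaging_study_id", "series_uid",
             "series_number", "series_concept_id", "value_as_number",
             "value_as_concept_id", "value_source_value", "unit_source_value"),
    type = c("id", "id", "text", "int", "int", "num", "int", "text", "text"),
    required = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ),
  imaging_annotation = data.frame(
    name = c("imaging_annotation_row_id", "imaging_study_id", "series_uid",
             "lesion_id", "annotation_concept_id", "value_as_number",
             "value_as_concept_id", "value_source_value"),
    type = c("id", "id", "text", "int", "int", "num", "int", "text"),
    required = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ),
  filepath = data.frame(
    name = c("filepath_id", "entity_kind", "entity_id", "file_path",
             "file_size_bytes", "file_format"),
    type = c("id", "text", "id", "text", "num", "text"),
    required = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ),
  vocabulary = data.frame(
    name = c("concept_id", "concept_name", "domain", "vocabulary",
             "standard_flag"),
    type = c("id", "text", "text", "text", "bool"),
    required = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
)

#' Column definitions of the imaging CDM tables
#'
#' @param table Optional table name; if omitted, the full list.
#' @return A data.frame (`name`, `type`, `required`) or a named list of them.
#' @export
icdm_schema <- function(table = NULL) {
  if (is.null(table)) return(.icdm_fields)
  if (!table %in% names(.icdm_fields)) {
    stop("unknown table '", table, "'; known: ",
         paste(names(.icdm_fields), collapse = ", "))
  }
  .icdm_fields[[table]]
}

.r_proto <- function(type) {
  switch(type,
         id = integer(0), int = integer(0), num = numeric(0),
         text = character(0), date = character(0), bool = logical(0))
}

.empty_table <- function(table) {
  f <- .icdm_fields[[table]]
  out <- stats::setNames(lapply(f$type, .r_proto), f$name)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Create an empty in-memory imaging CDM database
#'
#' The container the ETL populates: the four imaging tables, the mini
#' vocabulary, and (optionally filled later) the OMOP clinical stub tables
#' the cohort scenarios join against.
#'
#' @param vocabulary Optional vocabulary data.frame
#'   (see [load_vocabulary()]).
#' @return An object of class `icdm_db`: a named list of data.frames.
#' @export
icdm_db <- function(vocabulary = NULL) {
  db <- lapply(ICDM_TABLES, .empty_table)
  names(db) <- ICDM_TABLES
  db$vocabulary <- if (is.null(vocabulary)) .empty_table("vocabulary") else vocabulary
  db$person <- data.frame(person_id = integer(0),
                          person_source_value = character(0),
                          birth_date = character(0),
                          stringsAsFactors = FALSE)
  db$condition_occurrence <- data.frame(
    condition_occurrence_id = integer(0), person_id = integer(0),
    condition_concept_id = integer(0), condition_start_date = character(0),
    stringsAsFactors = FALSE)
  db$drug_exposure <- data.frame(
    drug_exposure_id = integer(0), person_id = integer(0),
    drug_concept_id = integer(0), drug_exposure_start_date = character(0),
    stringsAsFactors = FALSE)
  db$procedure_occurrence <- data.frame(
    procedure_occurrence_id = integer(0), person_id = integer(0),
    procedure_concept_id = integer(0), procedure_date = character(0),
    stringsAsFactors = FALSE)
  structure(db, class = "icdm_db")
}

#' @export
print.icdm_db <- function(x, ...) {
  cat("<imaging CDM database>\n")
  for (tb in c(ICDM_TABLES, "vocabulary", "person", "condition_occurrence",
               "drug_exposure", "procedure_occurrence")) {
    cat(sprintf("  %-22s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

.sql_type <- function(type, dialect) {
  if (dialect == "sqlite") {
    return(switch(type, id = "INTEGER", int = "INTEGER", num = "REAL",
                  text = "TEXT", date = "TEXT", bool = "INTEGER"))
  }
  switch(type, id = "BIGINT", int = "INTEGER", num = "NUMERIC",
         text = "VARCHAR(255)", date = "DATE", bool = "BOOLEAN")
}

#' Emit CREATE TABLE DDL for the imaging CDM extension
#'
#' Produces exactly four CREATE TABLE statements for the imaging tables
#' plus one for the mini vocabulary table.
#'
#' @param dialect One of `"generic_sql"`, `"sqlite"`, `"postgres"`.
#' @return A single DDL string.
#' @export
emit_ddl <- function(dialect = c("generic_sql", "sqlite", "postgres")) {
  supported <- c("generic_sql", "sqlite", "postgres")
  if (length(dialect) > 1) dialect <- dialect[[1]]
  if (!dialect %in% supported) {
    stop("unsupported dialect '", dialect, "'; supported dialects: ",
         paste(supported, collapse = ", "))
  }
  stmts <- vapply(c(ICDM_TABLES, "vocabulary"), function(tb) {
    f <- .icdm_fields[[tb]]
    cols <- sprintf("  %s %s%s", f$name, vapply(f$type, .sql_type, "", dialect),
                    ifelse(f$required, " NOT NULL", ""))
    pk <- sprintf("  PRIMARY KEY (%s)", f$name[1])
    sprintf("CREATE TABLE %s (\n%s\n);", toupper(tb),
            paste(c(cols, pk), collapse = ",\n"))
  }, "")
  paste(stmts, collapse = "\n\n")
}

.is_blank <- function(x) {
  is.null(x) || length(x) == 0 || is.na(x) || (is.character(x) && !nzchar(trimws(x)))
}

.is_pos_int <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) && x > 0
}

.is_iso_date <- function(x) {
  is.character(x) && length(x) == 1 &&
    grepl("^\\d{4}-\\d{2}-\\d{2}$", x) && !is.na(as.Date(x, "%Y-%m-%d"))
}

#' Validate a candidate row against the table's invariants
#'
#' Checks single-row invariants: field presence, types, sign constraints,
#' the EAV at-least-one-value rule, the attribute registries, and the
#' annotation value rules. Cross-row invariants (key uniqueness, count
#' consistency) are enforced by the data-quality engine.
#'
#' @param table Table name.
#' @param row Named list of field values.
#' @param vocabulary Optional vocabulary data.frame; when given,
#'   `modality_concept_id` must resolve in it or be a custom concept.
#' @return Character vector of violations, empty when the row is valid.
#' @export
validate_row <- function(table, row, vocabulary = NULL) {
  f <- icdm_schema(table)
  v <- character(0)
  extra <- setdiff(names(row), f$name)
  if (length(extra)) {
    v <- c(v, sprintf("%s: not a field of %s", extra, table))
  }
  for (i in seq_len(nrow(f))) {
    nm <- f$name[i]
    val <- row[[nm]]
    if (.is_blank(val)) {
      if (f$required[i]) v <- c(v, sprintf("%s: required field missing", nm))
      next
    }
    ok <- switch(f$type[i],
                 id = .is_pos_int(val),
                 int = is.numeric(val) && val == floor(val),
                 num = is.numeric(val) && is.finite(val),
                 text = is.character(val),
                 date = .is_iso_date(val),
                 bool = is.logical(val))
    if (!ok) v <- c(v, sprintf("%s: not a valid %s", nm, f$type[i]))
  }
  if (length(v)) return(v)  # type errors make semantic checks unreliable

  if (table == "imaging_study") {
    if (row$number_of_series < 0) v <- c(v, "number_of_series: must be >= 0")
    if (row$number_of_instances < 0) v <- c(v, "number_of_instances: must be >= 0")
    if (row$number_of_series > 0 && row$number_of_instances < row$number_of_series) {
      v <- c(v, "number_of_instances: fewer instances than series")
    }
    if (!is.null(vocabulary) && nrow(vocabulary)) {
      cid <- row$modality_concept_id
      if (!cid %in% vocabulary$concept_id && cid < CUSTOM_CONCEPT_FLOOR) {
        v <- c(v, "modality_concept_id: not in vocabulary and not a custom concept")
      }
    }
  } else if (table == "imaging_series") {
    if (.is_blank(row$value_as_number) && .is_blank(row$value_as_concept_id) &&
        .is_blank(row$value_source_value)) {
      v <- c(v, "value: at least one of value_as_number / value_as_concept_id / value_source_value must be populated")
    }
    if (!row$series_concept_id %in% series_attribute_registry()) {
      v <- c(v, "series_concept_id: not in the series attribute registry")
    }
  } else if (table == "imaging_annotation") {
    reg <- annotation_attribute_registry()
    if (!row$annotation_concept_id %in% reg) {
      v <- c(v, "annotation_concept_id: not in the annotation measure registry")
    } else {
      measure <- names(reg)[match(row$annotation_concept_id, reg)]
      if (measure %in% c("volume", "long_axis", "surface") &&
          .is_blank(row$value_as_number)) {
        v <- c(v, sprintf("value_as_number: required for measure %s", measure))
      }
      if (measure == "annotation_text" && .is_blank(row$value_source_value)) {
        v <- c(v, "value_source_value: annotation text rows need nonempty text")
      }
    }
  } else if (table == "filepath") {
    if (!row$entity_kind %in% c("study", "series", "annotation", "instance")) {
      v <- c(v, "entity_kind: must be one of study, series, annotation, instance")
    }
    if (row$file_size_bytes < 0) v <- c(v, "file_size_bytes: must be >= 0")
  }
  v
}

#' Append a validated row to a database table
#' @param db An `icdm_db`.
#' @param table Table name.
#' @param row Named list of field values.
#' @return The updated database.
#' @export
icdm_insert <- function(db, table, row) {
  viol <- validate_row(table, row)
  if (length(viol)) {
    stop("invalid ", table, " row: ", paste(viol, collapse = "; "))
  }
  f <- icdm_schema(table)
  filled <- stats::setNames(lapply(seq_len(nrow(f)), function(i) {
    val <- row[[f$name[i]]]
    if (.is_blank(val)) {
      switch(f$type[i], num = NA_real_, text = NA_character_,
             date = NA_character_, bool = NA, NA_integer_)
    } else val
  }), f$name)
  db[[table]] <- rbind(db[[table]], as.data.frame(filled, stringsAsFactors = FALSE))
  db
}

#' Export an imaging CDM database as CSV files
#'
#' One CSV per table with a header row matching the field names exactly.
#' Rows are written ordered by primary key so exports are byte-stable.
#'
#' @param db An `icdm_db`.
#' @param dir Output directory (created if needed).
#' @param tables Which tables to export.
#' @return Invisibly, the paths written.
#' @export
icdm_export_csv <- function(db, dir, tables = c(ICDM_TABLES, "vocabulary")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(tables, function(tb) {
    tab <- db[[tb]]
    if (nrow(tab)) tab <- tab[order(tab[[1]]), , drop = FALSE]
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE, na = "")
    p
  }, "")
  invisible(paths)
}

#' Import an imaging CDM database from CSV files
#' @param dir Directory holding CSVs written by [icdm_export_csv()].
#' @return An `icdm_db`.
#' @export
icdm_import_csv <- function(dir) {
  db <- icdm_db()
  for (tb in c(ICDM_TABLES, "vocabulary")) {
    p <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(p)) next
    got <- utils::read.csv(p, stringsAsFactors = FALSE)
    want <- icdm_schema(tb)$name
    if (!identical(names(got), want)) {
      stop("CSV header of ", p, " does not match schema for ", tb)
    }
    if (nrow(got)) db[[tb]] <- rbind(db[[tb]][0, ], got)
  }
  db
}

#' Create the imaging CDM tables in a SQLite database
#'
#' Executes the sqlite-dialect DDL on a (new or existing) SQLite file or
#' in-memory database and optionally loads an `icdm_db`'s rows.
#'
#' @param path SQLite file path, or `":memory:"`.
#' @param db Optional `icdm_db` whose rows are loaded after creation.
#' @return A live `DBI` connection; caller must disconnect.
#' @export
icdm_sqlite <- function(path = ":memory:", db = NULL) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  for (stmt in strsplit(emit_ddl("sqlite"), ";\\s*\\n\\s*\\n")[[1]]) {
    DBI::dbExecute(con, stmt)
  }
  if (!is.null(db)) {
    for (tb in c(ICDM_TABLES, "vocabulary")) {
      if (nrow(db[[tb]])) {
        DBI::dbWriteTable(con, toupper(tb), db[[tb]], append = TRUE)
      }
    }
  }
  con
}
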