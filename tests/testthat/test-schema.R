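test_that("DDL defines the four imaging tables plus the mini vocabulary", {
  for (dialect in c("generic_sql", "sqlite", "postgres")) {
    ddl <- emit_ddl(dialect)
    created <- regmatches(ddl, gregexpr("CREATE TABLE [A-Z_]+", ddl))[[1]]
    expect_length(created, 5)
    expect_setequal(sub("CREATE TABLE ", "", created),
                    c("IMAGING_STUDY", "IMAGING_SERIES", "IMAGING_ANNOTATION",
                      "FILEPATH", "VOCABULARY"))
    expect_length(grep("VOCABULARY", created), 1)  # 4 imaging + 1 vocab
  }
  expect_error(emit_ddl("oracle"), "generic_sql, sqlite, postgres")
})

test_that("sqlite DDL executes and accepts valid fixture rows", {
  con <- icdm_sqlite(":memory:")
  on.exit(DBI::dbDisconnect(con))
  tables <- DBI::dbListTables(con)
  expect_setequal(toupper(tables),
                  c("IMAGING_STUDY", "IMAGING_SERIES", "IMAGING_ANNOTATION",
                    "FILEPATH", "VOCABULARY"))
  row <- valid_study_row()
  expect_equal(validate_row("imaging_study", row), character(0))
  DBI::dbExecute(con, paste(
    "INSERT INTO IMAGING_STUDY (imaging_study_id, person_id, study_uid,",
    "study_date, modality_concept_id, modality_source_value,",
    "number_of_series, number_of_instances)",
    "VALUES (1, 1, '2.25.100', '2015-03-01', 91001001, 'CT', 2, 8)"))
  expect_equal(DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM IMAGING_STUDY")$n, 1)
})

test_that("validate_row flags each violated invariant by field", {
  expect_equal(validate_row("imaging_study", valid_study_row()), character(0))
  expect_match(validate_row("imaging_study",
                            valid_study_row(number_of_series = -1L)),
               "number_of_series", all = FALSE)
  expect_match(validate_row("imaging_study",
                            valid_study_row(study_date = "03/01/2015")),
               "study_date", all = FALSE)
  expect_match(validate_row("imaging_study",
                            valid_study_row(number_of_series = 5L,
                                            number_of_instances = 3L)),
               "fewer instances than series", all = FALSE)

  # EAV row with no value at all: exactly the at-least-one-value rule
  empty_eav <- list(imaging_series_row_id = 1L, imaging_study_id = 1L,
                    series_uid = "2.25.5", series_concept_id = 91000001L)
  v <- validate_row("imaging_series", empty_eav)
  expect_length(v, 1)
  expect_match(v, "at least one of")

  # annotation text row must carry text; volume row must carry a number
  reg <- annotation_attribute_registry()
  expect_match(validate_row("imaging_annotation",
                            list(imaging_annotation_row_id = 1L,
                                 imaging_study_id = 1L, lesion_id = 1L,
                                 annotation_concept_id = reg[["volume"]],
                                 value_source_value = "2500")),
               "value_as_number", all = FALSE)
  expect_error(validate_row("no_such_table", list()), "unknown table")
})

test_that("fuzzed study rows: validate_row agrees with direct invariant recheck", {
  set.seed(401)
  for (i in 1:60) {
    row <- valid_study_row(
      number_of_series = sample(c(-2L, 0L, 3L, NA), 1),
      number_of_instances = sample(c(-1L, 0L, 2L, 9L), 1),
      study_date = sample(c("2015-03-01", "20150301", ""), 1),
      modality_concept_id = sample(c(91001001L, 5L, 2000000001L), 1))
    ok_direct <- !is.na(row$number_of_series) && row$number_of_series >= 0 &&
      row$number_of_instances >= 0 &&
      grepl("^\\d{4}-\\d{2}-\\d{2}$", row$study_date) &&
      !(row$number_of_series > 0 &&
          row$number_of_instances < row$number_of_series)
    expect_equal(length(validate_row("imaging_study", row)) == 0, ok_direct,
                 info = paste(unlist(row), collapse = "/"))
  }
})

test_that("rows accepted by validate_row insert into DDL-created tables", {
  con <- icdm_sqlite(":memory:")
  on.exit(DBI::dbDisconnect(con))
  db <- small_fixture()$etl$db
  set.seed(402)
  for (tb in c("imaging_study", "imaging_series", "imaging_annotation",
               "filepath")) {
    tab <- db[[tb]]
    idx <- sample(nrow(tab), min(25, nrow(tab)))
    for (i in idx) {
      expect_equal(validate_row(tb, as.list(tab[i, ])), character(0),
                   info = paste(tb, i))
    }
    DBI::dbWriteTable(con, toupper(tb), tab[idx, ], append = TRUE)
    expect_equal(DBI::dbGetQuery(con, sprintf("SELECT COUNT(*) n FROM %s",
                                              toupper(tb)))$n, length(idx))
  }
})

test_that("CSV export/import round-trips the database", {
  db <- small_fixture()$etl$db
  dir <- withr::local_tempdir()
  icdm_export_csv(db, dir)
  expect_setequal(list.files(dir),
                  c("imaging_study.csv", "imaging_series.csv",
                    "imaging_annotation.csv", "filepath.csv", "vocabulary.csv"))
  back <- icdm_import_csv(dir)
  for (tb in c("imaging_study", "imaging_series", "imaging_annotation",
               "filepath")) {
    orig <- db[[tb]][order(db[[tb]][[1]]), ]
    rownames(orig) <- NULL
    got <- back[[tb]]
    expect_equal(nrow(got), nrow(orig), info = tb)
    expect_equal(got[[1]], orig[[1]], info = tb)
    expect_equal(names(got), names(orig), info = tb)
  }
})
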