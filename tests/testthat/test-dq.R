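# build a bare database with n studies whose counts are consistent
consistent_db <- function(n_studies = 100L, series_per_study = 2L,
                          inst_per_series = 3L) {
  db <- icdm_db()
  reg <- series_attribute_registry()
  st <- lapply(seq_len(n_studies), function(i) {
    data.frame(imaging_study_id = i, person_id = i,
               procedure_occurrence_id = NA_integer_,
               study_uid = sprintf("2.25.%d", i), study_date = "2015-03-01",
               modality_concept_id = 91001001L, modality_source_value = "CT",
               manufacturer_source_value = "ACME",
               number_of_series = series_per_study,
               number_of_instances = series_per_study * inst_per_series,
               stringsAsFactors = FALSE)
  })
  db$imaging_study <- do.call(rbind, st)
  rid <- 0L
  se <- lapply(seq_len(n_studies), function(i) {
    do.call(rbind, lapply(seq_len(series_per_study), function(s) {
      rid <<- rid + 1L
      data.frame(imaging_series_row_id = rid, imaging_study_id = i,
                 series_uid = sprintf("2.25.%d.%d", i, s),
                 series_number = s,
                 series_concept_id = reg[["number_of_instances"]],
                 value_as_number = inst_per_series,
                 value_as_concept_id = NA_integer_,
                 value_source_value = as.character(inst_per_series),
                 unit_source_value = NA_character_, stringsAsFactors = FALSE)
    }))
  })
  db$imaging_series <- do.call(rbind, se)
  db
}

count_rule <- function() {
  reg <- load_dq_registry()
  reg[reg$archetype == "count_consistency", ][1, ]
}

test_that("the default registry loads 44 rules referencing real targets", {
  reg <- load_dq_registry()
  expect_equal(nrow(reg), 44)
  expect_false(anyDuplicated(reg$rule_id) > 0)
  expect_silent(validate_dq_registry(reg))
  # a broken registry is rejected
  bad <- reg
  bad$archetype[1] <- "vibes"
  expect_error(validate_dq_registry(bad), "unknown archetype")
  bad2 <- reg
  bad2$attribute[11] <- "not_an_attribute"
  expect_error(validate_dq_registry(bad2), "not in registry")
})

test_that("count consistency: clean data passes at 100, mismatches are counted", {
  db <- consistent_db(100L)
  r <- evaluate_rule(count_rule(), db)
  expect_equal(r$status, "PASS")
  expect_equal(r$pass_pct, 100)
  expect_equal(r$error_count, 0L)
  expect_equal(r$evaluated_count, 100L)

  # 6 mismatched studies out of 100 at a 95% threshold
  db6 <- db
  db6$imaging_study$number_of_series[c(3, 10, 22, 47, 81, 99)] <- 99L
  r6 <- evaluate_rule(count_rule(), db6)
  expect_equal(r6$status, "FAIL")
  expect_equal(r6$pass_pct, 94.0)
  expect_equal(r6$error_count, 6L)
  oracle <- oracle_count_consistency(db6)
  expect_equal(r6$error_count, oracle$error_count)
  expect_equal(r6$pass_pct, round(oracle$pass_pct, 1))
})

test_that("a result exactly at the threshold passes (at-least semantics)", {
  db <- consistent_db(100L)
  db$imaging_study$number_of_series[1:5] <- 99L  # exactly 95% consistent
  r <- evaluate_rule(count_rule(), db)
  expect_equal(r$pass_pct, 95.0)
  expect_equal(r$status, "PASS")
  db$imaging_study$number_of_series[6] <- 99L    # one more tips it over
  expect_equal(evaluate_rule(count_rule(), db)$status, "FAIL")
})

test_that("adding a violating row never turns FAIL into PASS", {
  db <- consistent_db(60L)
  reg <- count_rule()
  prev <- evaluate_rule(reg, db)
  for (i in 1:10) {
    db$imaging_study$number_of_series[i] <- 99L
    cur <- evaluate_rule(reg, db)
    expect_lte(cur$pass_pct, prev$pass_pct)
    if (prev$status == "FAIL") expect_equal(cur$status, "FAIL")
    prev <- cur
  }
})

test_that("sum consistency compares study totals against aggregated series counts", {
  db <- consistent_db(50L, series_per_study = 3L, inst_per_series = 4L)
  rule <- load_dq_registry()
  rule <- rule[rule$archetype == "sum_consistency", ][1, ]
  expect_equal(evaluate_rule(rule, db)$status, "PASS")
  db$imaging_study$number_of_instances[7] <- 1L
  r <- evaluate_rule(rule, db)
  expect_equal(r$error_count, 1L)
  expect_equal(r$pass_pct, 98.0)
})

test_that("nearest-rank percentile equals the counting oracle", {
  expect_equal(percentile(1:100, 99), 99)
  expect_equal(percentile(1:100, 1), 1)
  expect_equal(percentile(rep(7, 25), 50), 7)
  expect_equal(percentile(3.5, 1), 3.5)
  expect_error(percentile(numeric(0), 50), "empty")
  set.seed(88)
  for (i in 1:40) {
    vals <- sample(-50:500, sample(c(1, 2, 7, 100, 999), 1), replace = TRUE)
    p <- sample(c(0, 1, 25, 50, 75, 99, 100), 1)
    expect_equal(percentile(vals, p), oracle_percentile(vals, p),
                 info = sprintf("n=%d p=%g", length(vals), p))
  }
})

test_that("outlier evaluation equals a brute-force sort-based recount", {
  reg <- series_attribute_registry()
  rule <- load_dq_registry()
  rule <- rule[rule$archetype == "outlier_percentile" &
                 rule$attribute == "slice_thickness", ][1, ]
  set.seed(89)
  for (trial in 1:10) {
    n <- sample(c(10, 100, 1000), 1)
    vals <- stats::rlnorm(n, 0, 1.5)
    db <- icdm_db()
    db$imaging_series <- data.frame(
      imaging_series_row_id = seq_len(n), imaging_study_id = 1L,
      series_uid = sprintf("2.25.1.%d", seq_len(n)), series_number = 1L,
      series_concept_id = reg[["slice_thickness"]], value_as_number = vals,
      value_as_concept_id = NA_integer_,
      value_source_value = as.character(vals),
      unit_source_value = "mm", stringsAsFactors = FALSE)
    r <- evaluate_rule(rule, db)
    lo <- oracle_percentile(vals, 1)
    hi <- oracle_percentile(vals, 99)
    n_out <- sum(vals < lo | vals > hi)
    expect_equal(r$error_count, n_out)
    expect_equal(r$status, ifelse(100 * n_out / n <= 5, "PASS", "FAIL"))
  }
})

test_that("value-set and nonempty-text rules count offending rows exactly", {
  fix <- small_fixture()
  db <- fix$etl$db
  allreg <- load_dq_registry()
  bb_rule <- allreg[allreg$attribute == "bb_non_bb", ][1, ]
  expect_equal(evaluate_rule(bb_rule, db)$status, "PASS")
  corrupted <- inject_corruption(db, list(n_invalid_bb = 2L), seed = 5)
  r <- evaluate_rule(bb_rule, corrupted$db)
  expect_equal(r$status, "FAIL")
  expect_equal(r$error_count, 2L)

  txt_rule <- allreg[allreg$attribute == "annotation_text" &
                       allreg$archetype == "nonempty_text", ][1, ]
  expect_equal(evaluate_rule(txt_rule, db)$status, "PASS")
  blanked <- inject_corruption(db, list(n_blank_text = 1L), seed = 5)
  expect_equal(evaluate_rule(txt_rule, blanked$db)$error_count, 1L)
})

test_that("an empty evaluated set is a vacuous pass with a warning", {
  empty <- icdm_db()
  rep <- run_dq(empty)
  expect_equal(rep$overall, "PASS")
  expect_true(all(rep$results$evaluated_count == 0))
  expect_true(all(grepl("vacuous", rep$results$warning)))
})

test_that("the report keeps registry order and renders like a QA table", {
  fix <- small_fixture()
  rep <- run_dq(fix$etl$db)
  reg <- load_dq_registry()
  expect_equal(rep$results$rule_id, reg$rule_id)
  expect_equal(rep$overall, "PASS")
  txt <- format_dq_report(rep)
  expect_match(txt[1], "Result")
  expect_match(txt[length(txt)], "Overall: PASS")
  p <- withr::local_tempfile(fileext = ".json")
  write_dq_report(rep, p)
  back <- jsonlite::fromJSON(p)
  expect_equal(back$overall, "PASS")
  expect_equal(nrow(back$results), 44)
})
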