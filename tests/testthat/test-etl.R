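fake_record <- function(st, se, i, modality = "CT", ...) {
  vals <- c(modality = modality, study_date = "20150301",
            manufacturer = "ACME", ...)
  list(file_path = sprintf("/x/%s/%s/%d.dcm", st, se, i), study_uid = st,
       series_uid = se, sop_uid = sprintf("%s.%d", se, i), values = vals,
       pixel_free = TRUE, warnings = character(0), deidentified = TRUE)
}

fake_group <- function(sizes, st = "2.25.9") {
  grp <- lapply(seq_along(sizes), function(s) {
    lapply(seq_len(sizes[s]), function(i) fake_record(st, sprintf("%s.%d", st, s), i))
  })
  names(grp) <- sprintf("%s.%d", st, seq_along(sizes))
  grp
}

test_that("study rows count series and instances from the group", {
  ctx <- mapping_context()
  st <- build_study(fake_group(c(3, 5)), ctx, person_id = 4L,
                    imaging_study_id = 9L)
  expect_equal(st$number_of_series, 2L)
  expect_equal(st$number_of_instances, 8L)
  expect_equal(st$modality_source_value, "CT")
  expect_equal(st$study_date, "2015-03-01")

  single <- build_study(fake_group(1), ctx, 1L)
  expect_equal(single$number_of_series, 1L)
  expect_equal(single$number_of_instances, 1L)

  mixed <- fake_group(c(1, 1, 1))
  mixed[[2]][[1]]$values[["modality"]] <- "MR"
  expect_equal(build_study(mixed, ctx, 1L)$modality_source_value, "CT")

  bad <- fake_group(c(2))
  bad[[1]][[2]]$study_uid <- "2.25.999"
  expect_error(build_study(bad, ctx, 1L), "conflicting study_uid")
})

test_that("series EAV rows carry parsed numbers, concepts and raw sources", {
  ctx <- mapping_context()
  recs <- lapply(1:4, function(i) {
    fake_record("2.25.9", "2.25.9.1", i, slice_thickness = "5.0",
                body_part_examined = "CHEST",
                series_description = "CHEST CT AXIAL")
  })
  eav <- build_series_eav(recs, ctx, imaging_study_id = 2L, row_id_start = 10L)
  rows <- eav$rows
  reg <- series_attribute_registry()
  st_row <- rows[rows$series_concept_id == reg[["slice_thickness"]], ]
  expect_equal(st_row$value_as_number, 5.0)
  expect_equal(st_row$value_source_value, "5.0")
  expect_equal(st_row$unit_source_value, "mm")
  bp_row <- rows[rows$series_concept_id == reg[["body_part_examined"]], ]
  expect_equal(bp_row$value_as_concept_id, 91002001L)
  expect_equal(bp_row$value_source_value, "CHEST")
  n_row <- rows[rows$series_concept_id == reg[["number_of_instances"]], ]
  expect_equal(n_row$value_as_number, 4)
  # CT series: no BB row
  expect_false(reg[["bb_non_bb"]] %in% rows$series_concept_id)
  expect_equal(rows$imaging_series_row_id, 10L + seq_len(nrow(rows)) - 1L)
})

test_that("MR series get a BB row; disagreement across instances is logged", {
  ctx <- mapping_context()
  recs <- lapply(1:2, function(i) {
    fake_record("2.25.9", "2.25.9.2", i, modality = "MR",
                series_description = "BRAIN MR 3D BB T1")
  })
  eav <- build_series_eav(recs, ctx, 1L)
  reg <- series_attribute_registry()
  bb <- eav$rows[eav$rows$series_concept_id == reg[["bb_non_bb"]], ]
  expect_equal(bb$value_as_concept_id, 45884084L)
  expect_equal(bb$value_source_value, "positive")

  recs[[2]]$values[["series_description"]] <- "BRAIN MR OTHER"
  eav2 <- build_series_eav(recs, ctx, 1L)
  expect_match(eav2$disagreements, "series_description", all = FALSE)
})

test_that("procedure linkage requires person, concept and date; ties pick lowest id", {
  study <- list(person_id = 3L, modality_concept_id = 91001001L,
                study_date = "2015-03-01", study_uid = "2.25.9")
  procs <- data.frame(procedure_occurrence_id = c(21L, 7L, 9L),
                      person_id = c(3L, 3L, 2L),
                      procedure_concept_id = c(91001001L, 91001001L, 91001001L),
                      procedure_date = c("2015-03-01", "2015-03-01", "2015-03-01"))
  expect_equal(link_procedure(study, procs), 7L)  # two same-day candidates
  one <- procs[1, ]
  expect_equal(link_procedure(study, one), 21L)
  none <- procs[procs$person_id == 2L, ]
  res <- link_procedure(study, none)
  expect_true(is.na(res))
  expect_match(attr(res, "warning"), "no matching procedure")
})

test_that("filepath rows record on-disk size and normalized format", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("a.dcm", "b.DCM", "c.dcm"))
  sizes <- c(100, 300, 50)
  for (i in 1:3) writeBin(raw(sizes[i]), paths[i])
  fp <- build_filepaths(paths, entity_ids = c(1L, 1L, 2L))
  expect_equal(nrow(fp$rows), 3)
  expect_equal(fp$rows$file_size_bytes, sizes)
  expect_equal(unique(fp$rows$file_format), "dcm")  # ".DCM" lowercased
  expect_length(fp$quarantine, 0)

  unlink(paths[2])
  fp2 <- build_filepaths(paths, entity_ids = c(1L, 1L, 2L))
  expect_equal(nrow(fp2$rows), 2)
  expect_length(fp2$quarantine, 1)
})

test_that("filepath byte totals equal what the generator wrote", {
  fix <- small_fixture()
  expect_equal(sum(fix$etl$db$filepath$file_size_bytes),
               sum(fix$manifest$files$bytes))
  expect_equal(nrow(fix$etl$db$filepath), nrow(fix$manifest$files))
})

test_that("annotation exports become EAV rows; bad rows are quarantined", {
  export <- data.frame(
    study_uid = c("S1", "S1", "S2", "S1"),
    series_uid = "SE", lesion_id = c(1L, 1L, 2L, 3L),
    measure = c("volume", "long_axis", "volume", "volume"),
    value = c("2500.0", "14.2", "oops", "90.5"),
    text = c("GGN", "GGN", "SOLID", ""),
    tool = c("AVIEW", "AVIEW", "AVIEW", "AVIEW"),
    stringsAsFactors = FALSE)
  got <- ingest_annotations(export, study_map = c(S1 = 10L))
  reg <- annotation_attribute_registry()
  # lesion 1: volume + long_axis + one text + one system row; lesion 3:
  # volume + system (blank text not emitted); S2 row quarantined
  expect_equal(sum(got$rows$lesion_id == 1), 4)
  expect_equal(sum(got$rows$lesion_id == 3), 2)
  expect_length(got$quarantine, 1)
  expect_match(got$quarantine[[1]]$reason, "unknown study_uid")
  vol <- got$rows[got$rows$annotation_concept_id == reg[["volume"]] &
                    got$rows$lesion_id == 1, ]
  expect_equal(vol$value_as_number, 2500.0)

  bad_num <- ingest_annotations(export[3, ], study_map = c(S2 = 11L))
  expect_equal(nrow(bad_num$rows), 0)
  expect_match(bad_num$quarantine[[1]]$reason, "malformed numeric")
})

test_that("ETL is internally consistent and idempotent", {
  fix <- small_fixture()
  db <- fix$etl$db
  # conservation: scanned = filepath rows + quarantined
  n_scanned <- nrow(fix$manifest$files)
  expect_equal(nrow(db$filepath) + length(fix$etl$quarantine), n_scanned)
  # counts agree with per-study recount (the construction invariant)
  for (i in seq_len(nrow(db$imaging_study))) {
    se <- db$imaging_series[db$imaging_series$imaging_study_id ==
                              db$imaging_study$imaging_study_id[i], ]
    expect_equal(db$imaging_study$number_of_series[i],
                 length(unique(se$series_uid)))
  }
  # every study links to exactly one procedure on the synthetic archive
  expect_false(any(is.na(db$imaging_study$procedure_occurrence_id)))
  # idempotence: re-running over the same input gives an identical database
  again <- run_etl(file.path(tempdir(), "icdm-fix-small"), salt = "icdm",
                   person_map = fix$clinical$person_map,
                   procedures = fix$clinical$procedure_occurrence,
                   annotations = fix$annotations$export)
  for (tb in c("imaging_study", "imaging_series", "imaging_annotation",
               "filepath")) {
    expect_identical(again$db[[tb]], db[[tb]], info = tb)
  }
})
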