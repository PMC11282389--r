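test_that("scenarios return zero-shaped results on an empty database", {
  db <- icdm_db()
  s1 <- scenario1_ct_frequency(db)
  expect_equal(s1$n_patients, c(0L, 0L))
  s3 <- scenario3_lowdose(db)
  expect_equal(s3$n_lowdose_studies, 0L)
  expect_true(is.na(s3$min_instances))
  s4 <- scenario4_mri_funnel(db)
  expect_equal(unlist(s4[c("total_mr_series", "t1", "contrast", "thin_slice",
                           "young_age")]),
               c(total_mr_series = 0L, t1 = 0L, contrast = 0L,
                 thin_slice = 0L, young_age = 0L))
  s2 <- scenario2_nodule_volumes(db)
  expect_equal(unname(s2$counts), c(0L, 0L, 0L))
  expect_true(is.na(s2$mean_volume_ggn))
})

test_that("nodule volume means are per-label lesion means", {
  db <- icdm_db()
  reg <- annotation_attribute_registry()
  mk <- function(id, lesion, concept, num = NA_real_, src = NA_character_) {
    data.frame(imaging_annotation_row_id = id, imaging_study_id = 1L,
               series_uid = "2.25.1.1", lesion_id = lesion,
               annotation_concept_id = concept, value_as_number = num,
               value_as_concept_id = NA_integer_, value_source_value = src,
               stringsAsFactors = FALSE)
  }
  db$imaging_annotation <- rbind(
    mk(1L, 1L, reg[["volume"]], 10), mk(2L, 1L, reg[["annotation_text"]],
                                        src = "GGN"),
    mk(3L, 2L, reg[["volume"]], 20), mk(4L, 2L, reg[["annotation_text"]],
                                        src = "SOLID_IN_GGN"),
    mk(5L, 3L, reg[["volume"]], 30), mk(6L, 3L, reg[["annotation_text"]],
                                        src = "SOLID"))
  s2 <- scenario2_nodule_volumes(db)
  expect_equal(s2$mean_volume_ggn, 10)
  expect_equal(s2$mean_volume_solid_in_ggn, 20)
  expect_equal(s2$mean_volume_solid_only, 30)
  expect_equal(unname(s2$counts), c(1L, 1L, 1L))
})

test_that("the 150-instance cutoff is strict", {
  db <- icdm_db()
  reg <- series_attribute_registry()
  mk_series <- function(rid, uid, concept, num = NA_real_,
                        src = NA_character_) {
    data.frame(imaging_series_row_id = rid, imaging_study_id = 1L,
               series_uid = uid, series_number = 1L,
               series_concept_id = concept, value_as_number = num,
               value_as_concept_id = NA_integer_, value_source_value = src,
               stringsAsFactors = FALSE)
  }
  db$imaging_study <- data.frame(
    imaging_study_id = 1L, person_id = 1L,
    procedure_occurrence_id = NA_integer_, study_uid = "2.25.1",
    study_date = "2015-03-01", modality_concept_id = 91001001L,
    modality_source_value = "CT", manufacturer_source_value = "ACME",
    number_of_series = 2L, number_of_instances = 301L,
    stringsAsFactors = FALSE)
  db$imaging_series <- rbind(
    mk_series(1L, "2.25.1.1", reg[["series_description"]],
              src = "CHEST CT LOW DOSE"),
    mk_series(2L, "2.25.1.1", reg[["number_of_instances"]], num = 150),
    mk_series(3L, "2.25.1.2", reg[["series_description"]],
              src = "CHEST CT LOWDOSE"),
    mk_series(4L, "2.25.1.2", reg[["number_of_instances"]], num = 151))
  s3 <- scenario3_lowdose(db)
  expect_equal(s3$n_lowdose_studies, 1L)
  expect_equal(s3$n_series_over_min, 1L)  # 150 excluded, 151 counted
  expect_equal(s3$min_instances, 150)
  expect_equal(s3$max_instances, 151)
})

test_that("all four scenario outputs equal brute-force manifest recomputation", {
  fix <- small_fixture()
  db <- fix$etl$db
  o <- oracle_scenarios(fix)

  s1 <- scenario1_ct_frequency(db)
  expect_equal(s1$n_patients, c(o$s1$n_ht, o$s1$n_noht))
  expect_equal(s1$mean_ct_studies, c(o$s1$mean_ht, o$s1$mean_noht))

  s2 <- scenario2_nodule_volumes(db)
  expect_equal(s2$mean_volume_ggn, o$s2$GGN)
  expect_equal(s2$mean_volume_solid_in_ggn, o$s2$SOLID_IN_GGN)
  expect_equal(s2$mean_volume_solid_only, o$s2$SOLID)

  s3 <- scenario3_lowdose(db)
  expect_equal(s3$n_lowdose_studies, o$s3$n_lowdose_studies)
  expect_equal(s3$n_series_over_min, o$s3$n_over)
  expect_equal(s3$min_instances, o$s3$min)
  expect_equal(s3$max_instances, o$s3$max)

  s4 <- scenario4_mri_funnel(db)
  expect_equal(unlist(s4[c("total_mr_series", "t1", "contrast", "thin_slice",
                           "young_age")]),
               o$s4)
})

test_that("the MR funnel is weakly decreasing on generated databases", {
  for (seed in c(3L, 19L)) {
    dir <- file.path(tempdir(), sprintf("icdm-funnel-%d", seed))
    unlink(dir, recursive = TRUE)
    fix <- gen_and_etl(fixture_config(seed = seed, n_patients = 4L), dir)
    s4 <- scenario4_mri_funnel(fix$etl$db)
    counts <- unlist(s4[c("total_mr_series", "t1", "contrast", "thin_slice",
                          "young_age")])
    expect_true(all(diff(counts) <= 0), info = paste(counts, collapse = ","))
    unlink(dir, recursive = TRUE)
  }
})

test_that("scenario results are pure functions of database and config", {
  db <- small_fixture()$etl$db
  expect_identical(scenario1_ct_frequency(db), scenario1_ct_frequency(db))
  expect_identical(scenario4_mri_funnel(db), scenario4_mri_funnel(db))
})
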