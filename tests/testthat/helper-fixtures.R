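# Shared fixtures (memoized: built once per test run) and independent
# brute-force oracles used against the implementation.

.fx <- new.env(parent = emptyenv())

# small end-to-end fixture for unit tests
small_fixture <- function() {
  if (is.null(.fx$small)) {
    dir <- file.path(tempdir(), "icdm-fix-small")
    unlink(dir, recursive = TRUE)
    .fx$small <- gen_and_etl(fixture_config(seed = 11L, n_patients = 8L), dir)
  }
  .fx$small
}

# the full-size fixture of the validation round trip (~50 patients)
big_fixture <- function() {
  if (is.null(.fx$big)) {
    dir <- file.path(tempdir(), "icdm-fix-big")
    unlink(dir, recursive = TRUE)
    .fx$big <- gen_and_etl(fixture_config(seed = 42L), dir)
  }
  .fx$big
}

# a minimal valid imaging_study row
valid_study_row <- function(...) {
  row <- list(imaging_study_id = 1L, person_id = 1L,
              procedure_occurrence_id = NA_integer_,
              study_uid = "2.25.100", study_date = "2015-03-01",
              modality_concept_id = 91001001L, modality_source_value = "CT",
              manufacturer_source_value = "ACME", number_of_series = 2L,
              number_of_instances = 8L)
  utils::modifyList(row, list(...))
}

# independent nearest-rank oracle: smallest value v in the set such that
# at least p% of all values are <= v (counting definition, no sorting
# index arithmetic shared with the implementation)
oracle_percentile <- function(values, p) {
  need <- p / 100 * length(values)
  for (v in sort(unique(values))) {
    if (sum(values <= v) >= need) return(v)
  }
  max(values)
}

# brute-force recount of the study/series count-consistency check
oracle_count_consistency <- function(db) {
  st <- db$imaging_study
  bad <- 0L
  for (i in seq_len(nrow(st))) {
    se <- db$imaging_series[db$imaging_series$imaging_study_id ==
                              st$imaging_study_id[i], ]
    if (is.na(st$number_of_series[i]) ||
        st$number_of_series[i] != length(unique(se$series_uid))) bad <- bad + 1L
  }
  list(error_count = bad, pass_pct = 100 * (nrow(st) - bad) / nrow(st))
}

# age in whole years at first lung-cancer diagnosis, from manifest truth
oracle_age_at_dx <- function(patients) {
  floor(as.numeric(as.Date(patients$dx_date) -
                     as.Date(patients$birth_date)) / 365.25)
}

# brute-force scenario recomputation over the generator manifest
oracle_scenarios <- function(fix) {
  m <- fix$manifest
  pats <- m$patients
  ct_per_pat <- vapply(pats$patient_id, function(pid) {
    sum(m$studies$patient_id == pid & m$studies$modality == "CT")
  }, 0L)
  grp_mean <- function(sel) if (any(sel)) mean(ct_per_pat[sel]) else NA_real_
  s1 <- list(
    n_ht = sum(pats$osimertinib & pats$hypertension),
    n_noht = sum(pats$osimertinib & !pats$hypertension),
    mean_ht = grp_mean(pats$osimertinib & pats$hypertension),
    mean_noht = grp_mean(pats$osimertinib & !pats$hypertension))

  les <- fix$annotations$lesions
  s2 <- lapply(c(GGN = "GGN", SOLID_IN_GGN = "SOLID_IN_GGN", SOLID = "SOLID"),
               function(l) mean(les$volume[les$label == l]))

  ct_uids <- m$studies$study_uid[m$studies$modality == "CT"]
  ld <- m$series[m$series$low_dose & m$series$study_uid %in% ct_uids, ]
  s3 <- list(n_lowdose_studies = length(unique(ld$study_uid)),
             n_over = sum(ld$n_instances > 150),
             min = min(ld$n_instances), max = max(ld$n_instances))

  mr_uids <- m$studies$study_uid[m$studies$modality == "MR"]
  mr <- m$series[m$series$study_uid %in% mr_uids, ]
  t1 <- mr[mr$weighting == "T1", ]
  ce <- t1[t1$contrast_enhanced, ]
  thin <- ce[!is.na(ce$slice_thickness) & ce$slice_thickness <= 1, ]
  ages <- oracle_age_at_dx(pats)
  young_pats <- pats$patient_id[ages <= 60]
  young_uids <- m$studies$study_uid[m$studies$patient_id %in% young_pats]
  s4 <- c(total_mr_series = nrow(mr), t1 = nrow(t1), contrast = nrow(ce),
          thin_slice = nrow(thin),
          young_age = sum(thin$study_uid %in% young_uids))
  list(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
}
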