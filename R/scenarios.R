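# The four lung-cancer cohort scenarios: parametrized queries joining the
# imaging tables to the OMOP clinical stubs. Series semantics (plane,
# contrast, low-dose, weighting) are derived at query time by running the
# deterministic description classifier over the stored series_description
# EAV rows, so the stored tables stay a faithful transcription of the
# DICOM headers.

#' Default scenario configuration
#'
#' @param lung_cancer_concepts,hypertension_concepts,osimertinib_concepts
#'   Concept-id sets for the cohort definitions (defaults: the synthetic
#'   vocabulary's test ids).
#' @param instance_count_min Scenario-3 series size cutoff; strictly more
#'   than this many instances counts.
#' @param slice_thickness_max_mm Scenario-4 slice-thickness cutoff in mm.
#' @param slice_strict If `TRUE` the slice filter is `<` instead of `<=`.
#' @param age_max_years Scenario-4 age-at-diagnosis cutoff.
#' @return A named list.
#' @export
scenario_config <- function(lung_cancer_concepts = 91005001L,
                            hypertension_concepts = 91005002L,
                            osimertinib_concepts = 91006001L,
                            instance_count_min = 150L,
                            slice_thickness_max_mm = 1.0,
                            slice_strict = FALSE,
                            age_max_years = 60L) {
  stopifnot(instance_count_min > 0, slice_thickness_max_mm > 0,
            age_max_years > 0)
  list(lung_cancer_concepts = lung_cancer_concepts,
       hypertension_concepts = hypertension_concepts,
       osimertinib_concepts = osimertinib_concepts,
       instance_count_min = instance_count_min,
       slice_thickness_max_mm = slice_thickness_max_mm,
       slice_strict = slice_strict,
       age_max_years = age_max_years)
}

.persons_with_condition <- function(db, concepts) {
  unique(db$condition_occurrence$person_id[
    db$condition_occurrence$condition_concept_id %in% concepts])
}

# per-series semantics derived from stored description rows
.series_semantics_table <- function(db, lexicon = default_lexicon()) {
  desc <- .attr_rows(db, "imaging_series", "series_description")
  sem <- lapply(desc$value_source_value, classify_description, lexicon = lexicon)
  data.frame(
    imaging_study_id = desc$imaging_study_id,
    series_uid = desc$series_uid,
    plane = vapply(sem, `[[`, "", "plane"),
    contrast_enhanced = vapply(sem, `[[`, TRUE, "contrast_enhanced"),
    low_dose = vapply(sem, `[[`, TRUE, "low_dose"),
    weighting = vapply(sem, `[[`, "", "weighting"),
    stringsAsFactors = FALSE)
}

#' Scenario 1: CT imaging frequency by hypertension status
#'
#' Cohort: persons with a lung-cancer condition and osimertinib exposure.
#' Within the cohort, compares the mean number of CT studies per patient
#' between the hypertensive and non-hypertensive groups (patients with no
#' CT study contribute zero).
#'
#' @param db An `icdm_db` with clinical stub tables populated.
#' @param cfg Scenario configuration.
#' @return A data.frame with rows `hypertension` / `no_hypertension` and
#'   columns `n_patients`, `mean_ct_studies`.
#' @export
scenario1_ct_frequency <- function(db, cfg = scenario_config()) {
  lc <- .persons_with_condition(db, cfg$lung_cancer_concepts)
  osi <- unique(db$drug_exposure$person_id[
    db$drug_exposure$drug_concept_id %in% cfg$osimertinib_concepts])
  cohort <- intersect(lc, osi)
  ht <- .persons_with_condition(db, cfg$hypertension_concepts)
  ct <- db$imaging_study[db$imaging_study$modality_source_value == "CT", ,
                         drop = FALSE]
  group_stats <- function(persons) {
    if (!length(persons)) {
      return(c(n_patients = 0L, mean_ct_studies = NA_real_))
    }
    counts <- vapply(persons, function(p) sum(ct$person_id == p), 0L)
    c(n_patients = length(persons), mean_ct_studies = mean(counts))
  }
  with_ht <- group_stats(intersect(cohort, ht))
  without_ht <- group_stats(setdiff(cohort, ht))
  data.frame(group = c("hypertension", "no_hypertension"),
             n_patients = c(with_ht[["n_patients"]], without_ht[["n_patients"]]),
             mean_ct_studies = c(with_ht[["mean_ct_studies"]],
                                 without_ht[["mean_ct_studies"]]),
             stringsAsFactors = FALSE)
}

#' Scenario 2: nodule volumes by lesion type
#'
#' Mean lesion volume (mm^3) grouped by annotation-text label: pure
#' ground-glass nodules (`GGN`), the solid component inside a GGN
#' (`SOLID_IN_GGN`), and solid nodules without GGN (`SOLID`). Each lesion
#' counts once (volume rows are unique per lesion by schema invariant).
#'
#' @inheritParams scenario1_ct_frequency
#' @return A list: `mean_volume_ggn`, `mean_volume_solid_in_ggn`,
#'   `mean_volume_solid_only`, and `counts` (named lesion counts; a label
#'   with no lesions reports count 0 and mean `NA`).
#' @export
scenario2_nodule_volumes <- function(db, cfg = scenario_config()) {
  vol <- .attr_rows(db, "imaging_annotation", "volume")
  txt <- .attr_rows(db, "imaging_annotation", "annotation_text")
  key <- function(d) paste(d$imaging_study_id, d$lesion_id)
  labels <- stats::setNames(txt$value_source_value, key(txt))
  vol$label <- labels[key(vol)]
  stat <- function(lbl) {
    v <- vol$value_as_number[!is.na(vol$label) & vol$label == lbl]
    list(n = length(v), mean = if (length(v)) mean(v) else NA_real_)
  }
  g <- stat("GGN"); sg <- stat("SOLID_IN_GGN"); s <- stat("SOLID")
  list(mean_volume_ggn = g$mean,
       mean_volume_solid_in_ggn = sg$mean,
       mean_volume_solid_only = s$mean,
       counts = c(ggn = g$n, solid_in_ggn = sg$n, solid_only = s$n))
}

#' Scenario 3: low-dose CT use and series instance range
#'
#' Counts CT studies with at least one low-dose series, the low-dose
#' series holding strictly more than `instance_count_min` instances, and
#' the smallest/largest low-dose series.
#'
#' @inheritParams scenario1_ct_frequency
#' @param lexicon Token lexicon for description classification.
#' @return A list: `n_lowdose_studies`, `n_series_over_min`,
#'   `min_instances`, `max_instances` (the latter two `NA` when no
#'   low-dose series exists).
#' @export
scenario3_lowdose <- function(db, cfg = scenario_config(),
                              lexicon = default_lexicon()) {
  sem <- .series_semantics_table(db, lexicon)
  ct_studies <- db$imaging_study$imaging_study_id[
    db$imaging_study$modality_source_value == "CT"]
  ld <- sem[sem$low_dose & sem$imaging_study_id %in% ct_studies, ,
            drop = FALSE]
  if (!nrow(ld)) {
    return(list(n_lowdose_studies = 0L, n_series_over_min = 0L,
                min_instances = NA_real_, max_instances = NA_real_))
  }
  inst <- .attr_rows(db, "imaging_series", "number_of_instances")
  counts <- inst$value_as_number[match(ld$series_uid, inst$series_uid)]
  list(n_lowdose_studies = length(unique(ld$imaging_study_id)),
       n_series_over_min = sum(counts > cfg$instance_count_min, na.rm = TRUE),
       min_instances = min(counts, na.rm = TRUE),
       max_instances = max(counts, na.rm = TRUE))
}

#' Scenario 4: enhanced thin-slice T1 MR funnel
#'
#' Successive filters over MR series, each applied to the survivors of the
#' previous one: T1 weighting, contrast enhancement, slice thickness at or
#' under the cutoff (series without a slice-thickness row are excluded at
#' that stage and logged), and age at first lung-cancer diagnosis at or
#' under the cutoff. Counts are weakly decreasing by construction.
#'
#' @inheritParams scenario3_lowdose
#' @return A list of the five funnel counts: `total_mr_series`, `t1`,
#'   `contrast`, `thin_slice`, `young_age`, plus `log`.
#' @export
scenario4_mri_funnel <- function(db, cfg = scenario_config(),
                                 lexicon = default_lexicon()) {
  log <- character(0)
  mr_studies <- db$imaging_study[db$imaging_study$modality_source_value == "MR", ,
                                 drop = FALSE]
  all_series <- unique(db$imaging_series[
    db$imaging_series$imaging_study_id %in% mr_studies$imaging_study_id,
    c("imaging_study_id", "series_uid")])
  sem <- .series_semantics_table(db, lexicon)
  sem <- sem[sem$series_uid %in% all_series$series_uid, , drop = FALSE]

  t1 <- sem[sem$weighting == "T1", , drop = FALSE]
  ce <- t1[t1$contrast_enhanced, , drop = FALSE]

  thick <- .attr_rows(db, "imaging_series", "slice_thickness")
  st <- thick$value_as_number[match(ce$series_uid, thick$series_uid)]
  missing_st <- is.na(st)
  if (any(missing_st)) {
    log <- c(log, sprintf("%d series lack a slice-thickness row; excluded at the thin-slice stage",
                          sum(missing_st)))
  }
  thin <- ce[!missing_st &
               (if (isTRUE(cfg$slice_strict)) st < cfg$slice_thickness_max_mm
                else st <= cfg$slice_thickness_max_mm), , drop = FALSE]

  # age at first lung-cancer diagnosis, per person
  lc <- db$condition_occurrence[
    db$condition_occurrence$condition_concept_id %in% cfg$lung_cancer_concepts, ,
    drop = FALSE]
  first_dx <- tapply(as.Date(lc$condition_start_date), lc$person_id, min)
  birth <- stats::setNames(as.Date(db$person$birth_date), db$person$person_id)
  age_ok <- function(pid) {
    p <- as.character(pid)
    if (!p %in% names(first_dx) || is.na(birth[p])) return(FALSE)
    age <- as.numeric(as.Date(first_dx[p], origin = "1970-01-01") - birth[p]) / 365.25
    floor(age) <= cfg$age_max_years
  }
  person_of_study <- stats::setNames(mr_studies$person_id,
                                     mr_studies$imaging_study_id)
  young <- thin[vapply(person_of_study[as.character(thin$imaging_study_id)],
                       age_ok, TRUE), , drop = FALSE]

  list(total_mr_series = nrow(all_series), t1 = nrow(t1), contrast = nrow(ce),
       thin_slice = nrow(thin), young_age = nrow(young), log = log)
}
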