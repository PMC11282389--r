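# Seeded synthetic fixture generator: DICOM files with controlled headers
# and a series-description token grammar, OMOP clinical stubs with
# plantable cohort effects, annotation exports with configurable
# lesion-type volume distributions, and corruption injection. The
# generator records every truth in a manifest, which acceptance tests use
# as an independent oracle.
#
# Defaults encode the study conditions the package is validated under:
# a lung-cancer cohort mixing chest X-ray, chest CT and brain MR, CT scan
# frequency differing slightly by hypertension status, and lesion volumes
# lognormal around the landmark means for GGN / solid-in-GGN / solid
# nodules. PHI (names, ids, birth dates) is deliberately planted so
# de-identification tests can grep exports for leakage.

#' Configuration for the synthetic fixture generator
#'
#' @param seed Integer seed; every output is a pure function of
#'   (config, seed).
#' @param n_patients Cohort size.
#' @param fraction_hypertension,fraction_osimertinib Cohort effect
#'   fractions.
#' @param ct_mean_ht,ct_mean_noht Mean CT studies per patient (Poisson) by
#'   hypertension status.
#' @param xray_mean,mr_mean Mean X-ray / MR studies per patient (Poisson).
#' @param ct_series_mean,mr_series_mean Mean extra series per CT / MR
#'   study (1 + Poisson).
#' @param ct_volume_series_prob Probability a CT series is a thin-cut
#'   volume series with 120-220 instances (others get 3 + Poisson(4)).
#' @param mr_instances_mean MR instances per series are 4 + Poisson(this).
#' @param p_lowdose,p_contrast_ct,p_contrast_mr,p_bb Token-grammar
#'   probabilities.
#' @param p_t1,p_t2 MR weighting probabilities (remainder: other).
#' @param plane_probs Probabilities for axial/coronal/sagittal/unknown.
#' @param p_annotated_ct Probability an annotated chest CT study carries
#'   lesions (1-3 each).
#' @param lesion_label_probs Probabilities for GGN / SOLID_IN_GGN / SOLID.
#' @param volume_means Target mean lesion volume (mm^3) per label.
#' @param volume_sdlog Lognormal shape parameter for volumes.
#' @param age_mean,age_sd Age at diagnosis (years), normal.
#' @return A named list of class `icdm_fixture_config`.
#' @export
fixture_config <- function(seed = 42L,
                           n_patients = 50L,
                           fraction_hypertension = 0.4,
                           fraction_osimertinib = 0.5,
                           ct_mean_ht = 1.8,
                           ct_mean_noht = 2.2,
                           xray_mean = 0.7,
                           mr_mean = 0.7,
                           ct_series_mean = 2,
                           mr_series_mean = 5,
                           ct_volume_series_prob = 0.06,
                           mr_instances_mean = 3,
                           p_lowdose = 0.3,
                           p_contrast_ct = 0.3,
                           p_contrast_mr = 0.5,
                           p_bb = 0.2,
                           p_t1 = 0.5,
                           p_t2 = 0.4,
                           plane_probs = c(axial = 0.5, coronal = 0.15,
                                           sagittal = 0.15, unknown = 0.2),
                           p_annotated_ct = 0.35,
                           lesion_label_probs = c(GGN = 0.3, SOLID_IN_GGN = 0.25,
                                                  SOLID = 0.45),
                           volume_means = c(GGN = 8135.616,
                                            SOLID_IN_GGN = 2578.006,
                                            SOLID = 34712.58),
                           volume_sdlog = 0.5,
                           age_mean = 62,
                           age_sd = 9) {
  stopifnot(abs(sum(plane_probs) - 1) < 1e-9,
            abs(sum(lesion_label_probs) - 1) < 1e-9,
            p_t1 + p_t2 <= 1, n_patients > 0)
  structure(as.list(environment()), class = "icdm_fixture_config")
}

.pick <- function(x, n = 1, prob = NULL) {
  if (length(x) == 1) rep(x, n) else sample(x, n, replace = TRUE, prob = prob)
}

#' Generate a synthetic DICOM archive
#'
#' Writes valid Part 10 files (tiny 8x8 pixel payloads) under `out_dir`,
#' headers drawn from the config, series descriptions composed from the
#' classifier's token grammar so planted labels are exactly recoverable.
#'
#' @param cfg A [fixture_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return The manifest: list of data.frames `patients`, `studies`,
#'   `series`, `files`, plus `phi_strings` and the config.
#' @export
gen_imaging <- function(cfg, out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop("out_dir exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  uid_root <- "1.2.826.0.1.999999"

  planes <- names(cfg$plane_probs)
  plane_desc_tok <- list(axial = c("AX", "AXIAL", "TRA"),
                         coronal = c("COR", "CORONAL"),
                         sagittal = c("SAG", "SAGITTAL"),
                         unknown = character(0))
  lowdose_tok <- c("LOW DOSE", "LOWDOSE", "LD")
  contrast_tok <- c("+C", "CE", "POST")
  t1_tok <- c("T1", "T1W")
  t2_tok <- c("T2", "T2W", "FLAIR")
  bb_tok <- c("BB", "BLACK BLOOD")
  manufacturers <- c("SIEMENS", "GE MEDICAL SYSTEMS", "PHILIPS HEALTHCARE",
                     "CANON MEDICAL")

  patients <- data.frame(
    patient_id = sprintf("SYNPID%03d", seq_len(cfg$n_patients)),
    patient_name = sprintf("SYNTHPHI^PATIENT%03d", seq_len(cfg$n_patients)),
    hypertension = stats::runif(cfg$n_patients) < cfg$fraction_hypertension,
    osimertinib = stats::runif(cfg$n_patients) < cfg$fraction_osimertinib,
    stringsAsFactors = FALSE)
  dx <- as.Date("2010-01-01") + floor(stats::runif(cfg$n_patients) * 2922)
  age_days <- round((cfg$age_mean + cfg$age_sd * stats::rnorm(cfg$n_patients)) * 365.25)
  patients$dx_date <- format(dx)
  patients$birth_date <- format(dx - age_days)

  studies <- list(); series <- list(); files <- list()
  study_n <- 0L

  for (p in seq_len(cfg$n_patients)) {
    ct_mean <- if (patients$hypertension[p]) cfg$ct_mean_ht else cfg$ct_mean_noht
    n_by_mod <- c(CT = stats::rpois(1, ct_mean),
                  XR = stats::rpois(1, cfg$xray_mean),
                  MR = stats::rpois(1, cfg$mr_mean))
    mods <- rep(names(n_by_mod), n_by_mod)
    for (mod0 in mods) {
      study_n <- study_n + 1L
      modality <- switch(mod0, XR = .pick(c("CR", "DX")), mod0)
      study_uid <- sprintf("%s.%d.%d", uid_root, p, study_n)
      study_date <- format(as.Date(patients$dx_date[p]) +
                             floor(stats::runif(1) * 1461), "%Y%m%d")
      n_series <- switch(mod0, XR = 1L,
                         CT = 1L + stats::rpois(1, cfg$ct_series_mean),
                         MR = 1L + stats::rpois(1, cfg$mr_series_mean))
      manufacturer <- .pick(manufacturers)
      study_dir <- file.path(out_dir, sprintf("P%03d", p),
                             sprintf("ST%05d", study_n))
      total_inst <- 0L
      for (s in seq_len(n_series)) {
        series_uid <- sprintf("%s.%d", study_uid, s)
        plane <- .pick(planes, prob = cfg$plane_probs)
        low_dose <- mod0 == "CT" && stats::runif(1) < cfg$p_lowdose
        contrast <- stats::runif(1) < switch(mod0, CT = cfg$p_contrast_ct,
                                             MR = cfg$p_contrast_mr, 0)
        weighting <- if (mod0 == "MR") {
          .pick(c("T1", "T2", "other"),
                prob = c(cfg$p_t1, cfg$p_t2, 1 - cfg$p_t1 - cfg$p_t2))
        } else "other"
        bb <- if (mod0 == "MR") stats::runif(1) < cfg$p_bb else NA

        toks <- switch(mod0, CT = c("CHEST", "CT"), MR = c("BRAIN", "MR"),
                       XR = c("CHEST", "XR"))
        if (weighting == "T1") toks <- c(toks, .pick(t1_tok))
        if (weighting == "T2") toks <- c(toks, .pick(t2_tok))
        if (isTRUE(bb)) toks <- c(toks, .pick(bb_tok))
        if (length(plane_desc_tok[[plane]])) {
          toks <- c(toks, .pick(plane_desc_tok[[plane]]))
        }
        if (contrast) toks <- c(toks, .pick(contrast_tok))
        if (low_dose) toks <- c(toks, .pick(lowdose_tok))
        description <- paste(toks, collapse = " ")

        n_inst <- switch(mod0, XR = 1L,
                         CT = if (stats::runif(1) < cfg$ct_volume_series_prob) {
                           .pick(120:220)
                         } else 3L + stats::rpois(1, 4),
                         MR = 4L + stats::rpois(1, cfg$mr_instances_mean))
        slice <- switch(mod0,
                        CT = .pick(c(0.6, 0.9, 1, 1.25, 2.5, 5),
                                   prob = c(.1, .1, .15, .2, .25, .2)),
                        MR = .pick(c(0.5, 0.8, 0.9, 1, 3, 5),
                                   prob = c(.15, .15, .2, .15, .2, .15)),
                        XR = NA_real_)
        mat <- switch(mod0, CT = 512L, MR = 256L, XR = 2048L)
        wc <- switch(mod0, CT = .pick(c("-600", "40")), MR = "300", XR = "2048")
        ww <- switch(mod0, CT = .pick(c("1500", "400")), MR = "600", XR = "4096")
        body_part <- switch(mod0, MR = "BRAIN", "CHEST")
        laterality <- if (stats::runif(1) < 0.2) .pick(c("L", "R", "B")) else NA
        position <- .pick(c("HFS", "FFS"), prob = c(.9, .1))

        series_dir <- file.path(study_dir, sprintf("SE%02d", s))
        dir.create(series_dir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_len(n_inst)) {
          el <- list(
            SOPInstanceUID = sprintf("%s.%d", series_uid, k),
            StudyInstanceUID = study_uid, SeriesInstanceUID = series_uid,
            StudyDate = study_date, Modality = modality,
            Manufacturer = manufacturer, SeriesDescription = description,
            PatientName = patients$patient_name[p],
            PatientID = patients$patient_id[p],
            PatientBirthDate = gsub("-", "", patients$birth_date[p]),
            SeriesNumber = as.character(s),
            Rows = mat, Columns = mat, WindowCenter = wc, WindowWidth = ww,
            BodyPartExamined = body_part, PatientPosition = position)
          if (!is.na(slice)) el$SliceThickness <- format(slice)
          if (!is.na(laterality)) el$Laterality <- laterality
          if (mod0 == "MR" && isTRUE(bb)) el$SequenceName <- "tse_bb"
          fp <- file.path(series_dir, sprintf("IM%04d.dcm", k))
          dicom_write(fp, el)
          files[[length(files) + 1L]] <- data.frame(
            path = fp,
            rel_path = substring(fp, nchar(out_dir) + 2L),
            bytes = file.info(fp)$size, study_uid = study_uid,
            series_uid = series_uid, stringsAsFactors = FALSE)
        }
        series[[length(series) + 1L]] <- data.frame(
          study_uid = study_uid, series_uid = series_uid, modality = modality,
          description = description, plane = plane,
          contrast_enhanced = contrast, low_dose = low_dose,
          weighting = weighting, bb = bb, n_instances = n_inst,
          slice_thickness = slice, matrix_size = mat,
          body_part = body_part, stringsAsFactors = FALSE)
        total_inst <- total_inst + n_inst
      }
      studies[[study_n]] <- data.frame(
        study_uid = study_uid, patient_id = patients$patient_id[p],
        modality = modality, study_date = study_date, n_series = n_series,
        n_instances = total_inst, stringsAsFactors = FALSE)
    }
  }
  list(patients = patients,
       studies = do.call(rbind, studies),
       series = do.call(rbind, series),
       files = do.call(rbind, files),
       phi_strings = c(patients$patient_name, patients$patient_id,
                       gsub("-", "", patients$birth_date)),
       config = cfg)
}

#' Generate the OMOP clinical stub tables for a manifest
#'
#' Every study in the manifest gets a matching same-day
#' PROCEDURE_OCCURRENCE row with the study's modality-mapped procedure
#' concept, so procedure linkage can succeed for all studies. Person
#' source values are the de-identification pseudonyms (PHI never enters
#' the clinical tables).
#'
#' @param manifest A manifest from [gen_imaging()].
#' @param salt De-identification salt the ETL will use.
#' @param ctx Mapping context (for modality -> procedure concepts).
#' @return A list of data.frames: `person`, `condition_occurrence`,
#'   `drug_exposure`, `procedure_occurrence`, `person_map`.
#' @export
gen_clinical <- function(manifest, salt = "icdm", ctx = mapping_context()) {
  cfg <- manifest$config
  set.seed(cfg$seed + 1L)
  pats <- manifest$patients
  person <- data.frame(
    person_id = seq_len(nrow(pats)),
    person_source_value = vapply(pats$patient_id, pseudonymize, "", salt = salt),
    birth_date = pats$birth_date, stringsAsFactors = FALSE)

  lc_concept <- 91005001L; ht_concept <- 91005002L; osi_concept <- 91006001L
  cond <- rbind(
    data.frame(person_id = person$person_id, condition_concept_id = lc_concept,
               condition_start_date = pats$dx_date, stringsAsFactors = FALSE),
    data.frame(person_id = person$person_id[pats$hypertension],
               condition_concept_id = rep(ht_concept, sum(pats$hypertension)),
               condition_start_date = format(as.Date(pats$dx_date[pats$hypertension]) -
                                               .pick(30:900, sum(pats$hypertension))),
               stringsAsFactors = FALSE))
  cond <- cond[order(cond$person_id, cond$condition_concept_id), ]
  cond <- data.frame(condition_occurrence_id = seq_len(nrow(cond)), cond,
                     stringsAsFactors = FALSE)

  n_osi <- sum(pats$osimertinib)
  drug <- data.frame(person_id = person$person_id[pats$osimertinib],
                     drug_concept_id = rep(osi_concept, n_osi),
                     drug_exposure_start_date = if (n_osi) {
                       format(as.Date(pats$dx_date[pats$osimertinib]) +
                                .pick(0:60, n_osi))
                     } else character(0),
                     stringsAsFactors = FALSE)
  drug <- data.frame(drug_exposure_id = seq_len(nrow(drug)), drug,
                     stringsAsFactors = FALSE)

  st <- manifest$studies
  proc <- data.frame(
    procedure_occurrence_id = seq_len(nrow(st)),
    person_id = person$person_id[match(st$patient_id, pats$patient_id)],
    procedure_concept_id = vapply(st$modality, modality_to_procedure_concept,
                                  0L, ctx$concept_map, ctx$registry),
    procedure_date = .da_to_iso_vec(st$study_date), stringsAsFactors = FALSE)

  list(person = person, condition_occurrence = cond, drug_exposure = drug,
       procedure_occurrence = proc, person_map = person)
}

.da_to_iso_vec <- function(x) vapply(x, .da_to_iso, "")

#' Generate an annotation export for a manifest
#'
#' Lesions are planted on chest CT studies; volumes are lognormal with the
#' configured per-label target means. The export references the
#' de-identified (remapped) study and series UIDs, like a labeling tool
#' working on the cleaned archive.
#'
#' @param manifest A manifest from [gen_imaging()].
#' @param salt De-identification salt (to reference remapped UIDs).
#' @return List: `export` (data.frame with columns study_uid, series_uid,
#'   lesion_id, measure, value, text, tool) and `lesions` (ground truth).
#' @export
gen_annotations <- function(manifest, salt = "icdm") {
  cfg <- manifest$config
  set.seed(cfg$seed + 2L)
  ct <- manifest$studies[manifest$studies$modality == "CT", , drop = FALSE]
  labels <- names(cfg$lesion_label_probs)
  lesions <- list()
  lesion_n <- 0L
  for (i in seq_len(nrow(ct))) {
    if (stats::runif(1) >= cfg$p_annotated_ct) next
    first_series <- manifest$series$series_uid[
      manifest$series$study_uid == ct$study_uid[i]][1]
    for (k in seq_len(.pick(1:3))) {
      lesion_n <- lesion_n + 1L
      label <- .pick(labels, prob = cfg$lesion_label_probs)
      mu <- log(cfg$volume_means[[label]]) - cfg$volume_sdlog^2 / 2
      lesions[[lesion_n]] <- data.frame(
        study_uid = ct$study_uid[i], series_uid = first_series,
        lesion_id = lesion_n, label = label,
        volume = round(stats::rlnorm(1, mu, cfg$volume_sdlog), 1),
        long_axis = round(stats::rlnorm(1, log(15), 0.4), 1),
        surface = round(stats::rlnorm(1, log(700), 0.5), 1),
        tool = .pick(c("AVIEW", "SYNTHSEG"), prob = c(.6, .4)),
        stringsAsFactors = FALSE)
    }
  }
  if (!lesion_n) {
    return(list(export = data.frame(study_uid = character(0),
                                    series_uid = character(0),
                                    lesion_id = integer(0), measure = character(0),
                                    value = character(0), text = character(0),
                                    tool = character(0), stringsAsFactors = FALSE),
                lesions = NULL))
  }
  les <- do.call(rbind, lesions)
  mk <- function(measure, value) {
    data.frame(study_uid = vapply(les$study_uid, remap_uid, "", salt = salt),
               series_uid = vapply(les$series_uid, remap_uid, "", salt = salt),
               lesion_id = les$lesion_id, measure = measure,
               value = as.character(value), text = les$label, tool = les$tool,
               stringsAsFactors = FALSE)
  }
  export <- rbind(mk("volume", les$volume), mk("long_axis", les$long_axis),
                  mk("surface", les$surface))
  export <- export[order(export$lesion_id, export$measure), ]
  rownames(export) <- NULL
  list(export = export, lesions = les)
}

#' Inject controlled corruptions into a database
#'
#' Supported corruptions: study series-count mismatches, nulled numeric
#' EAV values, planted extreme outliers, invalid BB concept ids, blanked
#' annotation text. Victims are sampled under the seed and recorded
#' exactly in the returned ledger.
#'
#' @param db A clean `icdm_db`.
#' @param spec Named list: any of `n_count_mismatch`,
#'   `n_null_numeric` (+ `numeric_attribute`), `n_outliers`
#'   (+ `outlier_attribute`, `outlier_factor`), `n_invalid_bb`,
#'   `n_blank_text`.
#' @param seed RNG seed for victim selection.
#' @return List: `db` (corrupted), `ledger` (data.frame: kind, table, key).
#' @export
inject_corruption <- function(db, spec, seed = 1L) {
  set.seed(seed)
  ledger <- list()
  note <- function(kind, table, key) {
    ledger[[length(ledger) + 1L]] <<- data.frame(kind = kind, table = table,
                                                 key = as.character(key),
                                                 stringsAsFactors = FALSE)
  }
  k <- spec$n_count_mismatch
  if (!is.null(k) && k > 0) {
    if (k > nrow(db$imaging_study)) stop("n_count_mismatch exceeds study count")
    vict <- sample(db$imaging_study$imaging_study_id, k)
    idx <- match(vict, db$imaging_study$imaging_study_id)
    db$imaging_study$number_of_series[idx] <-
      db$imaging_study$number_of_series[idx] + 1L
    for (v in sort(vict)) note("count_mismatch", "imaging_study", v)
  }
  k <- spec$n_null_numeric
  if (!is.null(k) && k > 0) {
    attr_name <- spec$numeric_attribute %||% "slice_thickness"
    rows <- which(db$imaging_series$series_concept_id ==
                    series_attribute_registry()[[attr_name]] &
                    !is.na(db$imaging_series$value_as_number))
    if (k > length(rows)) stop("n_null_numeric exceeds available rows")
    vict <- sample(rows, k)
    db$imaging_series$value_as_number[vict] <- NA_real_
    for (v in sort(db$imaging_series$imaging_series_row_id[vict])) {
      note("null_numeric", "imaging_series", v)
    }
  }
  k <- spec$n_outliers
  if (!is.null(k) && k > 0) {
    attr_name <- spec$outlier_attribute %||% "slice_thickness"
    fac <- spec$outlier_factor %||% 1000
    rows <- which(db$imaging_series$series_concept_id ==
                    series_attribute_registry()[[attr_name]] &
                    !is.na(db$imaging_series$value_as_number))
    if (k > length(rows)) stop("n_outliers exceeds available rows")
    vict <- sample(rows, k)
    db$imaging_series$value_as_number[vict] <-
      db$imaging_series$value_as_number[vict] * fac
    for (v in sort(db$imaging_series$imaging_series_row_id[vict])) {
      note("outlier", "imaging_series", v)
    }
  }
  k <- spec$n_invalid_bb
  if (!is.null(k) && k > 0) {
    rows <- which(db$imaging_series$series_concept_id ==
                    series_attribute_registry()[["bb_non_bb"]])
    if (k > length(rows)) stop("n_invalid_bb exceeds available BB rows")
    vict <- sample(rows, k)
    db$imaging_series$value_as_concept_id[vict] <- 0L
    for (v in sort(db$imaging_series$imaging_series_row_id[vict])) {
      note("invalid_bb", "imaging_series", v)
    }
  }
  k <- spec$n_blank_text
  if (!is.null(k) && k > 0) {
    reg <- annotation_attribute_registry()
    rows <- which(db$imaging_annotation$annotation_concept_id ==
                    reg[["annotation_text"]])
    if (k > length(rows)) stop("n_blank_text exceeds annotation-text rows")
    vict <- sample(rows, k)
    db$imaging_annotation$value_source_value[vict] <- ""
    for (v in sort(db$imaging_annotation$imaging_annotation_row_id[vict])) {
      note("blank_text", "imaging_annotation", v)
    }
  }
  list(db = db,
       ledger = if (length(ledger)) do.call(rbind, ledger)
                else data.frame(kind = character(0), table = character(0),
                                key = character(0), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete fixture and run the ETL over it
#'
#' Convenience wrapper used by tests, the acceptance script and the CLI:
#' generates the archive, the clinical stubs and the annotation export,
#' then runs the ETL.
#'
#' @param cfg A [fixture_config()].
#' @param out_dir Directory for the DICOM archive.
#' @param salt De-identification salt.
#' @return List: `etl` (the [run_etl()] result), `manifest`, `clinical`,
#'   `annotations`.
#' @export
gen_and_etl <- function(cfg, out_dir, salt = "icdm") {
  manifest <- gen_imaging(cfg, out_dir)
  clinical <- gen_clinical(manifest, salt = salt)
  ann <- gen_annotations(manifest, salt = salt)
  etl <- run_etl(out_dir, salt = salt,
                 person_map = clinical$person_map,
                 procedures = clinical$procedure_occurrence,
                 annotations = ann$export)
  etl$db$condition_occurrence <- clinical$condition_occurrence
  etl$db$drug_exposure <- clinical$drug_exposure
  list(etl = etl, manifest = manifest, clinical = clinical, annotations = ann)
}
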