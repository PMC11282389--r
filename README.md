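# imagingcdm

An R implementation of an imaging extension to the OMOP Common Data Model
(CDM): four tables — `IMAGING_STUDY`, `IMAGING_SERIES`, `IMAGING_ANNOTATION`
and `FILEPATH` — populated automatically from DICOM headers, so that medical
imaging metadata can be queried alongside standardized clinical data
(`PERSON`, `CONDITION_OCCURRENCE`, `DRUG_EXPOSURE`, `PROCEDURE_OCCURRENCE`).

## Who this is for

Clinical-research data engineers and imaging informaticists who hold (a) a
DICOM archive and (b) an OMOP CDM instance, and want cohort queries that mix
both — e.g. *"CT imaging frequency in osimertinib-treated lung-cancer
patients with vs. without hypertension"* — without hand-curating imaging
spreadsheets.

## The model

- `IMAGING_STUDY` holds one row per DICOM study (modality, manufacturer,
  series/instance counts) and references the `PROCEDURE_OCCURRENCE` row of
  the imaging order (same person, same date, matching procedure concept).
- `IMAGING_SERIES` and `IMAGING_ANNOTATION` use an entity–attribute–value
  (EAV) layout: each attribute–value pair (slice thickness, rows, columns,
  window center/width, body part, laterality, patient position, series
  description, per-series instance count, Black-Blood status; lesion volume,
  long axis, surface, text, annotation system) is its own row, identified by
  a concept id. New attributes are new rows, never schema changes.
- Source values are concept-mapped where a curated mapping exists (e.g.
  body part `CHEST` → the *chest imaging* procedure concept); everything
  else receives a deterministic custom concept id ≥ 2,000,000,000 (the OHDSI
  site-local convention), with the raw string always preserved in the
  `*_source_value` column. An optional RadLex crosswalk attaches RadLex ids.
- `FILEPATH` bridges CDM rows to files on disk (path, size in bytes, format).

Around the schema sit: a DICOM Part 10 header reader (nonempty tags only,
pixel data never loaded), de-identification (PHI removal, keyed pseudonyms,
deterministic UID remapping), rule-based parsing of Series Description text
into plane / contrast / low-dose / T1–T2 weighting / Black-Blood semantics,
a declarative **44-rule data-quality engine** (consistency, completeness,
value-set and 1st/99th-percentile outlier checks with PASS/FAIL thresholds),
four lung-cancer cohort scenario queries, and a seeded synthetic generator
that emits DICOM files + clinical stubs + annotation exports together with a
ground-truth manifest used as the test oracle.

## Worked example

```r
library(imagingcdm)

# 1. a seeded synthetic archive (stand-in for a real DICOM export)
cfg <- fixture_config(seed = 1, n_patients = 50)
fix <- gen_and_etl(cfg, "archive")   # generate + scan + de-identify + ETL
db  <- fix$etl$db
db
#> <imaging CDM database>
#>   imaging_study             164 rows
#>   imaging_series           5062 rows
#>   imaging_annotation        268 rows
#>   filepath                 6941 rows
#>   ...

# 2. data quality: 44 declarative rules
report <- run_dq(db)
report$overall
#> [1] "PASS"

# 3. a cohort query: the MR funnel (T1 -> contrast -> thin slice -> age)
scenario4_mri_funnel(db)[1:5]
#> $total_mr_series  178
#> $t1                77
#> $contrast          37
#> $thin_slice        26
#> $young_age         14
```

The funnel counts are successive filters over MR series, so they are weakly
decreasing; `run_dq()` reports one PASS/FAIL row per rule with the passing
percentage and error count (boundary semantics: a result exactly at the
threshold passes).

A command-line interface wraps the same functions:

```sh
exec/imagingcdm synth  --out archive --seed 1
exec/imagingcdm ingest --dicom archive --out tables \
    --person-map archive/person_map.csv --procedures archive/procedure_occurrence.csv
exec/imagingcdm dq --tables tables --strict
```

## Package layout

- `R/` — schema + DDL, DICOM I/O, ingest/de-identification, description
  semantics, vocabulary mapping, ETL, DQ engine, scenarios, synthetic
  generator, CLI.
- `inst/extdata/` — synthetic mini vocabulary, concept map and RadLex
  crosswalk (user-replaceable stand-ins for licensed vocabularies; files are
  labelled `_synthetic`), and the default 44-rule DQ registry CSV.
- `vignettes/imaging-cdm-methods.Rmd` — the methods vignette: model,
  assumptions, parameters, numerical choices, limitations.
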