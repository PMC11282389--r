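---
title: "Methods: an imaging extension to the OMOP CDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an imaging extension to the OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Observational imaging research needs DICOM metadata and clinical data in one
queryable store. `imagingcdm` extends an OMOP CDM instance with four tables:

* **IMAGING_STUDY** — one row per study: person, study date, modality
  (mapped to a Procedure-class concept), manufacturer, the number of series
  and the number of instances, and a reference to the
  `PROCEDURE_OCCURRENCE` row carrying the imaging order.
* **IMAGING_SERIES** — entity–attribute–value (EAV): one row per
  (study, series, attribute). Series identity lives in the `series_uid`
  column of each EAV row; there is no companion "series header" table. We
  chose the flat EAV-only design because every series-level question the
  package answers (counts, filters, funnels) is an aggregation over
  attribute rows, and a header table would duplicate the grouping keys.
* **IMAGING_ANNOTATION** — EAV rows per (lesion, measure): annotation
  system, annotation text, volume (mm³), long axis (mm), surface area (mm²).
* **FILEPATH** — one row per instance *file* (path, byte size, format
  token), with `entity_kind = "study"` pointing at the owning study. File
  granularity was chosen because file-level sizes are what storage planning
  and AI data loaders need; study- or series-level totals are derivable.

Column naming follows the FHIR `ImagingStudy` profile conventions where they
apply. DDL is emitted for generic SQL, SQLite and PostgreSQL; the in-memory
representation is a list of data frames, and SQLite loading is built in.

Assumptions: one patient per study; `StudyInstanceUID`/`SeriesInstanceUID`
define the hierarchy; header attributes are series-constant (violations are
logged, and the first instance's value is kept — a deliberate tie-break,
since per-instance variation in nominally series-level tags is noise from
the perspective of series-level queries).

## Header extraction and de-identification

Only configured, **present and nonempty** tags are extracted; raw strings
are preserved verbatim and always survive in `value_source_value` even after
concept mapping. A value that fails its declared class (numeric, date) is
kept as text with a warning — completeness failures are the data-quality
engine's job, not the reader's. Files that do not parse as DICOM Part 10,
use a transfer syntax other than explicit VR little endian, or lack the two
hierarchy UIDs are quarantined with a reason, never fatal: conservation
(scanned = stored + quarantined) is a tested invariant.

De-identification removes name, birth date, address, phone and secondary
IDs, replaces `PatientID` with a salted SHA-256 pseudonym, and remaps all
UIDs into the `2.25` namespace through the same keyed hash. Remapping is
deterministic within a salt (so re-runs and annotation exports stay
joinable) and one-way. Only remapped UIDs are stored. The operation is
idempotent on already-clean records.

## Series-description semantics

Plane, contrast, low-dose and T1/T2 weighting are recovered from the Series
Description by token matching after uppercasing and delimiter
normalization; matching is whole-word, so `CELLO` does not fire the `CE`
contrast token. The default lexicon (axial: `AX`, `AXIAL`, `TRA`; coronal:
`COR`, `CORONAL`; sagittal: `SAG`, `SAGITTAL`; contrast: `+C`, `CE`,
`ENHANCE(D)`, `POST`, `GAD`; low-dose: `LD`, `LOW DOSE`, `LOWDOSE`;
weighting: `T1`, `T1W`, `T2`, `T2W`, `FLAIR`; Black-Blood: `BB`,
`BLACK BLOOD`, `BLACKBLOOD`) is a reproducible default and overridable per
site via the YAML config. When tokens for conflicting values co-occur, the
token appearing first in the text wins and the category is flagged
ambiguous — a deterministic tie-break that favours the leading protocol
descriptor.

Black-Blood status is an MR-only attribute: positive when a BB token
appears in the description or `SequenceName`, negative otherwise for MR,
absent for all other modalities. The attribute admits exactly two concept
ids, 45884084 and 45878583; *which* id denotes positive is a package
convention (positive → 45884084), exposed as arguments on
`bb_concept()` rather than hard truth, because the two ids' polarity is not
fixed by any source we regard as authoritative. Rather than storing derived
plane/contrast/dose flags as extra EAV rows, the scenarios re-run the
deterministic classifier over the stored description rows at query time:
the tables remain a faithful transcription of the headers, and
classification changes never require re-ingestion.

## Concept mapping

Mapping is total: an exact (case-folded, trimmed) hit in the curated map
wins; anything else receives a custom concept allocated monotonically from
2,000,000,000 (the OHDSI site-local convention), keyed by
(attribute, normalized value) and persisted as CSV so ids are stable across
runs. The shipped vocabulary (~30 concepts), curated map and RadLex
crosswalk are synthetic stand-ins for licensed vocabularies — their files
are suffixed `_synthetic` and are drop-in replaceable.

## The data-quality engine

Rules are data, not code: each registry row names a table, an attribute, an
archetype and parameters. Seven archetypes cover the checks:
`count_consistency` (study's series count vs. actual series rows),
`sum_consistency` (study's instance count vs. the aggregated per-series
counts), `co_presence` (antecedent attribute implies consequent),
`nonmissing_numeric`, `nonempty_text`, `value_set`, and
`outlier_percentile` (values outside the 1st–99th percentile band).

Numerical choices:

* **Thresholds are "at least" bounds**: a result exactly at the threshold
  (e.g. 95.0% at a 95% threshold) is a PASS.
* **Percentiles are nearest-rank** (the ⌈p/100·n⌉-th order statistic):
  exactly reproducible on integers, no interpolation ambiguity.
* **Empty evaluated sets pass vacuously** with `evaluated_count = 0` and a
  warning, so a registry can be broader than any one archive without
  spurious failures.

The default registry holds 44 rules: the consistency/co-presence trio at a
95% threshold, non-missing checks at 99% (study counts, slice thickness,
rows, columns, window center/width, per-series instance counts) or 100%
(annotation measures), value-set checks (BB ids, laterality, patient
position, body part, file format), outlier checks (1st/99th percentile,
max 5%), and non-empty-text checks. The composition beyond the canonical
consistency/completeness/outlier checks is a documented reconstruction —
the registry is a CSV the user can edit rule by rule.

## The four scenarios

1. **CT frequency by hypertension** in the lung-cancer + osimertinib
   cohort: per-patient CT study counts (zero-count patients included),
   averaged per group.
2. **Nodule volumes by lesion type** (`GGN`, `SOLID_IN_GGN`, `SOLID`):
   per-label lesion-volume means; each lesion counts once.
3. **Low-dose CT**: CT studies with a low-dose series; low-dose series with
   *strictly more than* 150 instances (the cutoff is exclusive); min/max
   series sizes.
4. **MR funnel**: MR series → T1 → contrast-enhanced → slice thickness
   ≤ 1 mm → age at first lung-cancer diagnosis ≤ 60 years. Each filter
   applies to the previous survivors, so counts are weakly decreasing. The
   slice comparison defaults to ≤ (inclusive) with a `slice_strict` switch,
   because the two phrasings of the cutoff ("<1 mm" vs "≤1 mm") coexist in
   practice; series lacking a slice-thickness row are excluded at that
   stage and logged. Age is computed in whole years at the first
   lung-cancer condition start date.

Concept sets (lung cancer, hypertension, osimertinib) are plain id lists in
the scenario config — no vocabulary-descendant logic.

## The synthetic generator and what it does (not) show

The generator emulates a lung-cancer cohort archive: chest X-ray (CR/DX),
chest CT and brain MR studies; per-patient study counts Poisson with CT
means 1.8 (hypertensive) vs 2.2 (non-hypertensive) — a deliberately
desk-scale version of a small between-group difference; 40% hypertension,
50% osimertinib; CT series are mostly thin stacks (3 + Poisson(4)
instances) with a 6% admixture of volume series (120–220 instances) so the
150-instance cutoff has mass on both sides; MR weighting T1/T2/other at
0.5/0.4/0.1 with 20% Black-Blood; slice thickness drawn from typical
protocol values (0.5–5 mm) on both sides of the 1 mm cutoff; lesion volumes
lognormal with per-label means at the landmark values 8135.616 (GGN),
2578.006 (solid-in-GGN) and 34712.58 mm³ (solid), shape σ = 0.5; age at
diagnosis normal (62 ± 9 years) around the 60-year filter. Descriptions are
composed from the classifier's own token grammar, PHI is planted on
purpose, and every truth is recorded in a manifest.

Default problem sizes — 50 patients, ≈165 studies, ≈550 series, ≈6,500
instances — are the package's chosen validation scale: large enough that
every scenario filter and DQ archetype is exercised with non-trivial
counts, small enough to regenerate from scratch on a laptop. Tests at this
scale demonstrate *mechanical correctness* (the ETL, rules and queries
compute what they claim, verified against the manifest and brute-force
oracles) — they do not demonstrate robustness to real-archive messiness:
vendor-private tags, implicit-VR or compressed transfer syntaxes,
inconsistent description vocabularies, or multi-patient UID collisions.
The quarantine path and the overridable lexicon are the extension points
for exactly those.

## Known limitations

* The DICOM reader handles explicit VR little endian only; other transfer
  syntaxes are quarantined, not converted.
* Annotations are ingested from tabular exports; DICOM-SR parsing is out of
  scope, as is any pixel-based analysis.
* Procedure linkage requires exact date equality; imaging orders recorded
  on a different date than the study are reported as unlinked (with a
  warning) rather than fuzzily matched.
* The shipped vocabulary is a synthetic mini fixture; production use
  requires substituting licensed OMOP (and optionally RadLex) content.
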