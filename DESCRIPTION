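Package: imagingcdm
Title: An OMOP Common Data Model Extension for Medical Imaging Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extends the OMOP Common Data Model with four imaging tables
    (IMAGING_STUDY, IMAGING_SERIES, IMAGING_ANNOTATION, FILEPATH) populated
    from DICOM headers through an entity-attribute-value model. Provides a
    DICOM Part 10 header reader and de-identifier, rule-based classification
    of series descriptions (plane, contrast, low-dose, T1/T2 weighting,
    Black-Blood), concept mapping with deterministic custom-concept
    allocation, a declarative 44-rule data-quality engine, four lung-cancer
    cohort query scenarios, and a seeded synthetic fixture generator that
    emits DICOM files, OMOP clinical stubs and annotation exports together
    with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
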