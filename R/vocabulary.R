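# Concept mapping: extracted source values are mapped to standard concepts
# from a mini vocabulary where a curated mapping exists, and to
# deterministically allocated custom concepts otherwise. Mapping is total:
# it never fails on an unmapped value, and the raw source string always
# survives in the source-value column.
#
# The shipped vocabulary, curated concept map and RadLex crosswalk are
# synthetic stand-ins (ids in a 91xxxxxx range) for licensed OMOP/RadLex
# content, user-replaceable via the same CSV layout. The two Black-Blood
# status concepts (45884084 positive / 45878583 negative) are real.

#' Floor of the custom concept id range (OHDSI site-local convention)
#' @export
CUSTOM_CONCEPT_FLOOR <- 2000000000L

.pkg_extdata <- function(name) {
  system.file("extdata", name, package = "imagingcdm", mustWork = TRUE)
}

#' Load a vocabulary table
#' @param path CSV with columns concept_id, concept_name, domain,
#'   vocabulary, standard_flag. Default: the synthetic mini vocabulary
#'   shipped with the package.
#' @return A data.frame of concepts.
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) path <- .pkg_extdata("vocabulary_synthetic.csv")
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(v$concept_id))
  v$standard_flag <- as.logical(v$standard_flag)
  v
}

#' Load the curated attribute/source-value -> concept map
#' @param path CSV with columns attribute, source_value, concept_id.
#' @return A data.frame.
#' @export
load_concept_map <- function(path = NULL) {
  if (is.null(path)) path <- .pkg_extdata("concept_map_synthetic.csv")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$source_norm <- .norm_source(m$source_value)
  m
}

#' Load the RadLex crosswalk
#' @param path CSV with columns attribute, source_value, radlex_id.
#' @return A data.frame.
#' @export
load_radlex_crosswalk <- function(path = NULL) {
  if (is.null(path)) path <- .pkg_extdata("radlex_crosswalk_synthetic.csv")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$source_norm <- .norm_source(x$source_value)
  x
}

.norm_source <- function(x) toupper(trimws(x))

# attributes for which mapping requests are legal
.mappable_attributes <- function() {
  c(names(series_attribute_registry()), names(annotation_attribute_registry()),
    "modality", "manufacturer")
}

#' Create a custom-concept registry
#'
#' Allocates custom concept ids from 2,000,000,000 upward, keyed by
#' (attribute, normalized source value). Allocation order — and therefore
#' every id — is reproducible from the registry file.
#'
#' @param path Optional CSV to preload previously allocated concepts from.
#' @return An allocator object (environment) for [allocate_custom_concept()].
#' @export
concept_registry <- function(path = NULL) {
  reg <- new.env(parent = emptyenv())
  reg$entries <- data.frame(attribute = character(0), source_norm = character(0),
                            concept_id = integer(0), stringsAsFactors = FALSE)
  if (!is.null(path) && file.exists(path)) {
    got <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("attribute", "source_norm", "concept_id") %in% names(got)))
    reg$entries <- got[c("attribute", "source_norm", "concept_id")]
  }
  class(reg) <- "icdm_concept_registry"
  reg
}

#' Persist a custom-concept registry as CSV
#' @param registry A registry from [concept_registry()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_concept_registry <- function(registry, path) {
  ok <- tryCatch({
    utils::write.csv(registry$entries, path, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("failed to write concept registry to ", path, ": ",
         conditionMessage(ok))
  }
  invisible(path)
}

#' Allocate (or look up) a custom concept id
#' @param attribute Attribute name the value belongs to.
#' @param source_value Raw source string.
#' @param registry A registry from [concept_registry()].
#' @return The integer concept id (>= 2,000,000,000).
#' @export
allocate_custom_concept <- function(attribute, source_value, registry) {
  key_norm <- .norm_source(source_value)
  hit <- which(registry$entries$attribute == attribute &
                 registry$entries$source_norm == key_norm)
  if (length(hit)) return(registry$entries$concept_id[hit[1]])
  cid <- CUSTOM_CONCEPT_FLOOR + nrow(registry$entries)
  registry$entries <- rbind(registry$entries, data.frame(
    attribute = attribute, source_norm = key_norm, concept_id = cid,
    stringsAsFactors = FALSE))
  cid
}

#' Map a source value to a concept
#'
#' Exact (case-folded, trimmed) match against the curated map wins; any
#' other value receives a deterministic custom concept. A RadLex id is
#' attached when the crosswalk has an entry. Mapping is total.
#'
#' @param attribute Registered attribute name.
#' @param source_value Raw extracted string.
#' @param concept_map Curated map from [load_concept_map()].
#' @param registry Custom-concept registry.
#' @param crosswalk Optional RadLex crosswalk from [load_radlex_crosswalk()].
#' @return A one-row data.frame: attribute, source_value, concept_id,
#'   is_custom, radlex_id.
#' @export
map_value <- function(attribute, source_value, concept_map, registry,
                      crosswalk = NULL) {
  if (!attribute %in% .mappable_attributes()) {
    stop("unknown attribute '", attribute, "'")
  }
  key_norm <- .norm_source(source_value)
  hit <- which(concept_map$attribute == attribute &
                 concept_map$source_norm == key_norm)
  if (length(hit)) {
    cid <- concept_map$concept_id[hit[1]]
    custom <- FALSE
  } else {
    cid <- allocate_custom_concept(attribute, source_value, registry)
    custom <- TRUE
  }
  radlex <- NA_character_
  if (!is.null(crosswalk)) {
    xh <- which(crosswalk$attribute == attribute &
                  crosswalk$source_norm == key_norm)
    if (length(xh)) radlex <- crosswalk$radlex_id[xh[1]]
  }
  data.frame(attribute = attribute, source_value = source_value,
             concept_id = cid, is_custom = custom, radlex_id = radlex,
             stringsAsFactors = FALSE)
}

#' Map a DICOM modality code to a procedure-class concept
#'
#' CT/MR/CR/DX resolve to the vocabulary's imaging procedure concepts;
#' unknown codes fall through to custom allocation.
#'
#' @inheritParams map_value
#' @param modality_code DICOM Modality value (e.g. `"CT"`).
#' @return Integer concept id.
#' @export
modality_to_procedure_concept <- function(modality_code, concept_map, registry) {
  map_value("modality", modality_code, concept_map, registry)$concept_id
}
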