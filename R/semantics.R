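# Rule-based parsing of DICOM Series Description text into imaging
# semantics: plane, contrast enhancement, low-dose, T1/T2 weighting, and
# (for MR) Black-Blood status. Matching is token-based after uppercasing
# and delimiter normalization; the lexicon is data, not code, so sites can
# override it.

BB_POSITIVE_CONCEPT <- 45884084L
BB_NEGATIVE_CONCEPT <- 45878583L

#' Default token lexicon for series-description classification
#'
#' @return A list with a `version` string and one data.frame per category
#'   (`plane`, `contrast`, `low_dose`, `weighting`, `bb`), each mapping a
#'   token to the category value it implies.
#' @export
default_lexicon <- function() {
  tok <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(token = m[, 1], value = m[, 2], stringsAsFactors = FALSE)
  }
  list(
    version = "1",
    plane = tok("AX", "axial", "AXIAL", "axial", "TRA", "axial",
                "COR", "coronal", "CORONAL", "coronal",
                "SAG", "sagittal", "SAGITTAL", "sagittal"),
    contrast = tok("+C", "true", "CE", "true", "ENHANCE", "true",
                   "ENHANCED", "true", "POST", "true", "GAD", "true"),
    low_dose = tok("LD", "true", "LOW DOSE", "true", "LOWDOSE", "true"),
    weighting = tok("T1", "T1", "T1W", "T1", "T2", "T2", "T2W", "T2",
                    "FLAIR", "T2"),
    bb = tok("BB", "positive", "BLACK BLOOD", "positive",
             "BLACKBLOOD", "positive")
  )
}

# uppercase, map delimiters to single spaces, pad so tokens match on
# whole-word boundaries ("+" kept: it is part of the +C contrast token)
.norm_text <- function(text) {
  s <- toupper(text)
  s <- gsub("[^A-Z0-9+]+", " ", s)
  s <- gsub(" +", " ", s)
  paste0(" ", trimws(s), " ")
}

# position of the first occurrence of any category token; NA if none.
# Returns list(value, pos, n_distinct) for precedence and ambiguity logging.
.match_category <- function(norm, table) {
  pats <- paste0(" ", .norm_text(table$token), " ")
  pats <- substr(pats, 2, nchar(pats) - 1)  # .norm_text already pads
  pos <- vapply(pats, function(p) regexpr(p, norm, fixed = TRUE)[1], 0L,
                USE.NAMES = FALSE)
  hit <- which(pos > 0)
  if (!length(hit)) return(NULL)
  best <- hit[which.min(pos[hit])]
  list(value = table$value[best], token = trimws(pats[best]),
       n_values = length(unique(table$value[hit])))
}

#' Classify a series description
#'
#' Deterministic token matching against the lexicon. Unmatched categories
#' default to `unknown` / `FALSE` / `other`. When tokens for conflicting
#' values of one category are present (e.g. both T1 and T2), the token
#' occurring first in the text wins and the category is flagged ambiguous.
#'
#' @param text Series Description string (may be empty).
#' @param lexicon A lexicon, by default [default_lexicon()].
#' @return A list: `plane`, `contrast_enhanced`, `low_dose`, `weighting`,
#'   `matched_tokens`, `ambiguous` (character vector of category names).
#' @export
classify_description <- function(text, lexicon = default_lexicon()) {
  if (is.null(text) || is.na(text)) text <- ""
  norm <- .norm_text(text)
  out <- list(plane = "unknown", contrast_enhanced = FALSE, low_dose = FALSE,
              weighting = "other", matched_tokens = character(0),
              ambiguous = character(0))
  for (cat in c("plane", "contrast", "low_dose", "weighting")) {
    m <- .match_category(norm, lexicon[[cat]])
    if (is.null(m)) next
    out$matched_tokens <- c(out$matched_tokens, m$token)
    if (m$n_values > 1) out$ambiguous <- c(out$ambiguous, cat)
    if (cat == "plane") out$plane <- m$value
    if (cat == "contrast") out$contrast_enhanced <- TRUE
    if (cat == "low_dose") out$low_dose <- TRUE
    if (cat == "weighting") out$weighting <- m$value
  }
  out
}

#' Detect Black-Blood status of a series
#'
#' Emitted only for MR series: `"positive"` when a Black-Blood token
#' appears in the Series Description or SequenceName header, `"negative"`
#' otherwise. For any other modality the attribute is not applicable and
#' `NA` is returned.
#'
#' @param modality DICOM Modality code of the series.
#' @param description Series Description (may be `NA`).
#' @param sequence_name SequenceName header (may be `NA`).
#' @param lexicon Token lexicon.
#' @return `"positive"`, `"negative"`, or `NA_character_` for non-MR.
#' @export
detect_bb <- function(modality, description = NA, sequence_name = NA,
                      lexicon = default_lexicon()) {
  if (is.na(modality) || modality != "MR") return(NA_character_)
  hay <- .norm_text(paste(ifelse(is.na(description), "", description),
                          ifelse(is.na(sequence_name), "", sequence_name)))
  m <- .match_category(hay, lexicon$bb)
  if (is.null(m)) "negative" else "positive"
}

#' Concept id for a Black-Blood status
#'
#' The BB/non-BB attribute admits exactly two concept ids, 45884084 and
#' 45878583. Which id denotes "positive" is a package-level convention
#' (positive -> 45884084 by default) and can be swapped by callers.
#'
#' @param status `"positive"` or `"negative"`.
#' @param positive_id,negative_id The two valid concept ids.
#' @return Integer concept id.
#' @export
bb_concept <- function(status, positive_id = BB_POSITIVE_CONCEPT,
                       negative_id = BB_NEGATIVE_CONCEPT) {
  if (length(status) != 1 || !status %in% c("positive", "negative")) {
    stop("status must be \"positive\" or \"negative\"")
  }
  if (status == "positive") positive_id else negative_id
}

#' Inverse of [bb_concept()]
#' @param concept_id One of the two valid BB concept ids.
#' @inheritParams bb_concept
#' @return `"positive"` or `"negative"`.
#' @export
bb_status_from_concept <- function(concept_id,
                                   positive_id = BB_POSITIVE_CONCEPT,
                                   negative_id = BB_NEGATIVE_CONCEPT) {
  if (concept_id == positive_id) return("positive")
  if (concept_id == negative_id) return("negative")
  stop("not a valid BB/non-BB concept id: ", concept_id)
}
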