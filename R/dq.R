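# Declarative data-quality engine. Each rule is an archetype plus
# parameters and a threshold; evaluation yields PASS/FAIL with a
# percentage and an error count, rendered like a quality-assurance table
# (Threshold / Result (%) / Error (n)).
#
# The default registry holds 44 rules: the printed consistency,
# completeness, value-set and outlier checks, completed by instantiating
# the same archetypes across the remaining registered attributes. It is a
# documented reconstruction and fully user-editable (it is just a CSV).

DQ_ARCHETYPES <- c("count_consistency", "sum_consistency", "co_presence",
                   "nonmissing_numeric", "value_set", "outlier_percentile",
                   "nonempty_text")

#' Load a data-quality rule registry
#' @param path Registry CSV; default: the 44-rule registry shipped with
#'   the package.
#' @return A data.frame of rule specifications.
#' @export
load_dq_registry <- function(path = NULL) {
  if (is.null(path)) path <- .pkg_extdata("dq_rules_default.csv")
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dq_registry(reg)
  reg
}

#' Validate a rule registry
#'
#' Checks archetypes, referenced tables/attributes, and parameter
#' completeness per archetype (thresholds in (0, 100]).
#'
#' @param registry Registry data.frame.
#' @return `registry`, invisibly; errors on any violation.
#' @export
validate_dq_registry <- function(registry) {
  attrs <- c(names(series_attribute_registry()),
             names(annotation_attribute_registry()))
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    ctxt <- paste0("rule ", r$rule_id, ": ")
    if (!r$archetype %in% DQ_ARCHETYPES) {
      stop(ctxt, "unknown archetype ", r$archetype)
    }
    if (!r$table %in% ICDM_TABLES) stop(ctxt, "unknown table ", r$table)
    if (r$table %in% c("imaging_series", "imaging_annotation") &&
        !is.na(r$attribute) && nzchar(r$attribute) && !r$attribute %in% attrs) {
      stop(ctxt, "attribute not in registry: ", r$attribute)
    }
    if (r$table %in% c("imaging_study", "filepath") &&
        !is.na(r$attribute) && nzchar(r$attribute) &&
        !r$attribute %in% icdm_schema(r$table)$name) {
      stop(ctxt, "not a column of ", r$table, ": ", r$attribute)
    }
    if (r$archetype == "outlier_percentile") {
      if (is.na(r$lo_pct) || is.na(r$hi_pct) || is.na(r$max_outlier_pct)) {
        stop(ctxt, "outlier_percentile needs lo_pct, hi_pct, max_outlier_pct")
      }
      if (r$max_outlier_pct <= 0 || r$max_outlier_pct > 100) {
        stop(ctxt, "max_outlier_pct must be in (0, 100]")
      }
    } else {
      if (is.na(r$threshold_pct) || r$threshold_pct <= 0 || r$threshold_pct > 100) {
        stop(ctxt, "threshold_pct must be in (0, 100]")
      }
    }
    if (r$archetype == "value_set" &&
        (is.na(r$valid_values) || !nzchar(r$valid_values))) {
      stop(ctxt, "value_set needs valid_values")
    }
    if (r$archetype == "co_presence" &&
        (is.na(r$antecedent) || is.na(r$consequent))) {
      stop(ctxt, "co_presence needs antecedent and consequent")
    }
  }
  invisible(registry)
}

#' Nearest-rank percentile
#'
#' The p-th percentile as the ceiling(p/100 * n)-th order statistic
#' (1-indexed), clamped to the first for p = 0. Exactly reproducible on
#' integers, unlike interpolating definitions.
#'
#' @param values Nonempty numeric vector.
#' @param p Percentile in \[0, 100\].
#' @return The percentile value.
#' @export
percentile <- function(values, p) {
  if (!length(values)) stop("percentile of an empty value set")
  stopifnot(p >= 0, p <= 100)
  s <- sort(values)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

# rows of an EAV table for a named attribute
.attr_rows <- function(db, table, attribute) {
  reg <- if (table == "imaging_series") series_attribute_registry()
         else annotation_attribute_registry()
  tab <- db[[table]]
  concept_col <- if (table == "imaging_series") "series_concept_id"
                 else "annotation_concept_id"
  tab[tab[[concept_col]] == reg[[attribute]], , drop = FALSE]
}

# (values-as-number, values-as-concept, source-text) for a rule target
.rule_values <- function(db, rule) {
  if (rule$table %in% c("imaging_series", "imaging_annotation")) {
    rows <- .attr_rows(db, rule$table, rule$attribute)
    list(num = rows$value_as_number, concept = rows$value_as_concept_id,
         text = rows$value_source_value)
  } else {
    col <- db[[rule$table]][[rule$attribute]]
    list(num = suppressWarnings(as.numeric(col)),
         concept = col, text = as.character(col))
  }
}

.result <- function(rule, status, pass_pct, error_count, evaluated_count,
                    warning = NA_character_) {
  data.frame(rule_id = rule$rule_id, table = rule$table,
             attribute = ifelse(is.na(rule$attribute), "", rule$attribute),
             archetype = rule$archetype, status = status,
             pass_pct = round(pass_pct, 1), error_count = error_count,
             evaluated_count = evaluated_count, warning = warning,
             stringsAsFactors = FALSE)
}

.vacuous <- function(rule) {
  .result(rule, "PASS", 100, 0L, 0L,
          warning = "no rows to evaluate; vacuous pass")
}

#' Evaluate a single data-quality rule
#'
#' @param rule One registry row (data.frame row or named list).
#' @param db An `icdm_db`.
#' @return One-row data.frame: rule_id, status, pass_pct, error_count,
#'   evaluated_count, warning. For `outlier_percentile` rules `pass_pct`
#'   carries the outlier percentage (the quantity the threshold bounds);
#'   for all other archetypes it is the passing percentage. Boundary
#'   semantics: a result exactly at the threshold is a PASS.
#' @export
evaluate_rule <- function(rule, db) {
  a <- rule$archetype
  if (a == "count_consistency") {
    st <- db$imaging_study
    if (!nrow(st)) return(.vacuous(rule))
    se <- db$imaging_series
    per_study <- vapply(st$imaging_study_id, function(id) {
      length(unique(se$series_uid[se$imaging_study_id == id]))
    }, 0L)
    ok <- !is.na(st$number_of_series) & st$number_of_series == per_study
    return(.result(rule, ifelse(100 * mean(ok) >= rule$threshold_pct, "PASS", "FAIL"),
                   100 * mean(ok), sum(!ok), length(ok)))
  }
  if (a == "sum_consistency") {
    st <- db$imaging_study
    inst <- .attr_rows(db, "imaging_series", "number_of_instances")
    if (!nrow(st) || !nrow(inst)) return(.vacuous(rule))
    sums <- tapply(inst$value_as_number, inst$imaging_study_id, sum,
                   na.rm = TRUE)
    mapped <- st$imaging_study_id %in% as.integer(names(sums))
    st <- st[mapped, , drop = FALSE]  # only studies mapped between the tables
    if (!nrow(st)) return(.vacuous(rule))
    ok <- !is.na(st$number_of_instances) &
      st$number_of_instances == sums[as.character(st$imaging_study_id)]
    return(.result(rule, ifelse(100 * mean(ok) >= rule$threshold_pct, "PASS", "FAIL"),
                   100 * mean(ok), sum(!ok), length(ok)))
  }
  if (a == "co_presence") {
    if (rule$table == "imaging_study") {
      st <- db$imaging_study
      has_ante <- !is.na(st[[rule$antecedent]])
      has_cons <- !is.na(st[[rule$consequent]])
      ante_keys <- which(has_ante)
      ok <- has_cons[ante_keys]
    } else {
      key_col <- if (rule$table == "imaging_series") "series_uid" else "lesion_id"
      ante <- .attr_rows(db, rule$table, rule$antecedent)
      cons <- .attr_rows(db, rule$table, rule$consequent)
      ante_keys <- unique(paste(ante$imaging_study_id, ante[[key_col]]))
      cons_keys <- unique(paste(cons$imaging_study_id, cons[[key_col]]))
      ok <- ante_keys %in% cons_keys
    }
    if (!length(ante_keys)) return(.vacuous(rule))
    return(.result(rule, ifelse(100 * mean(ok) >= rule$threshold_pct, "PASS", "FAIL"),
                   100 * mean(ok), sum(!ok), length(ok)))
  }
  v <- .rule_values(db, rule)
  if (a == "nonmissing_numeric") {
    n <- length(v$num)
    if (!n) return(.vacuous(rule))
    ok <- !is.na(v$num) & is.finite(v$num)
    return(.result(rule, ifelse(100 * mean(ok) >= rule$threshold_pct, "PASS", "FAIL"),
                   100 * mean(ok), sum(!ok), n))
  }
  if (a == "nonempty_text") {
    n <- length(v$text)
    if (!n) return(.vacuous(rule))
    ok <- !is.na(v$text) & nzchar(trimws(v$text))
    return(.result(rule, ifelse(100 * mean(ok) >= rule$threshold_pct, "PASS", "FAIL"),
                   100 * mean(ok), sum(!ok), n))
  }
  if (a == "value_set") {
    valid <- trimws(strsplit(rule$valid_values, ";")[[1]])
    n <- length(v$concept)
    if (!n) return(.vacuous(rule))
    ok <- as.character(v$concept) %in% valid
    return(.result(rule, ifelse(100 * mean(ok) >= rule$threshold_pct, "PASS", "FAIL"),
                   100 * mean(ok), sum(!ok), n))
  }
  if (a == "outlier_percentile") {
    vals <- v$num[!is.na(v$num) & is.finite(v$num)]
    if (!length(vals)) return(.vacuous(rule))
    lo <- percentile(vals, rule$lo_pct)
    hi <- percentile(vals, rule$hi_pct)
    out <- vals < lo | vals > hi
    pct <- 100 * mean(out)
    return(.result(rule, ifelse(pct <= rule$max_outlier_pct, "PASS", "FAIL"),
                   pct, sum(out), length(vals)))
  }
  stop("unknown archetype ", a)
}

#' Run a rule registry against a database
#'
#' @param db An `icdm_db`.
#' @param registry Registry data.frame, default [load_dq_registry()].
#' @return An object of class `icdm_dq_report`: list with `results` (one
#'   row per rule, registry order) and `overall` (`"PASS"` iff every rule
#'   passed).
#' @export
run_dq <- function(db, registry = load_dq_registry()) {
  validate_dq_registry(registry)
  results <- do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
    evaluate_rule(registry[i, ], db)
  }))
  structure(list(results = results,
                 overall = if (all(results$status == "PASS")) "PASS" else "FAIL"),
            class = "icdm_dq_report")
}

#' @export
print.icdm_dq_report <- function(x, ...) {
  cat(format_dq_report(x), sep = "\n")
  invisible(x)
}

#' Render a DQ report as a text table
#' @param report An `icdm_dq_report`.
#' @return Character vector of lines (rule, threshold column mirror,
#'   Result (%), Error (n)).
#' @export
format_dq_report <- function(report) {
  r <- report$results
  c(sprintf("%-6s %-19s %-22s %-19s %-10s %8s", "Rule", "Table", "Attribute",
            "Archetype", "Result(%)", "Error(n)"),
    sprintf("%-6s %-19s %-22s %-19s %-10s %8d", r$rule_id, r$table,
            r$attribute, r$archetype,
            sprintf("%s (%.1f)", r$status, r$pass_pct), r$error_count),
    sprintf("Overall: %s (%d/%d rules passing)", report$overall,
            sum(r$status == "PASS"), nrow(r)))
}

#' Serialize a DQ report to JSON
#' @param report An `icdm_dq_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dq_report <- function(report, path) {
  jsonlite::write_json(list(overall = report$overall, results = report$results),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
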