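# Scoring engine. Each criterion's evidence is binary — 0 when the evidence
# does not apply or is unknown, 1 when it applies — and is multiplied by the
# criterion weight. The C-score sums the clinical contributions, the F-score
# the functional ones, and the RVE-score is their total, the accumulated
# evidence for a causative regulatory role. The RVE-score is then ranked
# against a reference distribution of curated regulatory variants by the
# <=-count ECDF, with a low/intermediate/high label at the reference
# tertiles.

#' Binarize a measurement under a threshold rule
#'
#' Comparative operators (`ge`/`gt`/`le`/`lt`, boundary-inclusive for
#' `ge`/`le`) compare a found measurement's value to the cutoff; `present`
#' scores 1 when the measurement was found (for interval sources, at least
#' one overlap); `absent` scores 1 when it was missing. Anything that cannot
#' be evaluated — in particular a missing measurement under a comparative
#' operator — scores 0: unknown evidence never counts.
#'
#' @param m An `rve_measurement`.
#' @param rule An `rve_rule` reading the same source.
#' @return `0L` or `1L`.
#' @export
binarize <- function(m, rule) {
  stopifnot(inherits(m, "rve_measurement"), inherits(rule, "rve_rule"))
  if (!identical(rule$source_key, m$source_key))
    stop_internal("rule reads source '%s' but measurement is from '%s'",
                  rule$source_key, m$source_key)
  if (rule$operator == "absent")  return(if (m$status == "missing") 1L else 0L)
  if (rule$operator == "present") return(if (m$status == "found") 1L else 0L)
  if (m$status == "missing") return(0L)
  val <- m$value
  if (!is_scalar_num(val) || !is.finite(val)) return(0L)
  ok <- switch(rule$operator,
               ge = val >= rule$cutoff,
               gt = val >  rule$cutoff,
               le = val <= rule$cutoff,
               lt = val <  rule$cutoff)
  if (isTRUE(ok)) 1L else 0L
}

#' Construct a per-criterion evidence value
#'
#' @param criterion_id Rubric criterion id.
#' @param value 0 or 1.
#' @param provenance How the value was set: `"auto"` (annotation source),
#'   `"user_answer"` (yes/no answer), `"user_override"` (forced in step 3),
#'   or `"default_unknown"` (never assessed, defaults to 0).
#' @param raw Optional `rve_measurement` backing an auto value.
#' @param comment Optional free-text comment (citations, justification).
#' @param previous For overrides, the value that was replaced.
#' @return An object of class `rve_evidence`.
#' @export
evidence_value <- function(criterion_id, value,
                           provenance = c("auto", "user_answer",
                                          "user_override", "default_unknown"),
                           raw = NULL, comment = "", previous = NULL) {
  provenance <- match.arg(provenance)
  if (!is_scalar_num(value) || !value %in% c(0, 1))
    stop_validation("evidence for '%s' must be 0 or 1, got %s",
                    criterion_id, paste(value, collapse = ","))
  if (provenance == "user_override" && is.null(previous))
    stop_validation("override of '%s' must retain the pre-override value",
                    criterion_id)
  structure(list(criterion_id = criterion_id, value = as.integer(value),
                 provenance = provenance, raw = raw,
                 comment = as.character(comment)[1L],
                 previous = if (is.null(previous)) NULL else as.integer(previous)),
            class = "rve_evidence")
}

validate_evidence_set <- function(evidence, rub) {
  ids <- criterion_ids(rub)
  extra <- setdiff(names(evidence), ids)
  if (length(extra))
    stop_validation("evidence key(s) not in rubric: %s",
                    paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Compute the C-score, F-score and RVE-score from an evidence set
#'
#' Criteria without an evidence value are treated as 0 (unknown). The
#' C-score sums value x weight over clinical criteria, the F-score over
#' functional criteria, and the RVE-score is C + F.
#'
#' @param evidence Named list of `rve_evidence`, keyed by criterion id
#'   (a subset of the rubric's ids).
#' @param rub An `rve_rubric`.
#' @return An object of class `rve_result` with fields `c_score`, `f_score`,
#'   `rve_score`, a per-criterion `contributions` data frame, and (after
#'   [rank_against_reference()]) `percentile` and `strength_label`.
#' @export
compute_scores <- function(evidence, rub) {
  stopifnot(inherits(rub, "rve_rubric"))
  if (is.null(evidence)) evidence <- list()
  validate_evidence_set(evidence, rub)
  rows <- lapply(rub$criteria, function(cr) {
    ev <- evidence[[cr$id]]
    val <- if (is.null(ev)) 0L else ev$value
    prov <- if (is.null(ev)) "default_unknown" else ev$provenance
    data.frame(id = cr$id, component = cr$component,
               value = as.numeric(val), weight = cr$weight,
               contribution = as.numeric(val) * cr$weight,
               provenance = prov, stringsAsFactors = FALSE)
  })
  contrib <- do.call(rbind, rows)
  c_score <- sum(contrib$contribution[contrib$component == "clinical"])
  f_score <- sum(contrib$contribution[contrib$component == "functional"])
  structure(list(c_score = c_score, f_score = f_score,
                 rve_score = c_score + f_score,
                 contributions = contrib,
                 max_scores = max_scores(rub),
                 percentile = NA_real_, strength_label = NA_character_),
            class = "rve_result")
}

#' Load a reference distribution of curated variant scores
#'
#' TSV with header columns `label` and `rve_score`. The bundled synthetic
#' stand-in (46 entries, see the package vignette) lives at
#' `system.file("extdata", "reference_scores_synthetic.tsv",
#' package = "rvescore")`.
#'
#' @param path TSV file path.
#' @param expected_size Declared size to validate against (`NULL` skips the
#'   check). The curated collection this distribution emulates holds 46
#'   variants.
#' @return An object of class `rve_reference` (data frame: label, rve_score).
#' @export
load_reference <- function(path, expected_size = 46L) {
  if (!is_scalar_chr(path) || !file.exists(path))
    stop_config("reference distribution file not found: '%s'", path)
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_io("cannot read reference file '%s': %s",
                           path, conditionMessage(e)))
  if (!all(c("label", "rve_score") %in% names(df)))
    stop_io("reference file '%s' must have columns label, rve_score", path)
  df$rve_score <- as.numeric(df$rve_score)
  if (anyNA(df$rve_score) || any(df$rve_score < 0))
    stop_validation("reference scores must be non-negative numbers")
  if (!is.null(expected_size) && nrow(df) != expected_size)
    stop_validation("reference distribution has %d entries, expected %d",
                    nrow(df), expected_size)
  structure(df[, c("label", "rve_score")], class = c("rve_reference", "data.frame"))
}

#' Path to the bundled synthetic reference distribution
#' @return File path of the installed reference TSV (a synthetic stand-in
#'   for the curated 46-variant collection; see the vignette).
#' @export
default_reference_path <- function() {
  system.file("extdata", "reference_scores_synthetic.tsv",
              package = "rvescore", mustWork = TRUE)
}

#' Rank a score against the reference distribution
#'
#' Percentile is the <=-count ECDF: `100 * #(reference <= rve_score) / n`.
#' The strength label compares the RVE-score to the reference tertiles:
#' below the first tertile is `low`, below the second `intermediate`,
#' otherwise `high`.
#'
#' @param result An `rve_result`.
#' @param reference An `rve_reference`.
#' @param probs Tertile cut probabilities (replaceable convention).
#' @return The result with `percentile` and `strength_label` set. An empty
#'   reference leaves both unset with a warning.
#' @export
rank_against_reference <- function(result, reference, probs = c(1, 2) / 3) {
  stopifnot(inherits(result, "rve_result"))
  scores <- if (is.null(reference)) numeric(0) else reference$rve_score
  if (!length(scores)) {
    warning("empty reference distribution: percentile and strength left unset")
    return(result)
  }
  result$percentile <- 100 * sum(scores <= result$rve_score) / length(scores)
  cuts <- stats::quantile(scores, probs = probs, names = FALSE)
  result$strength_label <-
    if (result$rve_score < cuts[1L]) "low"
    else if (result$rve_score < cuts[2L]) "intermediate"
    else "high"
  result
}

#' @export
print.rve_result <- function(x, ...) {
  ms <- x$max_scores
  cat(sprintf("RVE-score: %g  (C-score %g/%g, F-score %g/%g)\n",
              x$rve_score, x$c_score, ms[["max_c"]], x$f_score, ms[["max_f"]]))
  if (!is.na(x$percentile))
    cat(sprintf("Percentile vs reference: %.1f  strength: %s\n",
                x$percentile, x$strength_label))
  invisible(x)
}

#' @export
summary.rve_result <- function(object, ...) {
  print(object)
  tab <- object$contributions
  cat("\nContributing criteria:\n")
  hit <- tab[tab$value > 0, c("id", "component", "weight", "provenance")]
  if (nrow(hit)) print(hit, row.names = FALSE) else cat("  none\n")
  invisible(object)
}
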