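# The scoring rubric: 24 yes/no evidence criteria, each belonging to the
# clinical ("C") or functional ("F") component, carrying an integer weight
# and either an automatic binarization rule against an annotation source or
# a manual (user-answered) mode. The rubric is data, not code: the engine is
# rubric-agnostic and everything here is loaded from a YAML file.

RVE_OPERATORS   <- c("ge", "gt", "le", "lt", "absent", "present")
RVE_COMPONENTS  <- c("clinical", "functional")
RVE_N_CRITERIA  <- 24L

#' Threshold rule for an automatic criterion
#'
#' A rule binarizes a raw measurement from one annotation source into 0/1
#' evidence. Comparative operators (`ge`, `gt`, `le`, `lt`) compare the
#' measured value to `cutoff`; `present` scores 1 when the source yields a
#' measurement at all (for interval sources, at least one overlap) and
#' `absent` scores 1 when it does not.
#'
#' @param operator One of `"ge"`, `"gt"`, `"le"`, `"lt"`, `"absent"`,
#'   `"present"`.
#' @param source_key Identifier of the annotation source the rule reads
#'   (e.g. `"phylop"`).
#' @param cutoff Finite numeric cutoff; required for comparative operators,
#'   ignored for `absent`/`present`.
#' @return An object of class `rve_rule`.
#' @export
#' @examples
#' threshold_rule("ge", "phylop", 2)
threshold_rule <- function(operator, source_key, cutoff = NULL) {
  if (!is_scalar_chr(operator) || !operator %in% RVE_OPERATORS)
    stop_validation("threshold operator must be one of %s",
                    paste(RVE_OPERATORS, collapse = "/"))
  if (!is_scalar_chr(source_key))
    stop_validation("threshold rule needs a non-empty source_key")
  if (operator %in% c("ge", "gt", "le", "lt")) {
    if (is.null(cutoff) || !is_scalar_num(cutoff) || !is.finite(cutoff))
      stop_validation("operator '%s' requires a finite numeric cutoff", operator)
    cutoff <- as.numeric(cutoff)
  } else {
    cutoff <- NULL
  }
  structure(list(operator = operator, cutoff = cutoff,
                 source_key = source_key),
            class = "rve_rule")
}

#' Construct a single scoring criterion
#'
#' @param id Short criterion code, e.g. `"C3.1"` or `"F1.2"`. The leading
#'   letter must agree with `component`.
#' @param component `"clinical"` or `"functional"`.
#' @param description Free-text statement of the evidence.
#' @param weight Non-negative weight multiplying the 0/1 evidence value.
#' @param mode `"auto"` (scored from an annotation source) or `"manual"`
#'   (answered yes/no by the user).
#' @param rule An [threshold_rule()] — required iff `mode = "auto"`.
#' @return An object of class `rve_criterion`.
#' @export
criterion <- function(id, component, description, weight, mode,
                      rule = NULL) {
  if (!is_scalar_chr(id))
    stop_validation("criterion id must be a non-empty string")
  if (!is_scalar_chr(component) || !component %in% RVE_COMPONENTS)
    stop_validation("criterion '%s': component must be clinical or functional", id)
  expected_prefix <- if (component == "clinical") "C" else "F"
  if (substr(id, 1L, 1L) != expected_prefix)
    stop_validation("criterion '%s': id prefix does not match component '%s'",
                    id, component)
  if (!is_scalar_num(weight) || weight < 0 || !is.finite(weight))
    stop_validation("criterion '%s': weight must be a finite non-negative number", id)
  if (!is_scalar_chr(mode) || !mode %in% c("auto", "manual"))
    stop_validation("criterion '%s': mode must be auto or manual", id)
  if (mode == "auto" && is.null(rule))
    stop_validation("criterion '%s': mode=auto requires a threshold rule", id)
  if (mode == "manual" && !is.null(rule))
    stop_validation("criterion '%s': mode=manual must not carry a rule", id)
  if (!is.null(rule) && !inherits(rule, "rve_rule"))
    stop_validation("criterion '%s': rule must be an rve_rule", id)
  structure(list(id = id, component = component,
                 description = as.character(description)[1L],
                 weight = as.numeric(weight), mode = mode, rule = rule),
            class = "rve_criterion")
}

#' Assemble a rubric from criteria
#'
#' @param criteria List of [criterion()] objects, order preserved.
#' @param version Free-text rubric version label.
#' @param strict If `TRUE` (the production default), the rubric must hold
#'   exactly 24 criteria; `FALSE` admits toy rubrics for testing and
#'   exploration. Both components must be non-empty either way.
#' @return An object of class `rve_rubric`.
#' @export
rubric <- function(criteria, version = "unversioned", strict = TRUE) {
  if (!is.list(criteria) || !length(criteria) ||
      !all(vapply(criteria, inherits, logical(1), "rve_criterion")))
    stop_validation("criteria must be a non-empty list of rve_criterion objects")
  ids <- vapply(criteria, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_validation("duplicate criterion id '%s'", dup[1L])
  comps <- vapply(criteria, `[[`, character(1), "component")
  if (!all(RVE_COMPONENTS %in% comps))
    stop_validation("rubric must contain both clinical and functional criteria")
  if (strict && length(criteria) != RVE_N_CRITERIA)
    stop_validation("rubric must contain exactly %d criteria, found %d",
                    RVE_N_CRITERIA, length(criteria))
  structure(list(version = as.character(version)[1L], criteria = criteria),
            class = "rve_rubric")
}

record_to_criterion <- function(rec, where) {
  need <- c("id", "component", "description", "weight", "mode")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop_config("rubric %s: missing field(s) %s", where,
                paste(miss, collapse = ", "))
  rule <- NULL
  if (identical(rec$mode, "auto")) {
    if (is.null(rec$operator) || is.null(rec$source_key))
      stop_config("rubric %s (criterion '%s'): auto mode needs operator and source_key",
                  where, rec$id)
    rule <- threshold_rule(rec$operator, rec$source_key, rec$cutoff)
  }
  criterion(rec$id, rec$component, rec$description, rec$weight, rec$mode, rule)
}

#' Load a rubric from a YAML file
#'
#' The file holds a `version` label and a `criteria` sequence, one mapping
#' per criterion with keys `id`, `component`, `description`, `weight`,
#' `mode`, and for auto criteria `operator`, `cutoff` (comparative operators
#' only) and `source_key`. The bundled default lives at
#' `system.file("extdata", "rubric_default.yaml", package = "rvescore")`.
#'
#' @param path Path to the rubric YAML file.
#' @param strict Enforce the 24-criterion invariant (default `TRUE`).
#' @return An `rve_rubric`; criterion order follows the file.
#' @export
#' @examples
#' rub <- load_rubric(default_rubric_path())
#' max_scores(rub)
load_rubric <- function(path, strict = TRUE) {
  if (!is_scalar_chr(path) || !file.exists(path))
    stop_config("rubric file not found: '%s'", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_config("cannot parse rubric file '%s': %s", path, conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$criteria) || !is.list(doc$criteria))
    stop_config("rubric file '%s' must contain a 'criteria' sequence", path)
  crits <- lapply(seq_along(doc$criteria), function(i)
    record_to_criterion(doc$criteria[[i]], sprintf("file '%s', record %d", path, i)))
  rubric(crits, version = if (is.null(doc$version)) "unversioned" else doc$version,
         strict = strict)
}

#' Path to the bundled default rubric
#' @return File path of the installed default rubric YAML.
#' @export
default_rubric_path <- function() {
  system.file("extdata", "rubric_default.yaml", package = "rvescore",
              mustWork = TRUE)
}

#' Maximum attainable component scores
#'
#' The C-score is bounded by the sum of clinical weights and the F-score by
#' the sum of functional weights (every criterion counts toward exactly one
#' component).
#'
#' @param rub An `rve_rubric`.
#' @return Named numeric vector `c(max_c, max_f)`.
#' @export
max_scores <- function(rub) {
  stopifnot(inherits(rub, "rve_rubric"))
  w <- vapply(rub$criteria, `[[`, numeric(1), "weight")
  comp <- vapply(rub$criteria, `[[`, character(1), "component")
  c(max_c = sum(w[comp == "clinical"]), max_f = sum(w[comp == "functional"]))
}

criterion_ids <- function(rub, mode = NULL) {
  keep <- if (is.null(mode)) rep(TRUE, length(rub$criteria))
          else vapply(rub$criteria, `[[`, character(1), "mode") == mode
  vapply(rub$criteria[keep], `[[`, character(1), "id")
}

get_criterion <- function(rub, id) {
  for (cr in rub$criteria) if (cr$id == id) return(cr)
  stop_validation("unknown criterion id '%s'", id)
}

#' @export
as.data.frame.rve_rubric <- function(x, ...) {
  data.frame(
    id          = vapply(x$criteria, `[[`, character(1), "id"),
    component   = vapply(x$criteria, `[[`, character(1), "component"),
    description = vapply(x$criteria, `[[`, character(1), "description"),
    weight      = vapply(x$criteria, `[[`, numeric(1), "weight"),
    mode        = vapply(x$criteria, `[[`, character(1), "mode"),
    source_key  = vapply(x$criteria, function(cr)
      if (is.null(cr$rule)) NA_character_ else cr$rule$source_key, character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.rve_rubric <- function(x, ...) {
  df <- as.data.frame(x)
  ms <- max_scores(x)
  cat(sprintf("RVE scoring rubric (version %s): %d criteria\n", x$version, nrow(df)))
  cat(sprintf("  clinical:   %2d criteria, max C-score %g\n",
              sum(df$component == "clinical"), ms[["max_c"]]))
  cat(sprintf("  functional: %2d criteria, max F-score %g\n",
              sum(df$component == "functional"), ms[["max_f"]]))
  cat(sprintf("  auto-scored: %d, user-answered: %d\n",
              sum(df$mode == "auto"), sum(df$mode == "manual")))
  invisible(x)
}
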