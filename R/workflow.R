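# The staged scoring session. Step 1 fills every auto criterion from the
# annotation bundle; step 2 applies the user's yes/no answers for manual
# criteria; step 3 applies explicit overrides with comments. Every change
# appends to an audit log, and replaying that log from an empty evidence set
# reproduces the session's evidence exactly. finalize() is pure: it scores
# the evidence and ranks the result without touching the session.

audit_row <- function(step, criterion_id, old_value, new_value,
                      provenance, comment) {
  data.frame(step = step, criterion_id = criterion_id,
             old_value = as.numeric(old_value), new_value = as.numeric(new_value),
             provenance = provenance, comment = as.character(comment),
             stringsAsFactors = FALSE)
}

empty_audit <- function() {
  audit_row("x", "x", 0, 0, "x", "x")[0L, ]
}

#' Start a scoring session
#'
#' @param variant An `rve_variant`.
#' @param rub An `rve_rubric`.
#' @return An object of class `rve_session`.
#' @export
new_session <- function(variant, rub) {
  stopifnot(inherits(variant, "rve_variant"), inherits(rub, "rve_rubric"))
  structure(list(variant = variant, rubric = rub,
                 evidence = stats::setNames(list(), character(0)),
                 audit = empty_audit(),
                 steps_done = character(0),
                 source_versions = character(0)),
            class = "rve_session")
}

require_step <- function(session, step, before) {
  if (!step %in% session$steps_done)
    stop_validation("%s requires %s to have run first", before, step)
}

set_evidence <- function(session, ev, step) {
  old <- session$evidence[[ev$criterion_id]]
  old_value <- if (is.null(old)) NA_real_ else old$value
  session$evidence[[ev$criterion_id]] <- ev
  session$audit <- rbind(
    session$audit,
    audit_row(step, ev$criterion_id, old_value, ev$value, ev$provenance,
              ev$comment))
  session
}

#' Step 1: gather and binarize automatic evidence
#'
#' Queries each of the bundle's annotation sources that the rubric's auto
#' criteria read, binarizes the measurements under the criterion rules, and
#' stores the 0/1 values with provenance `"auto"` and the raw measurement
#' attached. Re-running step 1 is idempotent on the evidence and is recorded
#' in the audit log.
#'
#' @param session An `rve_session`.
#' @param bundle An `rve_bundle`.
#' @return The updated session.
#' @export
step1_auto <- function(session, bundle) {
  stopifnot(inherits(session, "rve_session"))
  meas <- gather_auto_evidence(bundle, session$variant, session$rubric)
  for (id in names(meas)) {
    cr <- get_criterion(session$rubric, id)
    val <- binarize(meas[[id]], cr$rule)
    session <- set_evidence(
      session,
      evidence_value(id, val, provenance = "auto", raw = meas[[id]]),
      step = "step1")
  }
  session$source_versions <- source_versions(bundle)
  session$steps_done <- union(session$steps_done, "step1")
  session
}

#' Step 2: apply the user's yes/no answers to manual criteria
#'
#' `yes` scores 1 and `no` scores 0, both with provenance `"user_answer"`;
#' a manual criterion left unanswered scores 0 with provenance
#' `"default_unknown"` (unknown evidence never counts, but the report keeps
#' it distinguishable from an assessed "no").
#'
#' @param session An `rve_session` after [step1_auto()].
#' @param answers Named character vector or list, criterion id to
#'   `"yes"`/`"no"`/`"unanswered"`. Keys must be manual-mode criteria.
#' @return The updated session.
#' @export
step2_manual <- function(session, answers = character(0)) {
  stopifnot(inherits(session, "rve_session"))
  require_step(session, "step1", "step2")
  answers <- unlist(answers)
  manual_ids <- criterion_ids(session$rubric, mode = "manual")
  bad <- setdiff(names(answers), manual_ids)
  if (length(bad))
    stop_validation("answer(s) supplied for non-manual criteria: %s",
                    paste(bad, collapse = ", "))
  bad_val <- answers[!answers %in% c("yes", "no", "unanswered")]
  if (length(bad_val))
    stop_validation("answers must be yes/no/unanswered, got '%s' for %s",
                    bad_val[1L], names(bad_val)[1L])
  for (id in manual_ids) {
    ans <- if (id %in% names(answers)) answers[[id]] else "unanswered"
    ev <- switch(ans,
      yes        = evidence_value(id, 1L, provenance = "user_answer"),
      no         = evidence_value(id, 0L, provenance = "user_answer"),
      unanswered = evidence_value(id, 0L, provenance = "default_unknown"))
    session <- set_evidence(session, ev, step = "step2")
  }
  session$steps_done <- union(session$steps_done, "step2")
  session
}

#' Step 3: force per-criterion values with justification
#'
#' Overrides replace any criterion's value with a forced 0 or 1, provenance
#' `"user_override"`; the replaced value is retained both on the evidence
#' and in the audit log. A warning is emitted per override — scores should
#' only be changed with strong supporting evidence — and an additional
#' warning flags an empty comment.
#'
#' @param session An `rve_session` after steps 1 and 2.
#' @param overrides Named list, criterion id to `list(value = 0 or 1,
#'   comment = "free text")`.
#' @return The updated session.
#' @export
step3_override <- function(session, overrides = list()) {
  stopifnot(inherits(session, "rve_session"))
  require_step(session, "step1", "step3")
  require_step(session, "step2", "step3")
  all_ids <- criterion_ids(session$rubric)
  for (id in names(overrides)) {
    if (!id %in% all_ids)
      stop_validation("override targets unknown criterion '%s'", id)
    ov <- overrides[[id]]
    val <- if (is.list(ov)) ov$value else ov
    if (!is_scalar_num(val) || !val %in% c(0, 1))
      stop_validation("override for '%s' must force 0 or 1", id)
    comment <- if (is.list(ov) && !is.null(ov$comment)) ov$comment else ""
    old <- session$evidence[[id]]
    old_value <- if (is.null(old)) 0L else old$value
    warning(sprintf(
      "overriding '%s' (%d -> %d): scores should only be changed with strong supporting evidence",
      id, old_value, as.integer(val)), call. = FALSE)
    if (!nzchar(comment))
      warning(sprintf("override of '%s' has no justifying comment", id),
              call. = FALSE)
    ev <- evidence_value(id, val, provenance = "user_override",
                         raw = if (is.null(old)) NULL else old$raw,
                         comment = comment, previous = old_value)
    session <- set_evidence(session, ev, step = "step3")
  }
  session$steps_done <- union(session$steps_done, "step3")
  session
}

#' Finalize a session into a ranked score
#'
#' Scores the current evidence ([compute_scores()]) and, when a reference
#' distribution is given, ranks it ([rank_against_reference()]). The session
#' itself is never mutated.
#'
#' @param session An `rve_session` after [step1_auto()] (steps 2-3 optional).
#' @param reference Optional `rve_reference`.
#' @return An `rve_result`.
#' @export
finalize <- function(session, reference = NULL) {
  stopifnot(inherits(session, "rve_session"))
  require_step(session, "step1", "finalize")
  result <- compute_scores(session$evidence, session$rubric)
  if (!is.null(reference)) result <- rank_against_reference(result, reference)
  result
}

#' Replay a session's audit log from an empty evidence set
#'
#' Applies the audit entries in order; the result carries the same values,
#' provenance and comments as the session's live evidence, which is the
#' audit invariant every session maintains.
#'
#' @param session An `rve_session`.
#' @return Named list of `rve_evidence` (raw measurements are not part of
#'   the audit trail and are absent here).
#' @export
replay_audit <- function(session) {
  stopifnot(inherits(session, "rve_session"))
  evidence <- stats::setNames(list(), character(0))
  au <- session$audit
  for (i in seq_len(nrow(au))) {
    prev <- evidence[[au$criterion_id[i]]]
    evidence[[au$criterion_id[i]]] <- evidence_value(
      au$criterion_id[i], au$new_value[i], provenance = au$provenance[i],
      comment = au$comment[i],
      previous = if (au$provenance[i] == "user_override")
        (if (is.null(prev)) 0L else prev$value) else NULL)
  }
  evidence
}

# --- Answers / overrides files ---------------------------------------------

#' Read a manual-answers YAML file
#'
#' A flat mapping of manual criterion id to `yes`/`no` (or `unanswered`).
#' YAML 1.1 booleans are accepted and normalized.
#'
#' @param path YAML file path.
#' @return Named character vector suitable for [step2_manual()].
#' @export
load_answers <- function(path) {
  if (!is_scalar_chr(path) || !file.exists(path))
    stop_config("answers file not found: '%s'", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_config("cannot parse answers file '%s': %s", path, conditionMessage(e)))
  if (is.null(doc)) return(character(0))
  vapply(doc, function(a) {
    if (isTRUE(a)) "yes"
    else if (isFALSE(a)) "no"
    else tolower(as.character(a)[1L])
  }, character(1))
}

#' Read an overrides YAML file
#'
#' Each entry maps a criterion id to `value` (0 or 1) and a free-text
#' `comment` justifying the change.
#'
#' @param path YAML file path.
#' @return Named list suitable for [step3_override()].
#' @export
load_overrides <- function(path) {
  if (!is_scalar_chr(path) || !file.exists(path))
    stop_config("overrides file not found: '%s'", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_config("cannot parse overrides file '%s': %s", path, conditionMessage(e)))
  if (is.null(doc)) list() else doc
}

# --- Session snapshots ------------------------------------------------------

SESSION_SCHEMA_VERSION <- "1"

#' Save a session snapshot to JSON
#'
#' The snapshot captures the variant, rubric version, evidence, audit log
#' and completed steps, so a scoring run is fully reproducible and
#' shareable as one file.
#'
#' @param session An `rve_session`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "rve_session"))
  snap <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    variant = session$variant[c("assembly", "chrom", "pos", "ref", "alt", "gene")],
    rubric_version = session$rubric$version,
    steps_done = as.list(session$steps_done),
    source_versions = as.list(session$source_versions),
    evidence = lapply(session$evidence, function(ev)
      list(criterion_id = ev$criterion_id, value = ev$value,
           provenance = ev$provenance, comment = ev$comment,
           previous = ev$previous,
           raw = if (is.null(ev$raw)) NULL else
             list(source_key = ev$raw$source_key, status = ev$raw$status,
                  value = ev$raw$value, features = as.list(ev$raw$features)))),
    audit = session$audit
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Load a session snapshot saved by [save_session()]
#'
#' @param path Snapshot JSON path.
#' @param rub The `rve_rubric` the session was scored under (validated
#'   against the snapshot's rubric version).
#' @return An `rve_session`.
#' @export
load_session <- function(path, rub) {
  if (!is_scalar_chr(path) || !file.exists(path))
    stop_config("session snapshot not found: '%s'", path)
  snap <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e)
                     stop_io("cannot parse session snapshot '%s': %s",
                             path, conditionMessage(e)))
  if (!identical(snap$schema_version, SESSION_SCHEMA_VERSION))
    stop_io("session snapshot '%s' has schema version '%s'; this build reads '%s'",
            path, as.character(snap$schema_version), SESSION_SCHEMA_VERSION)
  if (!identical(snap$rubric_version, rub$version))
    warning(sprintf("snapshot was scored under rubric '%s', loading under '%s'",
                    snap$rubric_version, rub$version))
  v <- snap$variant
  session <- new_session(
    variant_spec(v$chrom, v$pos, v$ref, v$alt, gene = v$gene,
                 assembly = v$assembly),
    rub)
  session$evidence <- stats::setNames(
    lapply(snap$evidence, function(ev)
      evidence_value(ev$criterion_id, ev$value, provenance = ev$provenance,
                     comment = if (is.null(ev$comment)) "" else ev$comment,
                     previous = ev$previous,
                     raw = if (is.null(ev$raw)) NULL else
                       measurement(ev$raw$source_key, ev$raw$status,
                                   value = ev$raw$value,
                                   features = if (length(ev$raw$features))
                                     unlist(ev$raw$features) else NULL))),
    vapply(snap$evidence, `[[`, character(1), "criterion_id"))
  au <- snap$audit
  session$audit <- if (length(au)) do.call(rbind, lapply(au, function(r)
    audit_row(r$step, r$criterion_id,
              if (is.null(r$old_value)) NA_real_ else r$old_value,
              r$new_value, r$provenance,
              if (is.null(r$comment)) "" else r$comment)))
    else empty_audit()
  session$steps_done <- unlist(snap$steps_done, use.names = FALSE)
  session$source_versions <- unlist(snap$source_versions)
  if (is.null(session$source_versions)) session$source_versions <- character(0)
  session
}

#' @export
print.rve_session <- function(x, ...) {
  cat(sprintf("Scoring session for %s (%s), rubric %s\n",
              format_variant(x$variant), x$variant$gene, x$rubric$version))
  cat(sprintf("  steps completed: %s\n",
              if (length(x$steps_done)) paste(x$steps_done, collapse = ", ")
              else "none"))
  cat(sprintf("  evidence set for %d of %d criteria; %d audit entries\n",
              length(x$evidence), length(x$rubric$criteria), nrow(x$audit)))
  invisible(x)
}
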