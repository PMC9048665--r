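# Report emission. The report mirrors the two halves of a result page: a
# header with the variant, the three scores and the strength vs the
# reference distribution, and a per-criterion table with the 0/1 value,
# weight, contribution, raw measurement, provenance and comment. JSON is
# the lossless machine format (versioned schema, round-trips through
# read_report); TSV carries the table for spreadsheets; markdown renders
# both for humans.

REPORT_SCHEMA_VERSION <- "1"

canonical_header <- function(h) {
  list(variant = as.character(h$variant), gene = as.character(h$gene),
       assembly = as.character(h$assembly),
       c_score = as.numeric(h$c_score), f_score = as.numeric(h$f_score),
       rve_score = as.numeric(h$rve_score),
       max_c = as.numeric(h$max_c), max_f = as.numeric(h$max_f),
       percentile = as.numeric(h$percentile),
       strength_label = as.character(h$strength_label))
}

canonical_table <- function(tab) {
  data.frame(id = as.character(tab$id),
             description = as.character(tab$description),
             component = as.character(tab$component),
             value = as.numeric(tab$value),
             weight = as.numeric(tab$weight),
             contribution = as.numeric(tab$contribution),
             raw = as.character(tab$raw),
             provenance = as.character(tab$provenance),
             comment = as.character(tab$comment),
             stringsAsFactors = FALSE)
}

new_report <- function(header, table, metadata) {
  rep <- structure(list(header = canonical_header(header),
                        table = canonical_table(table),
                        metadata = metadata),
                   class = "rve_report")
  validate_report(rep)
  rep
}

validate_report <- function(rep) {
  h <- rep$header; tab <- rep$table
  tol <- 1e-9
  if (abs(sum(tab$contribution) - h$rve_score) > tol)
    stop_validation("report header RVE-score (%g) disagrees with the table (%g)",
                    h$rve_score, sum(tab$contribution))
  cs <- sum(tab$contribution[tab$component == "clinical"])
  fs <- sum(tab$contribution[tab$component == "functional"])
  if (abs(cs - h$c_score) > tol || abs(fs - h$f_score) > tol)
    stop_validation("report header C/F scores disagree with the table")
  invisible(TRUE)
}

#' Build a report from a finalized session
#'
#' One table row per rubric criterion, in rubric order; the header carries
#' the C- and F-scores separately so the clinical and functional strength
#' of the assessment can be judged at a glance. Header scores always equal
#' the recomputation from the table's contributions.
#'
#' @param result An `rve_result` from [finalize()].
#' @param session The `rve_session` it came from.
#' @param timestamp Report timestamp (UTC, set automatically; injectable
#'   for reproducible output).
#' @return An object of class `rve_report`.
#' @export
build_report <- function(result, session,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  stopifnot(inherits(result, "rve_result"), inherits(session, "rve_session"))
  rub <- session$rubric
  rows <- lapply(rub$criteria, function(cr) {
    ev <- session$evidence[[cr$id]]
    val <- if (is.null(ev)) 0 else ev$value
    data.frame(
      id = cr$id, description = cr$description, component = cr$component,
      value = as.numeric(val), weight = cr$weight,
      contribution = as.numeric(val) * cr$weight,
      raw = if (is.null(ev) || is.null(ev$raw)) "" else format_measurement(ev$raw),
      provenance = if (is.null(ev)) "default_unknown" else ev$provenance,
      comment = if (is.null(ev)) "" else ev$comment,
      stringsAsFactors = FALSE)
  })
  header <- list(
    variant = format_variant(session$variant), gene = session$variant$gene,
    assembly = session$variant$assembly,
    c_score = result$c_score, f_score = result$f_score,
    rve_score = result$rve_score,
    max_c = result$max_scores[["max_c"]], max_f = result$max_scores[["max_f"]],
    percentile = result$percentile, strength_label = result$strength_label)
  metadata <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    rubric_version = rub$version,
    source_versions = as.list(session$source_versions),
    timestamp = timestamp,
    tool = sprintf("rvescore %s", as.character(utils::packageVersion("rvescore"))))
  new_report(header, do.call(rbind, rows), metadata)
}

render_markdown <- function(rep) {
  h <- rep$header
  strength <- if (is.na(h$strength_label)) "not ranked (no reference)"
    else sprintf("%s (percentile %.1f vs reference distribution)",
                 h$strength_label, h$percentile)
  tab <- rep$table
  unknown <- tab$id[tab$provenance == "default_unknown"]
  lines <- c(
    sprintf("# Regulatory variant evidence report: %s", h$variant),
    "",
    sprintf("- **Variant:** %s (%s), suspected target gene **%s**",
            h$variant, h$assembly, h$gene),
    sprintf("- **RVE-score:** %g", h$rve_score),
    sprintf("- **C-score (clinical):** %g / %g", h$c_score, h$max_c),
    sprintf("- **F-score (functional):** %g / %g", h$f_score, h$max_f),
    sprintf("- **Strength:** %s", strength),
    "",
    if (length(unknown))
      c(sprintf("**Unassessed criteria (scored 0 as unknown):** %s",
                paste(unknown, collapse = ", ")), "")
    else character(0),
    "## Evidence",
    "",
    "| id | description | value | weight | contribution | source data | provenance | comment |",
    "|----|-------------|-------|--------|--------------|-------------|------------|---------|",
    sprintf("| %s | %s | %g | %g | %g | %s | %s | %s |",
            tab$id, tab$description, tab$value, tab$weight, tab$contribution,
            tab$raw, tab$provenance, tab$comment),
    "",
    sprintf("_%s; rubric %s; generated %s_",
            rep$metadata$tool, rep$metadata$rubric_version,
            rep$metadata$timestamp))
  paste(lines, collapse = "\n")
}

#' Write a report to disk
#'
#' @param rep An `rve_report`.
#' @param path Output file path.
#' @param format `"json"` (lossless, versioned; see [read_report()]),
#'   `"tsv"` (the per-criterion table) or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rep, path, format = c("json", "tsv", "markdown")) {
  stopifnot(inherits(rep, "rve_report"))
  if (!is_scalar_chr(format) || !format %in% c("json", "tsv", "markdown"))
    stop_input("unknown report format '%s' (use json, tsv or markdown)",
               paste(format, collapse = ","))
  switch(format,
    json = jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE,
                                digits = NA, na = "null", null = "null",
                                dataframe = "rows"),
    tsv = utils::write.table(rep$table, path, sep = "\t", quote = FALSE,
                             row.names = FALSE),
    markdown = writeLines(render_markdown(rep), path))
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' Recovers the report field-for-field; a snapshot from a different schema
#' version fails with an explicit version error rather than a silent
#' misparse.
#'
#' @param path JSON report path.
#' @return An `rve_report` identical to the one written.
#' @export
read_report <- function(path) {
  if (!is_scalar_chr(path) || !file.exists(path))
    stop_io("report file not found: '%s'", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_io("cannot parse report '%s': %s", path,
                            conditionMessage(e)))
  if (!is.list(raw) || is.null(raw$metadata$schema_version))
    stop_io("'%s' is not an rvescore report (no schema version)", path)
  if (!identical(as.character(raw$metadata$schema_version),
                 REPORT_SCHEMA_VERSION))
    stop_io("report '%s' has schema version '%s'; this build reads '%s'",
            path, as.character(raw$metadata$schema_version),
            REPORT_SCHEMA_VERSION)
  h <- raw$header
  if (is.null(h$percentile)) h$percentile <- NA_real_
  if (is.null(h$strength_label)) h$strength_label <- NA_character_
  tab <- raw$table
  tab$comment[is.na(tab$comment)] <- ""
  tab$raw[is.na(tab$raw)] <- ""
  meta <- raw$metadata
  meta$source_versions <- as.list(unlist(meta$source_versions))
  if (is.null(unlist(meta$source_versions))) meta$source_versions <- list()
  new_report(h, tab, list(schema_version = as.character(meta$schema_version),
                          rubric_version = meta$rubric_version,
                          source_versions = meta$source_versions,
                          timestamp = meta$timestamp, tool = meta$tool))
}

#' @export
print.rve_report <- function(x, ...) {
  h <- x$header
  cat(sprintf("RVE report for %s (%s, gene %s)\n", h$variant, h$assembly, h$gene))
  cat(sprintf("  RVE-score %g (C %g/%g, F %g/%g)",
              h$rve_score, h$c_score, h$max_c, h$f_score, h$max_f))
  if (!is.na(h$percentile))
    cat(sprintf("; strength %s, percentile %.1f", h$strength_label, h$percentile))
  cat(sprintf("\n  %d criteria; rubric %s; %s\n", nrow(x$table),
              x$metadata$rubric_version, x$metadata$timestamp))
  invisible(x)
}
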