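# Shared fixtures and independent oracles. The brute-force scorers and the
# all-pairs interval scan are deliberately written against the raw tables,
# not through the package's query/aggregation paths.

toy_rubric4 <- function() {
  rubric(list(
    criterion("C1", "clinical", "toy clinical 1", 2, "manual"),
    criterion("C2", "clinical", "toy clinical 2", 1, "manual"),
    criterion("F1", "functional", "toy functional 1", 3, "manual"),
    criterion("F2", "functional", "toy functional 2", 1, "manual")),
    version = "toy", strict = FALSE)
}

random_toy_rubric <- function(n_c = sample(1:5, 1), n_f = sample(1:5, 1),
                              wmax = 5) {
  crits <- c(
    lapply(seq_len(n_c), function(i)
      criterion(sprintf("C%d", i), "clinical", sprintf("clinical %d", i),
                sample(0:wmax, 1), "manual")),
    lapply(seq_len(n_f), function(i)
      criterion(sprintf("F%d", i), "functional", sprintf("functional %d", i),
                sample(0:wmax, 1), "manual")))
  rubric(crits, version = "toy-random", strict = FALSE)
}

evidence_from_values <- function(vals) {
  stats::setNames(
    lapply(names(vals), function(id)
      evidence_value(id, vals[[id]], provenance = "user_answer")),
    names(vals))
}

# brute-force per-component weighted sum, straight off the rubric table
brute_component_scores <- function(vals, rub) {
  df <- as.data.frame(rub)
  v <- vapply(df$id, function(id)
    if (id %in% names(vals)) as.numeric(vals[[id]]) else 0, numeric(1))
  c(c = sum(v * df$weight * (df$component == "clinical")),
    f = sum(v * df$weight * (df$component == "functional")))
}

# all-pairs half-open overlap scan on raw 0-based interval columns
naive_overlap_idx <- function(chrom, start0, end0, qchrom, qstart0, qend0) {
  which(chrom == qchrom & start0 < qend0 & end0 > qstart0)
}

write_tsv_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_bed_file <- function(df, path = tempfile(fileext = ".bed")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  path
}

per_base_source <- function(chrom, pos, score, key = "phylop",
                            assembly = "GRCh38") {
  annotation_source(key, write_tsv_file(
    data.frame(chrom = chrom, pos = pos, score = score)), assembly = assembly)
}

allele_source <- function(df, key = "gnomad_af", assembly = "GRCh38") {
  annotation_source(key, write_tsv_file(df), assembly = assembly)
}

interval_source <- function(df, key = "remap", assembly = "GRCh38") {
  annotation_source(key, write_bed_file(df), assembly = assembly)
}

write_minimal_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    records), path)
  path
}

ref_dist <- function(scores) {
  data.frame(label = sprintf("R%02d", seq_along(scores)), rve_score = scores)
}

# full pipeline on a generated fixture bundle; returns list(session, key, dir)
fixture_session <- function(recipe, seed = 11, dir = tempfile()) {
  make_fixtures(dir, seed = seed, recipe = recipe)
  rub <- load_rubric(default_rubric_path())
  key <- yaml::read_yaml(file.path(dir, "key.yaml"))
  v <- parse_variant(key$variant, gene = key$gene, assembly = key$assembly)
  session <- step1_auto(new_session(v, rub), load_bundle(file.path(dir, "manifest.yaml")))
  list(session = session, key = key, dir = dir, rubric = rub)
}
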