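# Deterministic synthetic fixtures. make_fixtures() writes a complete
# annotation bundle (six sources), a reference distribution and a key file
# of planted truths, all as plain text and purely as a function of
# (seed, recipe), so the entire pipeline can be exercised offline and every
# expected evidence value is known by construction.
#
# The planted variant sits at chr1:150000 G>A; background rows/intervals are
# drawn away from it (positions 1,000-100,000) so they can never contaminate
# the planted truth.

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

FIXTURE_VARIANT <- list(chrom = "chr1", pos = 150000L, ref = "G", alt = "A",
                        gene = "TFX1")

# Expected 0/1 auto evidence for the default rubric, by construction of the
# planted values (these are the planted truths, not a re-run of the engine).
FIXTURE_EXPECTED <- list(
  `all-pass`    = list(C1.1 = 1L, C1.2 = 1L, C1.3 = 1L,
                       F1.1 = 1L, F1.2 = 1L, F1.3 = 1L),
  `no-coverage` = list(C1.1 = 0L, C1.2 = 0L, C1.3 = 0L,
                       F1.1 = 0L, F1.2 = 0L, F1.3 = 0L),
  mixed         = list(C1.1 = 1L, C1.2 = 0L, C1.3 = 0L,
                       F1.1 = 1L, F1.2 = 0L, F1.3 = 1L)
)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a synthetic annotation bundle, reference file and truth key
#'
#' Writes, deterministically from `seed`:
#' \itemize{
#'   \item per-base conservation tables (`phylop.tsv`, `phastcons.tsv`) with
#'     known values planted at the fixture variant's position,
#'   \item allele tables (`gnomad_af.tsv`, `cadd.tsv`) containing the
#'     planted variant at chosen values,
#'   \item interval sets (`remap.bed`, `encode.bed`) with intervals planted
#'     to overlap (or not) the variant,
#'   \item a bundle `manifest.yaml` tying them together,
#'   \item `reference.tsv`, a synthetic reference distribution of
#'     `n_reference` labelled RVE-scores,
#'   \item `key.yaml`, the planted truths (variant, and the expected 0/1
#'     auto evidence under the bundled default rubric) for use as a test
#'     oracle.
#' }
#'
#' Recipes: `"all-pass"` plants values satisfying every default auto rule;
#' `"no-coverage"` leaves the variant uncovered by every source;
#' `"mixed"` passes some rules and fails others (see `key.yaml`).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the output is a pure function of
#'   `(seed, recipe, n_reference)`. The caller's RNG state is preserved.
#' @param recipe `"all-pass"`, `"no-coverage"` or `"mixed"`.
#' @param n_reference Number of reference-distribution entries (default 46,
#'   the size of the curated collection the reference emulates).
#' @param assembly Assembly label stamped on every source.
#' @return `dir`, invisibly; side effect: files written.
#' @export
make_fixtures <- function(dir, seed = 1L,
                          recipe = c("all-pass", "no-coverage", "mixed"),
                          n_reference = 46L, assembly = "GRCh38") {
  recipe <- match.arg(recipe)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- FIXTURE_VARIANT
  with_preserved_seed(seed, {
    bg_pos <- sort(sample(1000:100000, 60))
    covered <- recipe != "no-coverage"

    # per-base conservation: planted score at the variant base when covered
    phylop <- data.frame(chrom = "chr1", pos = bg_pos[1:30],
                         score = round(stats::rnorm(30, 0, 1), 3))
    if (covered)
      phylop <- rbind(phylop, data.frame(chrom = v$chrom, pos = v$pos, score = 3.5))
    write_tsv(phylop, file.path(dir, "phylop.tsv"))

    phast_val <- if (recipe == "mixed") 0.2 else 0.95
    phast <- data.frame(chrom = "chr1", pos = bg_pos[31:60],
                        score = round(stats::runif(30), 3))
    if (covered)
      phast <- rbind(phast, data.frame(chrom = v$chrom, pos = v$pos, score = phast_val))
    write_tsv(phast, file.path(dir, "phastcons.tsv"))

    # allele tables: planted allele frequency / deleteriousness
    af_val <- if (recipe == "mixed") 0.5 else 1e-4
    gnomad <- data.frame(chrom = "chr1", pos = sample(1000:100000, 10),
                         ref = sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                         alt = "N", value = signif(stats::runif(10, 0, 0.5), 3))
    gnomad$alt <- ifelse(gnomad$ref == "A", "G", "A")
    if (covered)
      gnomad <- rbind(gnomad, data.frame(chrom = v$chrom, pos = v$pos,
                                         ref = v$ref, alt = v$alt, value = af_val))
    write_tsv(gnomad, file.path(dir, "gnomad_af.tsv"))

    cadd <- data.frame(chrom = "chr1", pos = sample(1000:100000, 10),
                       ref = sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                       alt = "N", value = round(stats::runif(10, 0, 40), 2))
    cadd$alt <- ifelse(cadd$ref == "A", "G", "A")
    if (covered)
      cadd <- rbind(cadd, data.frame(chrom = v$chrom, pos = v$pos,
                                     ref = v$ref, alt = v$alt, value = 25))
    write_tsv(cadd, file.path(dir, "cadd.tsv"))

    # interval sets, BED 0-based half-open; the variant base is [pos-1, pos)
    bed_background <- function(n, labels) {
      start <- sample(1000:99000, n)
      data.frame(chrom = "chr1", start = start,
                 end = start + sample(200:1000, n, replace = TRUE),
                 name = sample(labels, n, replace = TRUE))
    }
    remap <- bed_background(15, c("GATA1", "TAL1", "CTCF", "SPI1"))
    if (covered)
      remap <- rbind(remap, data.frame(chrom = v$chrom, start = v$pos - 51,
                                       end = v$pos + 50, name = "GATA1"))
    utils::write.table(remap[order(remap$start), ], file.path(dir, "remap.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)

    encode <- bed_background(15, c("PLS", "pELS", "dELS", "CTCF-only"))
    if (covered && recipe != "mixed")
      encode <- rbind(encode, data.frame(chrom = v$chrom, start = v$pos - 101,
                                         end = v$pos + 100, name = "dELS"))
    utils::write.table(encode[order(encode$start), ], file.path(dir, "encode.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)

    manifest <- list(sources = stats::setNames(lapply(
      names(RVE_SOURCE_KINDS), function(key) {
        ext <- if (RVE_SOURCE_KINDS[[key]] == "interval_set") "bed" else "tsv"
        list(path = paste0(key, ".", ext), assembly = assembly,
             version_label = sprintf("synthetic-%s-seed%d", key, seed))
      }), names(RVE_SOURCE_KINDS)))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))

    reference <- data.frame(
      label = sprintf("SYN%02d", seq_len(n_reference)),
      rve_score = sort(sample(0:40, n_reference, replace = TRUE)))
    write_tsv(reference, file.path(dir, "reference.tsv"))

    key <- list(
      recipe = recipe, seed = as.integer(seed), assembly = assembly,
      variant = sprintf("%s:%d:%s:%s", v$chrom, v$pos, v$ref, v$alt),
      gene = v$gene,
      expected_auto_evidence = FIXTURE_EXPECTED[[recipe]])
    yaml::write_yaml(key, file.path(dir, "key.yaml"))
  })
  invisible(dir)
}
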