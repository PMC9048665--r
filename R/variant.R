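# Variant representation. Variants are 1-based (VCF convention); every
# interval query uses 0-based half-open coordinates (BED convention), and
# ref_span_zero_based() is the single conversion point. Chromosome names are
# normalized to the "chr"-prefixed dialect. The genome assembly travels as
# an opaque label that each annotation source must match; no liftover.

norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

ALLELE_RE <- "^[ACGTacgt]+$"

#' Construct a variant specification
#'
#' @param chrom Chromosome name ("chr9" and "9" are equivalent; normalized
#'   to the chr-prefixed form).
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Reference / alternate allele strings (A/C/G/T, non-empty,
#'   different from each other; upper-cased).
#' @param gene Suspected target gene symbol.
#' @param assembly Genome assembly label, e.g. `"GRCh38"`.
#' @return An object of class `rve_variant`.
#' @export
#' @examples
#' variant_spec("chr9", 136545000, "G", "A", gene = "NOTCH1")
variant_spec <- function(chrom, pos, ref, alt, gene, assembly = "GRCh38") {
  if (!is_scalar_chr(as.character(chrom)))
    stop_input("chromosome must be a non-empty string")
  pos <- suppressWarnings(as.numeric(pos))
  if (!is_scalar_num(pos) || pos < 1 || pos != floor(pos))
    stop_input("position must be an integer >= 1 (1-based)")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!is_scalar_chr(ref) || !grepl(ALLELE_RE, ref))
    stop_input("ref allele must be a non-empty A/C/G/T string, got '%s'", ref)
  if (!is_scalar_chr(alt) || !grepl(ALLELE_RE, alt))
    stop_input("alt allele must be a non-empty A/C/G/T string, got '%s'", alt)
  if (identical(ref, alt))
    stop_input("ref and alt alleles are identical ('%s')", ref)
  if (!is_scalar_chr(gene))
    stop_input("a suspected target gene symbol is required")
  structure(list(assembly = as.character(assembly)[1L],
                 chrom = norm_chrom(chrom), pos = pos,
                 ref = ref, alt = alt, gene = gene),
            class = "rve_variant")
}

parse_colon_variant <- function(text, gene, assembly) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 4L)
    stop_input("variant string must be 'chrom:pos:ref:alt', got '%s'", text)
  variant_spec(parts[1L], parts[2L], parts[3L], parts[4L],
               gene = gene, assembly = assembly)
}

parse_vcf_variant <- function(path, gene, assembly) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE), error = function(e)
    stop_input("cannot read VCF '%s': %s", path, conditionMessage(e)))
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) stop_input("VCF '%s' contains no records", path)
  if (nrow(fx) > 1L)
    stop_input("VCF '%s' has %d records; exactly one is required", path, nrow(fx))
  alt <- fx[1L, "ALT"]
  if (grepl(",", alt, fixed = TRUE))
    stop_input("multi-allelic VCF records are not supported (ALT '%s')", alt)
  variant_spec(fx[1L, "CHROM"], fx[1L, "POS"], fx[1L, "REF"], alt,
               gene = gene, assembly = assembly)
}

#' Parse a variant from a CLI string or a single-record VCF
#'
#' Accepts either a `"chrom:pos:ref:alt"` string or the path of a VCF
#' (v4.x) file containing exactly one record.
#'
#' @param text Variant string or VCF file path.
#' @param gene Suspected target gene symbol.
#' @param assembly Genome assembly label.
#' @return An `rve_variant`.
#' @export
#' @examples
#' parse_variant("chr9:136545000:G:A", gene = "NOTCH1")
parse_variant <- function(text, gene, assembly = "GRCh38") {
  if (!is_scalar_chr(text)) stop_input("empty variant specification")
  if (file.exists(text) || grepl("\\.vcf(\\.gz)?$", text))
    parse_vcf_variant(text, gene, assembly)
  else
    parse_colon_variant(text, gene, assembly)
}

#' Format a variant back to its canonical string
#' @param v An `rve_variant`.
#' @return `"chrom:pos:ref:alt"` string.
#' @export
format_variant <- function(v) {
  stopifnot(inherits(v, "rve_variant"))
  sprintf("%s:%d:%s:%s", v$chrom, as.integer(v$pos), v$ref, v$alt)
}

#' Reference span in 0-based half-open coordinates
#'
#' The reference allele occupies 1-based positions
#' `[pos, pos + nchar(ref) - 1]`; in BED convention that is the half-open
#' interval `[pos - 1, pos - 1 + nchar(ref))`.
#'
#' @param v An `rve_variant`.
#' @return Named numeric vector `c(start, end)`, 0-based half-open.
#' @export
ref_span_zero_based <- function(v) {
  stopifnot(inherits(v, "rve_variant"))
  c(start = v$pos - 1, end = v$pos - 1 + nchar(v$ref))
}

#' @export
print.rve_variant <- function(x, ...) {
  cat(sprintf("Variant %s (%s), suspected target gene %s\n",
              format_variant(x), x$assembly, x$gene))
  invisible(x)
}
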