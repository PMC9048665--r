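# rvescore

Evidence scoring for regulatory variants implicated in rare disease.

Assessing whether a non-coding variant — in a promoter, enhancer or UTR —
causes a disease by disrupting the regulation of a target gene is hard to do
consistently: the strongest evidence is scattered across population
databases, conservation tracks, epigenomic annotations and gene-specific
publications. `rvescore` implements a semiquantitative evidence rubric for
exactly this setting. It is aimed at clinical and research geneticists who
need a reproducible, auditable score for a candidate regulatory variant and
its suspected target gene, computed entirely offline from local annotation
files.

## The score

Evidence is organised as 24 criteria in two components:

- **clinical** criteria `C*` ask *is there a causal link between genotype
  and phenotype?* (conservation, rarity, gene relevance, familial
  segregation, recurrence, model organisms);
- **functional** criteria `F*` ask *does the variant have a damaging effect
  on the regulation of the target gene?* (TF-binding and regulatory-element
  overlap, predicted deleteriousness, biochemical and reporter assays,
  engineered systems).

Each criterion *i* is scored binary — eᵢ = 0 when the evidence does not
apply **or is unknown**, eᵢ = 1 when it applies — and weighted:

```
C-score   = Σ_{i ∈ clinical}   eᵢ · wᵢ
F-score   = Σ_{i ∈ functional} eᵢ · wᵢ
RVE-score = C-score + F-score
```

The RVE-score (Regulatory Variant Evidence score) is then ranked against a
reference distribution of curated regulatory variants by the ≤-count ECDF,
with a low / intermediate / high label at the reference tertiles. Six
criteria are scored automatically from local annotation sources (phyloP,
phastCons, gnomAD, CADD, ReMap, ENCODE adapters); the rest are answered
yes/no by the user, and any value can be overridden with a justifying
comment. Every decision is kept in an audit log, and the per-criterion
table, raw measurements and provenance are emitted as JSON, TSV and
markdown reports. The score is complementary to — and separate from — ACMG
classification.

## Worked example

A complete offline run against a generated fixture bundle (the
`make_fixtures()` generator plants known values at a known variant, so the
expected evidence is known by construction):

```r
library(rvescore)

dir <- tempfile()
make_fixtures(dir, seed = 7, recipe = "all-pass")

rub <- load_rubric(default_rubric_path())
bundle <- load_bundle(file.path(dir, "manifest.yaml"))
v <- parse_variant("chr1:150000:G:A", gene = "TFX1")

s <- new_session(v, rub) |>
  step1_auto(bundle) |>
  step2_manual(c(C3.1 = "yes", F3.1 = "yes"))
s <- step3_override(s, list(C2.1 = list(value = 1, comment = "PMID:12345")))

res <- finalize(s, load_reference(default_reference_path()))
res
#> RVE-score: 14  (C-score 8/27, F-score 6/26)
#> Percentile vs reference: 63.0  strength: intermediate

rep <- build_report(res, s)
write_report(rep, "variant_report.json", "json")
write_report(rep, "variant_report.md", "markdown")
```

The six automatic criteria all fire on the `all-pass` fixture (3 clinical +
3 functional, weight 1 each), the two *yes* answers add the familial
segregation criterion C3.1 (weight 3) and the reporter-assay criterion F3.1
(weight 3), and the override adds gene-relevance C2.1 (weight 2): C-score
3 + 3 + 2 = 8 of 27, F-score 3 + 3 = 6 of 26, RVE-score 14. 63% of the
bundled reference scores lie at or below 14, between the reference tertiles,
hence *intermediate*.

The same run from a shell:

```sh
rve=$(Rscript -e 'cat(system.file("exec", "rve", package = "rvescore"))')
Rscript "$rve" make-fixtures --dir fx --seed 7 --recipe all-pass
Rscript "$rve" score --variant chr1:150000:G:A --gene TFX1 \
    --bundle fx/manifest.yaml --answers answers.yaml --out variant_report
```

The bundled rubric (`inst/extdata/rubric_default.yaml`) is data, not code:
point `--rubric` at your own transcription to change criterion texts,
weights, modes or thresholds. The bundled reference distribution is a
synthetic stand-in (`reference_scores_synthetic.tsv`, 46 labelled scores);
substitute the curated collection you rank against via `--reference`.

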