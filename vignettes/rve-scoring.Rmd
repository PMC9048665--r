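---
title: "Scoring regulatory variant evidence: model, conventions and design"
author: "rvescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring regulatory variant evidence: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvescore)
```

## The model

`rvescore` computes the Regulatory Variant Evidence score (RVE-score) for a
candidate regulatory variant and its suspected target gene. The model is an
evidence rubric, not a statistical fit: 24 criteria, each a yes/no
statement about the variant, are scored

* `0` — the evidence does not apply to the variant **or is unknown**,
* `1` — the evidence applies,

and each 0/1 value is multiplied by a non-negative criterion weight. The
clinical component (criteria `C*`: conservation, population rarity, gene
relevance, familial segregation, recurrence across families, model-organism
phenotypes) sums to the **C-score**; the functional component (criteria
`F*`: TF-binding and regulatory-element overlap, predicted deleteriousness,
motif and biochemical evidence, reporter and engineered-system assays) sums
to the **F-score**; their total is the **RVE-score**, the accumulated
evidence for a causative regulatory role. The two components are reported
separately so a user can see whether an assessment is clinically strong but
functionally thin, or vice versa.

Two modelling consequences of the 0/1-with-unknown rule are worth stating
explicitly. First, the score is monotone: acquiring evidence can never
lower it (the package property-tests this exhaustively on toy rubrics).
Second, absence of data and assessed absence are conflated *in the score* —
both contribute 0 — but never in the report: every value carries a
provenance (`auto`, `user_answer`, `user_override`, `default_unknown`) and
unassessed criteria are listed prominently.

### Ranking against a reference distribution

A raw RVE-score is hard to interpret alone, so it is ranked against a
reference distribution of scored regulatory variants: the percentile is the
≤-count ECDF, `100 · #(reference ≤ score) / n`, and a strength label is
assigned by comparing the score to the reference tertiles (below the first
tertile: *low*; below the second: *intermediate*; otherwise *high*). The
tertile convention is a deliberate, replaceable choice — the display only
needs "is this high or low compared to published variants" — and the cut
probabilities are an argument of `rank_against_reference()`. The curated
collection this emulates holds 46 variants; since its per-variant scores
are not redistributable here, the package ships a **synthetic** stand-in
(`reference_scores_synthetic.tsv`, 46 labelled scores spanning 3–30 with a
right tail), clearly labelled as such. Any real reference TSV
(`label`, `rve_score`) can be substituted.

## The rubric is data

The engine is rubric-agnostic: criterion texts, components, weights, modes
and thresholds live in a YAML file (`rubric_default.yaml`), loaded and
validated by `load_rubric()`. Production loading enforces exactly 24
criteria with both components non-empty; `strict = FALSE` admits toy
rubrics so the engine's algebra can be tested independently of the shipped
scheme.

The bundled default transcribes the published scheme's structure — five
clinical evidence tiers (variant-level, gene-level, family-level,
population-level, model-organism) and four functional tiers (location,
biochemical, regulatory activity, engineered systems) — with weights that
increase with evidentiary strength, from 1 for annotation-level evidence to
4 for model-organism demonstration. The weights and the six automatic
thresholds are package defaults, documented here so they can be criticised
and edited in one place:

| source | criterion | rule | rationale |
|---|---|---|---|
| phyloP | C1.1 | ≥ 2.0 | common operating point for per-base constraint |
| phastCons | C1.2 | ≥ 0.5 | posterior probability of a conserved element |
| gnomAD AF | C1.3 | < 0.01 | rare-disease allele-frequency ceiling |
| CADD | F1.3 | ≥ 10 | phred scale: top 10% most deleterious |
| ReMap | F1.1 | overlap present | any experimentally supported TF binding |
| ENCODE cCRE | F1.2 | overlap present | any candidate regulatory element |

Threshold boundaries are inclusive for `ge`/`le` and exclusive for
`gt`/`lt`, exactly as the operator names say; rubric authors choose the
operator. The operator set also contains `absent`/`present` so a rubric can
score *absence from a population database* as evidence, keeping "missing"
distinguishable from "frequency 0". A variant missing from the allele table
under the comparative `< 0.01` rule scores 0 — unknown, not rare — which is
the conservative reading; a rubric that prefers to reward absence can say
so with the `absent` operator.

The scheme defines no per-category cap, so plain weighted sums are
implemented; if a transcription of the rubric requires a cap, the rubric
file is the single place it would be encoded, and the engine would need a
documented extension.

## Coordinates and annotation adapters

Variants are 1-based (VCF convention); all interval queries are 0-based
half-open (BED convention); `ref_span_zero_based()` is the single
conversion point, so an SNV at position *p* queries `[p−1, p)`. Chromosome
names are normalised to the `chr`-prefixed dialect on input, both for
variants and for source files. The assembly is an opaque label checked for
equality between the variant and every source — a mismatch is a
configuration error, and no liftover is attempted. All queries are
strand-agnostic.

The six external resources are served by three adapter kinds, all reading
local plain-text files declared in a YAML bundle manifest:

* `per_base_score` (phyloP, phastCons): TSV `chrom, pos, score`. Multi-base
  reference spans take the **maximum** per-base score — the most conserved
  base — a conservative choice for evidence of constraint.
* `allele_table` (gnomAD, CADD): TSV `chrom, pos, ref, alt, value`, exact
  four-field match; duplicate allele rows are rejected at load with the row
  named.
* `interval_set` (ReMap, ENCODE): BED4, any-overlap (≥1 shared base)
  semantics via `GenomicRanges::findOverlaps`; column 4 carries the feature
  label (TF name, element class) into the report. Zero overlaps are
  represented as a *missing* measurement, which is what the
  `present`/`absent` operators read.

Each source carries a free-text `version_label` that flows into report
metadata, so a score is always traceable to the resource versions that
produced it.

## The staged workflow and its audit trail

A scoring session mirrors a three-step assessment: `step1_auto()` gathers
and binarizes all automatic evidence (raw measurements retained);
`step2_manual()` applies yes/no answers for the manual criteria (`yes` → 1,
`no` → 0 with provenance `user_answer`; unanswered → 0 with
`default_unknown`); `step3_override()` forces values with a justifying
comment, warning on every override — and again on an empty comment —
because scores should only be changed with strong evidence. Step order is
enforced; automatic and manual criteria are disjoint, and overrides are the
sole mechanism for changing an automatic value. Every change appends to an
audit log, and replaying that log from an empty evidence set reproduces the
session's decisions exactly (a property the tests assert); sessions
serialize to a single JSON snapshot for sharing and re-rendering.
`finalize()` is pure: it scores and ranks without mutating the session.

## Numerical and degenerate-input choices

* Scores are integers whenever all weights are integers; the engine accepts
  non-negative real weights without losing any invariant.
* An empty reference distribution leaves percentile and strength unset with
  a warning — the score itself is still reported.
* Comparative rules evaluate only *found*, finite measurements; anything
  else scores 0 rather than erroring, because unknown is a defined outcome
  of the model.
* JSON reports carry a schema version; a report from a different schema
  fails loudly rather than misparsing.
* Ties at a tertile cut point fall upward (`score < cut` is strict), so a
  score exactly at the first tertile is *intermediate*.

## What the synthetic fixtures do and do not show

`make_fixtures()` writes, deterministically from a seed, a complete bundle
in which known values are planted at a known variant (chr1:150000 G>A) and
background rows are drawn away from it: recipes `all-pass`, `no-coverage`
and `mixed` plant measurements that satisfy all, none, or a hand-chosen
subset of the default automatic rules, and a `key.yaml` records the planted
truths so tests can assert exact expected evidence without re-running the
engine. The generator emulates the *interfaces* of real resources — table
shapes, coordinate conventions, boundary behaviour — at small scale
(tens of rows and intervals around a single locus; reference distribution
of 46 by default). It does not emulate genome-scale data volume, realistic
score distributions, multi-chromosome structure or correlated annotations;
passing tests therefore demonstrate the correctness of the plumbing and the
algebra, not calibration of the thresholds against real tracks. Property
suites run at sizes chosen to enumerate the relevant cases (1,000 random
evidence vectors; all 2⁸ vectors of an 8-criterion rubric; 10⁴
interval/variant pairs against an all-pairs scan).

## Known limitations

* The default rubric's weights and thresholds are this package's own
  transcription of the published scheme's structure; users holding the
  original supplementary tables should transcribe them into the rubric file
  verbatim and version it.
* The bundled reference distribution is synthetic; strength labels against
  it are illustrative until a real curated reference is supplied.
* Single-variant, single-allele focus: no HGVS parsing, multi-allelic
  records, structural variants, liftover, or live database queries. Batch
  scoring is a thin loop left to the user.
* The score is evidence accumulation, not a calibrated pathogenicity
  probability, and is separate from ACMG classification.
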