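# Default 24-criterion scoring rubric for regulatory variant evidence.
# Clinical criteria (C*) ask whether there is a causal link between genotype
# and phenotype; functional criteria (F*) ask whether the variant has a
# damaging effect on the regulation of the target gene. Each criterion is
# scored 0 (does not apply / unknown) or 1 (applies) and multiplied by its
# weight. Six criteria are scored automatically from local annotation
# sources; the rest are answered yes/no by the user. Weights and thresholds
# are package defaults documented in the methods vignette; edit this file
# (or point --rubric at your own) to use a different transcription of the
# scheme.
version: default-1.0
criteria:
  # --- Clinical: variant-level evidence (auto) ------------------------------
  - id: C1.1
    component: clinical
    description: "Variant position is evolutionarily conserved (phyloP)"
    weight: 1
    mode: auto
    operator: ge
    cutoff: 2.0
    source_key: phylop
  - id: C1.2
    component: clinical
    description: "Variant falls in a conserved element (phastCons)"
    weight: 1
    mode: auto
    operator: ge
    cutoff: 0.5
    source_key: phastcons
  - id: C1.3
    component: clinical
    description: "Variant is rare in unaffected individuals in the relevant populations (gnomAD allele frequency)"
    weight: 1
    mode: auto
    operator: lt
    cutoff: 0.01
    source_key: gnomad_af
  # --- Clinical: gene-level evidence (manual) -------------------------------
  - id: C2.1
    component: clinical
    description: "Suspected target gene has been implicated in the same or a similar disease phenotype, or is otherwise relevant"
    weight: 2
    mode: manual
  - id: C2.2
    component: clinical
    description: "Coding variants in the suspected target gene cause a similar disease phenotype"
    weight: 2
    mode: manual
  - id: C2.3
    component: clinical
    description: "No coding variant in the suspected target gene explains the phenotype in the proband"
    weight: 1
    mode: manual
  # --- Clinical: family-level evidence (manual) -----------------------------
  - id: C3.1
    component: clinical
    description: "Variant shows familial segregation with the disease"
    weight: 3
    mode: manual
  - id: C3.2
    component: clinical
    description: "Variant arose de novo in the proband"
    weight: 2
    mode: manual
  # --- Clinical: population-level evidence (manual) -------------------------
  - id: C4.1
    component: clinical
    description: "Variant observed in multiple unrelated affected individuals with the same disease phenotype"
    weight: 3
    mode: manual
  - id: C4.2
    component: clinical
    description: "Variant or locus is statistically associated with the disease phenotype in a cohort"
    weight: 3
    mode: manual
  # --- Clinical: model-organism evidence (manual) ---------------------------
  - id: C5.1
    component: clinical
    description: "Introduction of the variant in a model organism recapitulates the disease phenotype"
    weight: 4
    mode: manual
  - id: C5.2
    component: clinical
    description: "Phenotype in a model is rescued by restoring target gene expression"
    weight: 4
    mode: manual
  # --- Functional: location and annotation evidence -------------------------
  - id: F1.1
    component: functional
    description: "Variant overlaps an experimentally supported transcription-factor binding region (ReMap)"
    weight: 1
    mode: auto
    operator: present
    source_key: remap
  - id: F1.2
    component: functional
    description: "Variant lies in a candidate cis-regulatory element (ENCODE cCRE)"
    weight: 1
    mode: auto
    operator: present
    source_key: encode
  - id: F1.3
    component: functional
    description: "Variant has a high predicted deleteriousness score (CADD, phred scale)"
    weight: 1
    mode: auto
    operator: ge
    cutoff: 10
    source_key: cadd
  - id: F1.4
    component: functional
    description: "Variant lies in open chromatin or an active regulatory region in a disease-relevant tissue"
    weight: 1
    mode: manual
  # --- Functional: biochemical evidence (manual) ----------------------------
  - id: F2.1
    component: functional
    description: "Variant alters transcription-factor binding in vitro (e.g. EMSA)"
    weight: 2
    mode: manual
  - id: F2.2
    component: functional
    description: "Variant disrupts a predicted transcription-factor binding motif"
    weight: 1
    mode: manual
  - id: F2.3
    component: functional
    description: "Allele-specific transcription-factor binding or chromatin state observed in vivo"
    weight: 3
    mode: manual
  # --- Functional: regulatory-activity evidence (manual) --------------------
  - id: F3.1
    component: functional
    description: "Variant alters reporter gene expression in a relevant cell type (e.g. luciferase assay)"
    weight: 3
    mode: manual
  - id: F3.2
    component: functional
    description: "Variant region physically contacts the target gene promoter (e.g. 3C/Hi-C)"
    weight: 2
    mode: manual
  - id: F3.3
    component: functional
    description: "Target gene expression is altered in patient-derived cells or tissue"
    weight: 3
    mode: manual
  # --- Functional: engineered-system evidence (manual) ----------------------
  - id: F4.1
    component: functional
    description: "Introduction of the variant in a cell line alters target gene expression"
    weight: 4
    mode: manual
  - id: F4.2
    component: functional
    description: "Introduction of the variant in a model organism alters target gene expression"
    weight: 4
    mode: manual
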