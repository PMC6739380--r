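---
title: "Discordant-sibling exome segregation with sibseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discordant-sibling exome segregation with sibseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibseg)
```

## The design

Monogenic disorders with incomplete penetrance pose a classic mapping
problem: siblings can share the causal genotype yet diverge completely in
clinical outcome. A well-known example is severe α1-antitrypsin deficiency,
where some PI\*ZZ carriers develop early emphysema and their PI\*ZZ siblings
stay healthy. The *extreme discordant sibling* design exploits this: within
each family, compare exomes of genotype-concordant, phenotype-discordant
siblings; across a handful of unrelated families, keep only variants whose
inheritance pattern repeats. Modifier variants segregating with (or against)
the phenotype become visible with very few subjects because the shared
monogenic background and the family structure remove most heterogeneity.

`sibseg` implements that workflow end to end on standard file formats
(multi-sample VCF, 6-column PED, annotation TSV, GMT gene sets), with every
stage auditable and a synthetic-cohort generator providing ground truth for
validation.

## The filter cascade

Variants pass through a fixed-order cascade; the per-stage ledger
(`FilterTrace`) records how many remain after each step, mirroring the
flowchart style of exome studies.

| stage | semantics | parameter (default) |
|---|---|---|
| `total` | input biallelic variants | — |
| `drop_low_quality` | calls with genotype quality below the floor are masked to missing; variants left with no alternate-carrying call drop out (this also catches cohort-monomorphic sites) | GQ floor (20, Phred) |
| `drop_unconfirmed_transcript` | annotation says the transcript is not confirmed | — |
| `drop_utr` | 5'/3' untranslated regions | — |
| `functionally_annotated` | checkpoint: variants with no annotation row at all are dropped and counted here | — |
| `high_confidence` | alternate-supporting depth aggregated over carriers must *strictly* exceed the threshold (exactly 30 fails) | alt coverage (30 reads), aggregation `max`/`min`/`sum` (`max`) |
| `non_synonymous` | synonymous consequences leave; unknown vocabulary is an error in strict mode, never silently synonymous | synonym dictionary (shipped) |
| `drop_minor_in_reference` | sites where the reference genome carries the population-minor allele (alternate population frequency > 0.5) are systematic false positives; a tie at exactly 0.5 is kept, a missing frequency keeps the variant and increments a counter | — |

Choices the literature leaves open, declared here: "alternate allele
coverage" is read as the maximum alt depth across carrier samples
(configurable); the quality floor acts on genotype quality, since base-level
filtering happens upstream in the caller; variants lacking annotation are
accounted at the checkpoint rather than silently merged into other stages.
Coordinates are 1-based, multiallelic records are split into biallelic
variants (allele-specific AD; a non-focal alternate allele counts as
non-carrier for the focal variant), and sex chromosomes are treated as
autosomal unless `exclude_sex_chrom` is set.

Coverage QC (`qc_report()`) reports per-sample mean depth, the fraction of
targets at ≥ 20X, and uniformity. Uniformity has no standard definition, so
the report declares the one used: the fraction of targets with depth at
least 0.2 × the sample's mean depth.

## Segregation calling

Two inheritance models are tested per phenotype group:

* **recessive** ("shared homozygosity"): every group member of a family is
  homozygous for the alternate allele;
* **dominant** ("shared variant"): every group member carries at least one
  alternate allele.

A family with several same-group siblings must satisfy the model in *all* of
them (strictest reading of "shared"; `member_rule = "any"` relaxes this). A
missing genotype makes the family fail — conservative, rather than removing
the family from the denominator. A call requires the model to hold in at
least *k* of the *N* families (defaults k = 3, N = 4). Model assignment gives
recessive precedence: a variant recessively confirmed is reported only under
the recessive model, so the two blocks are disjoint per (variant, group).

**Exclusivity.** A discriminating variant should fail in the opposite
phenotype group. The default mode (`same_model`) requires that the opposite
group could not itself be confirmed under the call's model; `any_model` is
stricter, `none` disables the check. The mode used is echoed in the report,
because published gene lists do not always state whether exclusivity was
enforced globally or inspected post hoc.

**Table-fixture mode.** `segregate_table()` classifies *printed* genotype
tables (gene, SNP id, wild-type allele, per-subject cells) row by row: a row
whose evidence is purely homozygous-alternate in ≥ k cells is recessive;
otherwise ≥ k carrier cells make it dominant. Classifying rows rather than
merged variants matters: such tables can legitimately print one variant in
both blocks when the dominant evidence covers more families than the
homozygous evidence (the bundled worked example contains exactly one such
row). Rows confirmed in fewer than k families are flagged; with
`rescue = TRUE` (default) they are kept when the same gene already has a
confirmed call under the same model — the gene-level reading that printed
tables use — and marked `rescued`.

```{r}
fx <- paper_fixtures()
calls <- segregate_table(fx$affected, group = "affected", k = 3)
summarize_calls(calls, fx$curated_affected)
```

Curated-gene percentages (here, immune-related genes) are computed against a
user-supplied list — membership is an input, never inferred — and rounded
half-up to integers, the convention such summaries print with.

## Over-representation and the enrichment map

`hypergeom_upper()` computes the exact one-sided hypergeometric tail (no
normal approximation); `bh_fdr()` is the standard Benjamini–Hochberg
step-up. `run_ora()` tests each gene set against the query within a declared
universe; the pipeline's default universe is every gene carrying at least
one post-cascade variant, a choice declared in the outputs because published
analyses rarely state their background. Sets smaller than 3 or larger than
500 genes after universe intersection are skipped (configurable). Only
over-representation is tested, not depletion.

`build_enrichment_map()` turns significant sets (q ≤ 0.05) into a network
whose edges weight gene overlap. The default similarity is the overlap
coefficient |A∩B|/min(|A|,|B|) with cutoff 0.375 — the convention of the
enrichment-map tooling this mirrors — with Jaccard available by flag.
Networks export as SIF plus an edge-attribute TSV.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: four unrelated families,
one affected sibling each and five non-affected siblings overall (one family
contributes two), exome-like depths from a negative binomial with mean 105
and size 8, genotype qualities high (90) except where a variant is fated to
fail the quality stage (5).

* **Background variants** draw genotypes per individual from Hardy–Weinberg
  proportions at a variant-specific alternate-allele frequency, uniform on
  [0.05, 0.5] (the alternate is the minor allele), except reference-minor
  fated variants which draw from [0.55, 0.95]. Siblings are genotype-wise
  independent: no identity-by-descent transmission model, no linkage
  disequilibrium, no mutation-rate or sequence-context realism. That is
  sufficient to exercise the caller and the cascade; it is *not* a
  population-genetic simulator, so passing tests say nothing about, e.g.,
  haplotype-aware methods on real data.
* **Planted variants** (default three per model × group combination, twelve
  in total) are forced to satisfy their model in exactly three of the four
  families, fail it in the remaining family, and be homozygous-reference
  throughout the opposite group — hence exclusive under every mode.
* **Stage fates**: each background variant is assigned a cascade fate
  (about a quarter on unconfirmed transcripts, a fifth in UTRs, half of the
  annotated remainder synonymous, small fractions for quality, coverage and
  reference-minor failures), and its annotation/evidence is constructed to
  realize it. The truth manifest then records the *realized* fate, re-derived
  per variant from the raw evidence by independent scalar bookkeeping — so a
  background variant that happens to draw no alternate allele is honestly
  booked to the quality stage, and manifest totals match the cascade exactly.
* **Planted pathway**: one GMT set contains all planted genes, padded with
  genes whose variants do not survive the cascade. The enrichment effect
  size is therefore the full planted gene count against the post-cascade
  universe — a deliberately strong, well-defined signal; the decoy sets are
  random draws.

Everything is reproducible from the mandatory seed; the same configuration
writes byte-identical files.

```{r}
sim <- simulate_cohort(sim_config(seed = 1, n_background = 100))
sim
table(sim$manifest$fate)
```

## Validation strategy and problem sizes

The test suite checks each component against an independent oracle:
segregation against a plain-loop brute-force enumerator on random genotype
matrices; the hypergeometric tail against exhaustive enumeration of all
draws for universes up to 25; BH against hand-computed step-ups and the
reference implementation; enrichment-map edges against all-pairs overlap;
generator output against closed-form Hardy–Weinberg expectations (pooled
chi-square over 5000 variants, and a 200-seed comparison of false-call
counts against the exact Poisson-binomial form). Planted-variant recovery is
verified across 200 seeded cohorts of 30 background plus 12 planted
variants, and planted-pathway power across 100 seeded runs at the default
configuration — sizes chosen to make the checks statistically meaningful
while keeping the suite quick on a laptop.

## Limitations

De novo, compound-heterozygote and X-linked models are out of scope, as are
kinship verification, linkage statistics, annotation generation (annotations
are a file input) and genome-build liftover. The worked-example fixtures
transcribe printed tables whose blank-cell positions are not recoverable;
block membership does not depend on them, and the one structurally ambiguous
row (confirmed in only two printed cells) is included solely via the flagged
gene-level rescue described above.
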