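---
title: "Knowledgebase-driven panel design and single-molecule validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledgebase-driven panel design and single-molecule validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmips)
```

panelmips implements the full life cycle of a clinically driven targeted
cancer panel built from a community-curated variant knowledgebase: selecting
variants worth capturing, turning them into merged genomic target regions,
collapsing molecular-tagged (smMIP/UMI) capture reads into single-molecule
consensus data, calling variants and validating them against orthogonal
sequencing, statistically triaging panel-only findings, and matching calls
back to the knowledgebase for clinical reporting. This vignette documents
the models, the tunable parameters and the design decisions behind each
stage, and states exactly what the synthetic cohort used by the test suite
does and does not emulate.

## Variant selection from a knowledgebase snapshot

The unit of input is a snapshot JSON of knowledgebase variants, each with
1-based fully-closed genomic coordinates, sequence-ontology accessions and
a list of *evidence items* (type Predictive/Prognostic/Diagnostic/
Predisposing, level A–E, 0–5 star trust rating, direction, clinical
significance, variant origin, disease, drugs, curation status).

**Variant evidence score.** Knowledgebases summarize curation weight as an
aggregate score. We implement it as the weighted sum

$$S(v) \;=\; \sum_{e \in \mathrm{counted}(v)} w_{\mathrm{level}(e)} \cdot \mathrm{stars}(e),$$

with default weights $w_A=10, w_B=5, w_C=1, w_D=0.5, w_E=0.25$ mirroring
the public convention (validated association down to inferential). The
weights and the decision whether submitted (unreviewed) items count are
deliberately configuration (`score_config()`), not constants: different
snapshot vintages and curation policies weight evidence differently, and
the gate itself — `score > 20`, strictly — is what the downstream design
reproduces. Only `accepted` items count by default.

**Eligibility cascade.** `filter_eligible()` applies, in a fixed order that
assigns each excluded variant exactly one primary reason:

1. has coordinates (coordinate-free records can never be captured);
2. evidence score strictly above the threshold (default 20);
3. DNA-detectable sequence ontology (membership in a shipped, overridable
   whitelist of SO accessions — fusions and expression-level records are
   excluded since DNA capture cannot see them);
4. not germline-only (all counted evidence of germline origin). Panels
   aimed at somatic profiling drop these; because predisposition evidence
   is inherently germline, a flag (`germline_exempt_predisposing`) lets
   users retain variants whose only germline evidence is Predisposing;
5. not directly conflicting. The knowledgebase does not define "directly
   conflicting", so we operationalize it: two counted, Supports-direction
   items of the same evidence type and disease (and identical drug sets
   for Predictive items) whose clinical-significance labels form an
   opposing pair (Sensitivity/Response vs Resistance, Better vs Poor
   Outcome, Positive vs Negative, Pathogenic vs Benign). The opposition
   table is user-replaceable;
6. not a redundant container. Gene-level container records ("MUTATION",
   empty alleles) often summarize hotspots that specific records already
   cover. Variants are visited in descending score (ties broken by id);
   a container is dropped when more than `redundancy_majority_fraction`
   (default 0.5, i.e. a strict majority) of its counted evidence items
   cite a hotspot coordinate lying inside already-selected regions.

## Target regions

Variant length (`stop − start + 1`) decides the capture strategy: strictly
below 250 bp is a *hotspot* target (the variant interval, optionally
flanked); at or above 250 bp the variant is exon-tiled. The 250 bp
boundary itself goes to tiling because the hotspot rule is a strict
inequality. Whether tiling is *full* (all CDS exons of the gene) or
*sparse* (only exons intersecting evidence-cited hotspot coordinates) is
governed by a name rule — gene-level container names `MUTATION`, `LOSS`,
`FRAMESHIFT`, `DELETION` tile fully, everything else sparsely — with a
per-variant configuration-table override; the rule is intentionally
prominent configuration because no single convention fits every
knowledgebase. A sparse-tiled record with no cited hotspots anchors exon
selection on its own interval instead (the alternative — contributing no
targets at all — silently drops a scored variant).

All intervals are merged per chromosome with bookended intervals
coalescing (contiguous capture targets; `[1,10]` and `[11,20]` become
`[1,20]`), source variant ids are unioned, and BED output converts the
internal 1-based closed convention to BED's 0-based half-open one at the
last moment. Merging is idempotent and its footprint equals a per-base
count, which the test suite verifies by brute force.

**Percentage reporting.** Panel summaries report evidence-type shares as
integer percentages using largest-remainder (Hamilton) apportionment so
shares always sum to exactly 100 — the convention that matches how mixed
rounded percentages are reported in practice; plain nearest rounding and
raw shares remain available (`percent_shares()`).

## Single-molecule consensus

Each capture probe ligates a random molecular tag (UMI) to one original
DNA molecule; strands are captured separately. Reads therefore group into
families keyed by (probe, tag, strand), and PCR/sequencing redundancy
within a family can be collapsed into one consensus observation per
molecule:

* at each position, the consensus base is the base whose support strictly
  exceeds `family_agreement_min` (default 0.5 — a strict majority) of the
  family's covering reads; ties and split support yield `N`;
* `N` base calls in raw reads never vote;
* families smaller than `min_reads_per_family` (default 1) are dropped;
* a family contributes at most 1 to each position of the pileup, and `N`
  consensus calls are tallied separately but excluded from depth, so
  depth never exceeds the number of covering molecules.

The strict-majority rule and the singleton-family floor are deliberate
simplicity: they are not the only defensible choices (published pipelines
vary in minimum family size and agreement), so both live in `qc_config()`.
Strand-separate families are *not* re-merged into duplex consensus; duplex
error modeling is out of scope.

Sample-level sequencing QC operates on the batch processed together: a
sample fails when its tag complexity (distinct captured molecules) is
below 600,000 or its total read count lies more than 1 standard deviation
below the batch mean (both thresholds configurable). The SD test needs at
least two samples and is otherwise skipped with a warning.

## Calling and orthogonal validation

SNVs are emitted per position/base where the consensus base differs from
the reference and unique-molecule support passes `min_depth` (20),
`min_alt_count` (4) and `min_vaf` (0.01). These defaults are explicit
configuration: consensus depth is molecule count, not read count, and
appropriate cutoffs depend on input mass and family counts.

Validation against an orthogonal truth set first intersects truth
variants with the panel footprint (only overlapping variants are
detectable by design), then matches on exact chromosome/position/ref/alt
— never position alone — after both sides are normalized to left-aligned
minimal representation (the classical trim-and-extend algorithm), which
removes VCF dialect differences for indels. Sensitivity is reported as a
nearest-integer percentage alongside the raw fraction; VAF concordance is
the product-moment correlation over detected variants, with zero-variance
inputs signalled as a distinct condition rather than returning `NaN`.

## Triaging panel-only variants

A deep consensus panel will call variants the original exome/genome
missed. `classify_rescued()` assigns each panel-only variant exactly one
category, testing in a fixed order (a variant can satisfy several tests;
the order encodes which explanation wins):

1. **germline** — in the matched normal, the variant allele sits in the
   heterozygous VAF window (default `[0.40, 0.60]`, inclusive) or at or
   above the homozygous threshold (0.90) with adequate normal depth.
   Diploid dosage clusters panel VAFs near 50%/100%, which is the
   signature this test captures. Without a matched normal the test is
   skipped;
2. **artifact** — the reference context within ±10 bp contains repeat
   structure touching the site: a mononucleotide run ≥ 5 (MN), a
   dinucleotide unit repeated ≥ 3 times (DN), or a 3–6 bp unit repeated
   ≥ 2 times (TR), with precedence MN > DN > TR and DN/TR units required
   to contain two distinct bases. These contexts dominate alignment and
   caller artifacts in practice; artifact classes needing read-level
   review (multiple mismatches/variants) are out of scope and fall
   through to later categories;
3. **no support in the original data** (`original_alt_count = 0`) — the
   exact binomial decides whether the original coverage could have been
   expected to show the variant:
   $$P(X \le k) = \sum_{i=0}^{k} \binom{n}{i} p^i (1-p)^{n-i},$$
   with $n$ the original depth, $p$ the observed panel VAF, and $k = 3$
   supporting reads. If $P(X \le k) > 0.95$ the original coverage was
   statistically **insufficient**; otherwise the variant had **adequate
   coverage** and is suspect. The sum is computed in log space
   (`lchoose`) for numerical stability at large $n$, with degenerate
   inputs ($n = 0$ or $p = 0$) returning 1. No multiple-testing
   correction is applied: the rule is a fixed per-variant 95% screen,
   not an inference procedure;
4. **supported in the original data** — at least one original
   variant-supporting read existed but the variant was not called
   (typically low VAF or caller filters).

Summaries report counts, one-decimal percentages of the classifiable
total, the insufficient-coverage share of the no-support class, and the
count of potentially clinically relevant somatic variants missed by the
original sequencing (all non-germline, non-artifact categories).

## Annotation reports

Calls annotate knowledgebase records only on exact five-key equality
(chromosome, start, stop, ref, alt) after identical allele normalization.
Fuzzy matching and container roll-up are deliberately absent — the cost of
a false clinical annotation outweighs a missed container association, and
duplicate snapshot keys are rejected at load time so a call can match at
most one record. Reports order variants by descending evidence score,
group evidence by type (Predictive, Prognostic, Diagnostic, Predisposing)
and template hyperlinks from record identifiers; JSON output validates
against a shipped structural schema.

## The synthetic validation cohort

`simulate_validation_cohort()` generates every pipeline input with no
downloads, deterministically from one seed:

* a single ~25 kb contig of uniform random base composition carrying 12
  genes with four 240 bp CDS exons each; windows around planted sites are
  re-drawn until repeat-free, and MN/DN/TR motifs are injected at
  designated artifact sites, so repeat-context expectations are exact;
* a snapshot with one eligible hotspot record per planted site plus
  archetypes covering every eligibility branch (score at/below the gate,
  non-DNA ontology, germline-only, conflicting, redundant container,
  eligible full-tiling container, sparse tiling, coordinate-free, and the
  250 bp boundary), with a truth table of expected decisions;
* tagged tumor and matched-normal reads: 500 families per site split
  across strands, mean 3 reads per family (1 + Poisson), 80 bp reads,
  1% independent per-base errors; each family carries the variant allele
  with probability equal to the site's VAF — 30 somatic sites with true
  VAFs uniform on [0.05, 0.6], plus heterozygous/homozygous germline
  plants (both samples) and artifact plants (tumor only);
* an "original sequencing" call set with engineered rescue regimes:
  validated sites draw negative-binomial depth (mean 120) with supporting
  reads conditioned above the calling floor; insufficient-coverage sites
  get 2–8× depth, zero support and low VAFs so the binomial decision sits
  far from its 0.95 boundary; adequate-coverage sites get 3000–6000×
  depth with support *forced* to zero — a constructed scenario, since a
  genuinely somatic variant essentially never leaves zero reads at that
  depth, but exactly the situation the adequate-coverage category exists
  to flag; supported sites carry 1–3 reads.

These sizes keep the full simulation-plus-pipeline run around a minute on
one CPU while leaving wide statistical margins: with 500 molecules per
site the binomial sampling error of a called VAF is ≤ 0.023, so the suite's
requirements (sensitivity ≥ 95%, true-vs-called VAF correlation ≥ 0.95,
≥ 95% rescue-category recovery) are comfortably away from chance failure.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: FFPE and oxidative base damage, context-
dependent sequencing error, probe-arm capture thermodynamics and
efficiency dropout, alignment around indels (reads are planted gapless),
tumor purity and subclonality, copy-number alterations, and multi-sample
batch structure (the preset is a single tumor/normal pair; batch QC is
exercised on constructed per-sample totals instead).

## Numerical choices and degenerate inputs

* Binomial tail: log-space term summation; agreement with brute-force
  outcome enumeration (n ≤ 12) and with the distribution function is
  test-enforced.
* Consensus ties produce `N`, never an arbitrary winner; read order never
  affects pileups.
* Interval merging uses reduce semantics with `min.gapwidth = 1` so
  bookended targets coalesce.
* Chromosomes sort naturally (1…22, X, Y, MT) in all outputs.
* Zero-variance correlation inputs raise a classed condition
  (`panelmips_zero_variance`); comparisons report `NA` rather than fail.
* Zero eligible truth variants leave sensitivity undefined (`NA`), not 0.
* Windows at contig ends are truncated, not errors.

## Known limitations

The caller is SNV-only (indel and copy-number calling are out of scope;
indel *normalization* is implemented for matching external call sets).
Rescue classification trusts the supplied original depth/alt table; it
does not re-examine original alignments. Annotation is exact-match only.
The evidence-score weights reproduce a convention, not a ground truth —
any gate defined on them should be reported together with the weights
used.
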