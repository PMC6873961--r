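# panelmips

Design clinically driven targeted cancer capture panels from a
knowledgebase snapshot, and analyze the single-molecule molecular
inversion probe (smMIP) sequencing data they produce.

Precision-oncology panels face a moving target: the set of variants worth
capturing changes as fast as the clinical literature. panelmips is for
groups who want their panel content *derived*, reproducibly, from a
community-curated clinical variant knowledgebase (CIViC-style snapshots),
and who sequence with molecular-tagged capture chemistry that supports
single-molecule consensus. It covers the whole loop:

1. **Select** — score each knowledgebase variant by its curated evidence,
   `S(v) = Σ w_level · stars` (defaults A=10, B=5, C=1, D=0.5, E=0.25),
   keep variants with `S > 20` that are DNA-detectable, and drop
   germline-only, directly conflicting, and redundant container records.
2. **Design** — hotspot-target variants shorter than 250 bp; sparsely or
   fully tile protein-coding exons for longer ones; merge everything into
   a BED of non-overlapping targets.
3. **Collapse** — group reads by (probe, UMI, strand) into single-molecule
   families and call a strict-majority consensus per position, yielding
   unique-molecule pileups with built-in error correction.
4. **Call & validate** — emit SNVs with consensus VAFs, compare against
   orthogonal exome/genome truth (sensitivity, Pearson VAF concordance).
5. **Triage panel-only variants** — germline (matched-normal VAF at
   50%/100%), repeat-context artifact (MN/DN/TR), or no original support,
   where the exact binomial `P(X ≤ k) = Σ_{i≤k} C(n,i) p^i (1−p)^{n−i}`
   (k = 3, n = original depth, p = panel VAF) decides whether the original
   coverage was statistically insufficient (`P > 0.95`) to have seen the
   variant at all.
6. **Annotate** — match calls back to the knowledgebase by exact
   chromosome/start/stop/ref/alt and render per-sample clinical reports
   (Markdown + JSON) with evidence items, assertions and links.

A seed-deterministic synthetic cohort generator
(`simulate_validation_cohort()`) produces every input — snapshot,
reference + gene models, tagged tumor/normal reads with planted variants,
truth and original-sequencing call sets — so the entire pipeline is
testable offline.

## Worked example

```r
library(panelmips)

sim <- simulate_validation_cohort(sim_config(seed = 42))
res <- run_validation_pipeline(sim)

sim$snapshot
#> civic_snapshot: 51 variants (1 coordinate-free), 100 evidence items

panel_summary(sim$regions, eligible_variants(sim$filtered))
#> panel: 44 variants (hotspot 42, sparse_tiling 1, full_tiling 1), 1242 bp
#> evidence items: Predictive 46 (52%), Prognostic 14 (16%), Diagnostic 14 (16%), Predisposing 14 (16%)

res$comparison
#> comparison: 30/30 truth variants detected (100% sensitivity), VAF r = 0.996

res$rescue_summary
#> rescued variants: 22 classified (0 unresolvable)
#>   germline        6 (27.3%)
#>   artifact        6 (27.3%)
#>   no_support      8 (36.4%)
#>   supported       2 (9.1%)
#>   no-support with insufficient original coverage: 6 (75%)
#>   clinically relevant missed by original sequencing: 10

binomial_detectability(100, 0.10)
#> [1] 0.007836487   # 100x original coverage at 10% VAF: adequate to detect
```

Reading the output: all 30 planted somatic SNVs were recovered with
closely concordant VAFs; of the 22 variants only the panel called, the
classifier recovered each engineered explanation — 6 germline plants, 6
repeat-context artifacts, 8 sites the original sequencing could not
support (6 of them with statistically insufficient coverage), and 2 with
marginal original support. The binomial value is the probability of seeing
at most 3 supporting reads at 100× and 10% VAF; being far below 0.95, such
a site would count as *adequately* covered, so a zero-support variant
there is suspect rather than excused.

The same steps are scriptable from a shell via the thin CLI in
`inst/cli/panelmips.R` (`simulate`, `design-panel`, `consensus`, `call`,
`compare`, `rescue`, `annotate`).

## Snapshot schema

`load_snapshot()` expects a top-level `"variants"` array; each record
carries `coordinates` (`chromosome`, `start`, `stop`, `reference_bases`,
`variant_bases`, `reference_build`; 1-based, fully closed),
`variant_types` (sequence-ontology accessions) and `evidence_items`
(`evidence_type`, `evidence_level`, `trust_rating`, `direction`,
`clinical_significance`, `variant_origin`, `disease`, `drugs`, `status`,
`citation`, optional cited `variant_coordinates`). Users exporting from a
live knowledgebase API should flatten their export to this shape —
`write_snapshot()` shows the exact field mapping, and the generator's
`snapshot.json` output is a complete example.

## Scope

Probe-arm design/synthesis chemistry, read alignment, duplex (strand-pair)
error modeling, indel/CNV calling, and live knowledgebase API access are
out of scope; inputs are a snapshot JSON, GTF/FASTA, aligned tagged reads
(TSV dialect or SAM/BAM), and VCFs.
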