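# kinduce

Kinetic transcriptome analysis of *Trichoderma reesei* cellulase-producer
strains under lactose fed-batch induction.

Industrial cellulase production decouples growth from enzyme synthesis: a
glucose batch phase is followed by a limiting lactose feed that induces
the cellulolytic regulon at near-zero growth. Comparing a moderate
producer (NG14) with the hyper-producer derived from it (RUTC30) over the
first 24 h of induction — and cross-referencing the regulated genes with
mutation catalogues — separates induction-related genes from
productivity-related ones. `kinduce` implements that analysis as a
tested, reusable R pipeline for anyone working with two-channel
time-course arrays, strain-comparison RNA-seq counts and mutation
catalogues in filamentous fungi.

## What the pipeline computes

* **Microarray preprocessing** — global lowess normalization of M on A per
  hybridization (no background subtraction); detectability against a
  background threshold (mean of "not found" features + 2 SD, both channels
  above); transcript log2 ratios as the mean of detectable in-CDS
  matching-strand probes, with dye-swap orientation correction.
* **Differential expression** — per-contrast replicate means with
  empirical-Bayes moderated variances,
  t = lfc / sqrt(s2_post / n) on d0 + d df with
  s2_post = (d0 s0² + d s²)/(d0 + d); Benjamini–Hochberg FDR within each
  strain × time contrast; regulated ⇔ FDR ≤ 0.05 and |log2 FC| > 1;
  strain-specific/shared partition of the regulated union.
* **Consensus clustering** — K from the average-linkage dendrogram's
  largest relative merge-height gap; five seeded K-means runs; pairwise
  co-occurrence aggregation cut at a 60% threshold, with unclustered
  genes; per-cluster mean profiles and up/down directions.
* **Basal comparison** — RPKM = reads × 10⁹ / (exon length × total mapped
  reads); flag genes with |log2 RPKM ratio| ≥ 4 and average reads > 100;
  per-cluster higher/lower/equal distributions; an audit mode that
  re-applies the rule to published tables and reports violations.
* **Mutation integration** — assign mutations to genes within 800 bp of
  the coding span (GenomicRanges-backed, oracle-tested), classify
  promoter/exon/intron/terminator strand-aware, intersect with regulated
  genes, tabulate by cluster and lineage.
* **Functional categories** — main categories (> 10 genes), category ×
  cluster counts with integer percentages and a 2-gene emphasis rule.
* **Bioprocess metrics** — specific productivity
  q = 1000 ΔP / (mean biomass × Δt) in mg/g_cell/h, the 3.5–5× Bradford→
  Lowry correction range, and the ≥ 0.90 carbon-balance check.
* **Synthetic data** — a seeded generator for every input (gene models,
  probe tables, counts, mutations, category labels, cultivation series)
  with ground truth, used by all recovery tests.

## Worked example

```r
library(kinduce)

run <- run_pipeline("demo_out", syn_config = synthetic_config(seed = 42),
                    seed = 1)
print(run)
#> Pipeline run -> demo_out
#>   stages run: preprocess, de, cluster, basal, mutations, funcat, metrics
#>   cluster ARI: 1

print(run$results$de$venn)
#> Regulated gene sets:
#>   NG14-specific: 322
#>   RUTC30-specific: 113
#>   shared: 115
#>   total: 550

run$results$metrics[c("q_bradford", "q_lowry_low", "q_lowry_high")]
#> $q_bradford
#> [1] 4
#> $q_lowry_low
#> [1] 14
#> $q_lowry_high
#> [1] 20
```

The manifest (`demo_out/manifest.json`) records the configuration
snapshot, input/output digests, per-stage record counts and — in synthetic
mode — recovery against ground truth: here all 550 truly regulated genes
are recovered, the consensus clustering matches the 9 generating
archetypes (adjusted Rand index 1), every mutation maps back to its true
target gene, and the constant-productivity cultivation series inverts to
its generating q = 4 mg/g_cell/h, i.e. a corrected Lowry-equivalent range
of 14–20 mg/g_cell/h.

Single stages are available as plain functions (`preprocess_probes()`,
`de_analysis()`, `consensus_cluster()`, `basal_compare()`,
`window_assign()`, ...), and `inst/scripts/kinduce` is a thin command-line
front end with one subcommand per stage.

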