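# evonet

Comparative analysis of gene evolutionary provenance versus
protein-interaction-network properties, for systems biologists studying how
gene duplicability and network centrality co-evolved.

In several species — microbes, yeast, fly — highly connected ("hub")
proteins are encoded by single-copy genes whose duplication is selected
against; in human, many hubs are duplicated. `evonet` implements the full
analysis needed to ask *when* that changed:

1. **Provenance** — every gene of a focal species is assigned an
   *origin* (the most ancient of seven tree-of-life nodes — LUCA,
   eukaryotes, opisthokonts, metazoans, vertebrates, mammals,
   group-specific — where an ortholog is found), a *conservation* score
   (the number of internal nodes between origin and the group-specific node
   with no ortholog: 0 = fully retained, 5 = maximal loss), and a
   *duplicability* class (duplicated iff its reference-level ortholog
   cluster, KOG/COG, holds ≥ 2 focal-species genes).
2. **Interactome** — multi-source interaction evidence is integrated into a
   simple undirected graph (orthology-inferred records and self-loops
   dropped, parallel evidence merged); experiments reporting < 100
   interactions are *single-gene* studies, the rest *high-throughput*; a
   *gold set* keeps edges with single-gene support or ≥ 2 independent
   screenings. Per-protein degree and unnormalized betweenness are
   computed; *hubs* are the top 25% most connected proteins; the degree
   tail is checked against a power law (log–log interpolation above
   degree 10 plus a Kolmogorov–Smirnov fit test).
3. **Statistics** — each origin/conservation stratum is compared with all
   younger/older (less/more conserved) genes by two-sided Wilcoxon rank-sum
   tests and by a subset-resampling statistic: repeatedly draw
   min(500, n) genes per side without replacement and record the tail
   fractions z_low = P(D < 0), z_high = P(D > 0) of the difference of
   subset means over (by default) 10,000–100,000 repetitions. Duplicated
   and singleton genes of the same age are compared the same way. Results
   render as red/green/black heatmap matrices with p-values floored at
   10⁻³.
4. **Annotation** — GO level-5/6 Fisher enrichment with Benjamini–Hochberg
   FDR between gene classes; dosage-regulation overlap of duplicated versus
   singleton hubs with ohnologs (reconciled against duplicability), miRNA
   targets, and tissue-selective genes (expressed in < 25% of tissues);
   origin profiles of gene subsets; cross-network conservation of ancient
   singleton hubs.
5. **Synthetic data** — a generator that emits every input file with
   planted ground truth (origin/conservation/duplicability, an age–degree
   coupling, a within-stratum duplicability contrast, GO category skews,
   dosage-annotation enrichments) and a JSON manifest, enabling exact
   round-trip and calibration tests.

All inputs are simple TSV dialects (`clusters.tsv`, `species_nodes.tsv`,
`interactions.tsv`, `go_dag.tsv`, …) documented in the function help pages;
converting native database dumps into them is out of scope.

## Worked example

Generate a human-like synthetic study and run the core analysis:

```r
library(evonet)

cfg <- sim_config(seed = 42, n_genes = 2000)   # human-like defaults
sim <- simulate_all(cfg, "sim")

ladder  <- build_ladder(read_species_nodes("sim/species_nodes.tsv"), "hsap")
prov    <- annotate_genes(read_gene_list("sim/gene_list.txt"),
                          read_clusters("sim/clusters.tsv"), ladder, "KOG")
#> annotate_genes: 2000 genes; excluded downstream: 10 untraceable, 8 without KOG cluster

net <- classify_experiment_scale(
  integrate_evidence(read_interactions("sim/interactions.tsv")))
net
#> Interactome: 1189 proteins, 4757 interactions, 6555 evidence records
#>   evidence scale classes assigned (threshold 100)

metrics <- compute_metrics(net)
hubs <- call_hubs(metrics)                     # threshold 8 -> 283 hubs (23.8%)
fit_power_law(metrics)
#> Power-law tail fit (degree > 10, n = 213): gamma = 2.36 +/- 0.26, KS p = 0.025

cc <- compare_strata(prov, metrics, "origin")
head(build_heatmap(cc), 8)
#>   stratum        label    side      metric value color
#> 1       0         LUCA younger      degree 0.001   red
#> 2       0         LUCA younger betweenness 0.001   red
#> 3       1   eukaryotes younger      degree 0.001   red
#> 4       1   eukaryotes   older      degree 0.001 green
#> 5       1   eukaryotes younger betweenness 0.001   red
#> 6       1   eukaryotes   older betweenness 0.001 green
#> 7       2 opisthokonts younger      degree 0.001   red
#> 8       2 opisthokonts   older      degree 0.001 green
```

Reading the heatmap: each stratum's proteins are *more* connected and
central than younger proteins (red versus the younger pool) and *less* than
older proteins (green versus the older pool) — the planted age–degree
coupling, recovered at p ≤ 10⁻³ (the display floor). The excluded genes are
the 10 with no traceable origin and the 8 without a reference-level
cluster, mirroring the exclusion rules of the analysis.

`run_all(run_config(...))` (or the `inst/scripts/evonet.R` CLI with a YAML
config) chains all stages — provenance, network, comparisons with
randomization z, enrichment, dosage overlap — and writes
`provenance.tsv`, `node_metrics.tsv`, `comparisons.tsv`, `heatmap.tsv`,
`enrichment.tsv`, `dosage_overlap.tsv`, and a run log, each with its
generating parameters as `#` header comments; a rerun with the same seed is
byte-identical.

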