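# stratomics

Driver-mutation-stratified integrative multi-omics analysis for tumor
cohorts, in R.

Many cancer driver genes — *PBRM1* in clear cell renal cell carcinoma is
the motivating example — act as tumor suppressors through *truncating*
somatic mutations (nonsense, splice-site, frameshift). To see what such
mutations do downstream, one compares tumors carrying them against
"pan-negative" tumors that carry neither the target-gene mutation nor any
mutation in a panel of co-driver genes (for ccRCC: *VHL*, *BAP1*, *SETD2*,
*PTEN*, *KDM5C*), so that the molecular contrast is attributable to the one
driver. `stratomics` implements that whole design as a reusable, tested
pipeline:

1. **Cohort stratification** — classify variants from a MAF-like table,
   define cases (≥1 truncating target-gene variant, no co-driver mutation)
   and pan-negative controls, and restrict to samples with complete
   RNA-Seq, methylation and miRNA-Seq data.
2. **Differential expression** (mRNA and miRNA counts) — CPM filtering
   (cpm > 1 in ≥2 samples), TMM normalization, common NB dispersion by
   conditional maximum likelihood, and a conditional negative-binomial
   exact test. For feature counts *y* with group sums *(a, b)* conditional
   on *t = a + b*, the two-sided p-value sums the probabilities of all
   splits no more likely than the observed one. Calls use |log2FC| > 1,
   p < 0.05.
3. **Differential methylation** (450K-style β-values) — probe filtering
   (sex chromosomes, SNP within 5 bp, no gene annotation), per-probe
   β-difference (case mean − control mean), a SAM-style moderated statistic
   d = (mean difference)/(s + s₀) with permutation p-values, calls at
   |β-difference| > 0.15, p < 0.01, and a region-distribution comparison of
   hyper vs hypo probes.
4. **Integration** — miRNA-target overlaps (four-set Venn of DEG-up,
   DEG-down, up-miRNA targets, down-miRNA targets) and **hyper-down genes**
   (down-regulated ∩ hyper-methylated).
5. **Enrichment** — hypergeometric over-representation of every result
   family against a GMT catalog, Benjamini–Hochberg adjusted, retained at
   padj < 0.05.
6. **Networks** — Pearson correlations among expressed genes in the *case*
   group, top 5 % by |r| intersected with a reference PPI (the
   mutation-specific background network), projection of DE gene sets plus
   their regulating miRNAs, the hyper-down **core network** (seeds + first
   neighbors), and a display degree filter (≥3).

A synthetic multi-omics generator (`sim_config()`, `simulate_multiomics()`)
emulates all inputs with planted effects and a recorded ground truth, so
the pipeline is validated end to end at desk scale: 11 cases vs 33
controls, planted |log2FC| = 2, planted Δβ = 0.3, NB dispersion 0.1.

## Worked example

```r
library(stratomics)

bundle <- simulate_multiomics(sim_config(seed = 7))
dir <- tempfile(); write_bundle(bundle, dir)

cfg <- pipeline_config(
  maf = file.path(dir, "mutations.tsv"),
  samples = file.path(dir, "samples.txt"),
  mrna = file.path(dir, "mrna_counts.tsv"),
  mirna = file.path(dir, "mirna_counts.tsv"),
  beta = file.path(dir, "beta.tsv"),
  anno = file.path(dir, "probe_anno.tsv"),
  targets = file.path(dir, "targets.tsv"),
  gmt = file.path(dir, "genesets.gmt"),
  ppi = file.path(dir, "ppi.tsv"),
  tfs = file.path(dir, "tf_list.txt"),
  outdir = file.path(dir, "out"),
  n_perm = 1000, seed = 1)

report <- run_pipeline(cfg)
report
#> Pipeline run 220850b2dab3be1241328eca187fb879
#>   cohort: 11 cases / 33 controls
#>   mRNA DE: 40 up / 160 down (phi = 0.101)
#>   methylation: 180 hyper / 20 hypo probes -> 176 / 19 genes
#>   miRNA DE: 20 up / 20 down
#>   hyper-down genes: 30 (miRNA targets: 23 )
#>   background network: 382 nodes / 271 edges
```

The report says: stratification recovered the 11 planted truncating-mutation
cases and 33 pan-negative controls; the exact test called all 200 planted DE
genes (40 up, 160 down) at an estimated dispersion of 0.101 (truth: 0.1);
methylation analysis recovered the 200 planted probes (180 hyper / 20 hypo);
30 genes are both hyper-methylated and down-regulated (the planted
hyper-down overlap); and the background network is the top-5 % co-expression
∩ PPI intersection, containing the planted 12-gene clique. All intermediate
tables are written under `outdir` with the configuration hash in their
header.

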