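---
title: "Stratified multi-omics analysis of truncating driver mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified multi-omics analysis of truncating driver mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratomics)
```

## The analytical design

`stratomics` compares tumors carrying truncating mutations in a single
driver gene against "pan-negative" tumors carrying neither that mutation
nor any mutation in a panel of co-occurring driver genes. The rationale is
noise reduction: driver mutations often hit overlapping pathways, so a
control group contaminated with other drivers dilutes or distorts the
molecular contrast. The cost is sample size — in the motivating ccRCC
setting the design leaves 11 cases and 33 controls with complete
mutation, mRNA, methylation and miRNA data, which is why every statistical
engine in the package is built for small unbalanced groups.

Stratification itself is rule-based. A sample is a **case** if it has at
least one target-gene variant in the truncating classes and no
exclusion-gene variant; a **control** if it has neither target-gene nor
exclusion-gene variants; everything else is excluded with a recorded
reason. Two rules deserve comment:

* The default truncating set is {nonsense, frameshift deletion, frameshift
  insertion, splice site}. Only the first, second and fourth classes were
  observed in the motivating cohort; frameshift insertions are included by
  the same loss-of-function rationale and can be dropped from
  `cohort_design()`.
* Samples whose only target-gene variants are non-truncating (e.g.
  missense) are excluded from *both* groups rather than used as controls.
  Controls should be target-negative in every sense; a missense carrier is
  neither a clean case nor a clean control.

Sample ids are opaque strings compared after whitespace trimming;
platform-specific barcode conventions are deliberately not interpreted.

## Differential expression: a conditional NB exact test

Counts are modeled as negative binomial with a **common dispersion**
$\phi$ across features. The pipeline is: strict CPM filter (cpm > 1 in at
least two samples of the combined case+control matrix, all-zero features
always dropped; a per-group variant is available), TMM normalization
(trimmed mean of M-values, 30 % trim on M and 5 % on A, plain unweighted
trimmed mean, factors rescaled to geometric mean 1), dispersion estimation
by maximizing the conditional (Dirichlet-multinomial) likelihood of the
counts given per-feature group totals, and a per-feature exact test.

For the exact test, counts are first *equalized*: each sample's counts are
mean-scaled to the geometric-mean effective library and rounded (banker's
rounding). This is a documented simplification of quantile-based
equalization; at the library-size spread the generator produces (less than
two-fold) the difference is negligible, and it keeps the conditional
argument exact. Given equalized group sums $(a, b)$ with total $t$, the
two-sided p-value sums $P(x \mid t)$ over all splits $x$ with
$P(x \mid t) \le P(a \mid t)$ — probability ordering, which handles the
strong asymmetry of small unbalanced groups better than tail doubling
(offered as an option). At $\phi = 0$ the conditional law is exactly
binomial$(t,\, n_1/(n_1+n_2))$, which the test suite exploits as an
independent oracle by full enumeration of all totals up to 30.

Fold changes are $\log_2$ ratios of group mean CPM with a prior of 0.5 CPM
on both sides (settable to 0). Calls use the published cutoffs —
|log2FC| > 1 and **raw** p < 0.05, strict inequalities — with BH-adjusted
p-values always reported alongside; this mirrors the original analysis
convention rather than endorsing raw-p thresholds.

The dispersion search runs on $[0, 10]$ with Brent's method (tolerance
$10^{-6}$) plus an explicit boundary comparison at $\phi = 0$, since the
Poisson limit is a boundary maximum the interior search cannot land on
exactly.

## Differential methylation: SAM-style statistic with permutation nulls

β-values live in [0, 1] and are heteroskedastic (variance
$\approx \mu(1-\mu)/(1+\text{precision})$), so the package uses a
moderated two-class statistic rather than a count model:
$d = (\bar\beta_{case} - \bar\beta_{ctrl}) / (s + s_0)$ with $s$ the
pooled standard error and $s_0$ an exchangeability constant damping
low-variance probes. $s_0$ defaults to the **median** of all per-probe
$s$ values — a documented simplification of the coefficient-of-variation
minimization used by the original SAM procedure; `sam_statistic(s0 = )`
is the hook for plugging in any other rule.

Significance comes from label permutations applied jointly across probes,
with $s_0$ refit in every permutation so the null statistic sees the same
estimation noise as the observed one. Two-sided p-values use the
add-one-correct estimator $(1 + \#\{|d^\ast| \ge |d|\})/(1 + B)$; when
$\binom{n}{n_1} \le B$ the package switches to full enumeration and drops
the correction, making p-values exact for small cohorts (asserted against
brute force in the tests). With the default 1000 permutations the smallest
attainable p is $1/1001$, comfortably below the 0.01 call threshold.

Probe filtering follows array practice: sex-chromosome probes (sex-biased
cohort composition), probes with a SNP within 5 bp of the CpG (genotype
artifacts), and probes with no gene annotation are removed. Calls use
|β-difference| > 0.15 and p < 0.01 (the Methods-stated thresholds; a
conflicting p < 0.05 appears once in the motivating paper's Results and is
treated as a typo — both are configurable). Gene-level sets are unions over
called probes, with multi-gene annotations split on ";". The
region-distribution comparison is a plain two-proportion z-test per region
label, BH-adjusted, with z defined as 0 when the pooled proportion is
degenerate.

## Integration, enrichment, networks

Integration is set algebra and is tested against brute-force enumeration.
One semantic choice matters: miRNA target sets are intersected with the
**expressed-gene universe** (features surviving the CPM filter) before any
overlap, so Venn counts refer to the analyzed gene space; `targets_of()`
takes `universe = NULL` to disable this. Hyper-down miRNA targets use
targets of either miRNA direction, with per-direction breakdowns reported,
since "targets of the DE miRNAs" is ambiguous about direction.

Enrichment is upper-tail hypergeometric with BH adjustment, replacing the
two-sided test plus kappa-score term clustering of interactive tools like
ClueGO — a deliberate semantic substitution documented here; adjusted
p < 0.05 retention is kept. The universe defaults to the catalog's, and
the pipeline passes the expressed-gene universe. BH is computed across all
catalog terms represented in the universe (including zero-overlap terms,
which carry p = 1); only overlapping terms are returned as rows.

Networks: Pearson correlations are computed among filtered genes on
log2(CPM + 1) of **case samples only** — the network is meant to describe
co-regulation inside the mutated group; log-CPM is chosen for variance
stabilization (the transformation is not fixed by the design). The top 5 %
of pairs by |r| (signed mode available; |r| is the default because
miRNA-mediated relations can be negative) are intersected with the PPI to
form the background network. Subnetworks are induced subgraphs plus miRNA
nodes attached to their retained targets; the core network is the closed
first neighborhood of the hyper-down seeds; the degree-3 filter is a
single-pass display filter (degrees computed once on the input), not a
k-core — an iterative mode exists for users who want the latter.

## The synthetic generator: what it emulates and what it does not

The generator plants known signal into every layer under one global seed,
expanded into per-layer substreams so adding a layer never perturbs the
others. Its defaults are the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| n_case / n_control / n_other | 11 / 33 / 6 | the stratified cohort of the motivating design |
| n_genes / n_probes / n_mirnas | 2000 / 4000 / 300 | desk-scale panels with realistic relative sizes |
| n_de_genes, effect_log2fc | 200, 2 | clear planted contrast, 10 % of features |
| frac_down | 0.8 | mirrors the observed down-skew (485/613) |
| n_dm_probes, delta_beta, frac_hyper | 200, 0.3, 0.9 | mirrors the observed hyper-skew (94 %) |
| nb_dispersion | 0.1 | typical bulk RNA-Seq biological CV ≈ 0.3 |
| beta_precision | 50 | β-value SD ≈ 0.06 at mid-methylation |
| lib_size_range | 5×10⁵–10⁶ | modest library-size spread |
| module_size, module_cor_sd | 12, 1.5 | clique recoverable from 11 samples at top-5 % |

Counts are NB with library-size scaling of log-normal baseline
abundances; fold changes multiply case means, so expected column sums in
the case group drift by a few percent — intentional, as renormalizing
would silently shrink planted fold changes. β-values are drawn directly
from beta distributions with a bimodal baseline; intensity-level (M/U)
simulation is out of scope, so array artifacts such as probe-type bias do
not exist here. The co-expression module is driven by a shared log-normal
latent factor on case samples, mean-corrected so module genes are not
spuriously DE; setting `module_cor_sd = 0` (together with zero effect
sizes) yields a fully null cohort for calibration runs. Planted methylation
probes always receive a clean, filter-surviving annotation, and a block of
planted hyper probes is assigned to planted down-regulated genes so a
hyper-down overlap exists by construction.

What passing tests on this generator do **not** show: robustness to
tagwise dispersion heterogeneity, batch effects, normalization-breaking
global shifts, annotation errors, or the much larger multiplicity of real
platforms (480 k probes, 20 k genes). The validation demonstrates that the
engines are correct and calibrated under their own model assumptions at
the design's sample sizes — not that the assumptions hold on any given
dataset.

## Numerical and degenerate-input conventions

* Strict inequalities at every call threshold; features exactly at a
  cutoff are not called.
* Probability-ordering ties in the exact test are resolved with a
  $1 + 10^{-12}$ relative tolerance so floating-point noise cannot split
  exactly tied tail outcomes.
* All-zero count matrices yield $\hat\phi = 0$ with a warning; zero-library
  samples are an input error.
* Probes with fewer than two observed values per group are dropped from
  β-differences with a warning; an all-zero-SE matrix falls back to a
  machine-epsilon $s_0$.
* Empty network intersections and seedless cores return empty networks
  with warnings, not errors; empty case/control groups abort the pipeline
  with a typed input error naming the stage.
* Input errors (`stratomics_input_error`) and configuration errors
  (`stratomics_config_error`) are distinct condition classes throughout.

## Validation problem sizes

The shipped validation suite runs the null-calibration cohort at 5000
genes (11 vs 33 samples), dispersion recovery at 2000 features (20 vs 20),
methylation recovery on the default 4000-probe cohort with 1000
permutations, and enrichment null rates over 500 replicate queries; these
sizes give Monte-Carlo noise well inside the asserted bands while keeping
a full run in the low minutes on one core.

## Known limitations

* Common dispersion only; no tagwise shrinkage, trends, or GLM covariates.
* The TMM reference column follows the upper-quartile heuristic; extreme
  composition bias beyond what trimming absorbs is not handled.
* Exact-test equalization rounds scaled counts; with very small libraries
  (tens of counts) the rounding error is no longer negligible.
* Symbol matching is exact and case-sensitive everywhere; no alias
  resolution.
* The enrichment replacement is one-sided over-representation; depletion
  is not tested.
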