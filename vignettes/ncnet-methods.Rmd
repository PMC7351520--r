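---
title: "Models and design choices behind ncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind ncnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncnet)
```

## What the package computes

ncnet analyses non-coding RNA dysregulation in visceral adipocytes across
four subject groups — normal-weight controls (Nw), obese (Ob), and
colorectal-cancer patients who are lean (NwCRC) or obese (ObCRC) — with each
disease group contrasted against Nw. The pipeline has five stages:

1. **Differential expression** of small-RNA counts by a conditional exact
   negative-binomial (NB) test.
2. **Overlap analysis** of the differential lncRNA (DEL) and miRNA (DEM)
   gene sets across the three contrasts.
3. **Tripartite ceRNA network construction** from interaction evidence,
   restricted to differential molecules, with hub identification.
4. **Over-representation analysis** of the network's mRNA targets.
5. **qPCR validation** by 2^-ddCt relative quantification.

The package ships curated per-contrast DEL/DEM tables compiled from a
published visceral-adipocyte study (`load_del_tables()`,
`load_dem_tables()`), and seeded generators (`synth_config()`,
`simulate_*()`) that produce every other input with ground truth, so the
whole pipeline is testable offline.

## The exact NB test

For a feature with counts $y_{ij}$ in sample $j$ of group $i$, the model is
$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi)$ with
$\mathrm{Var}(y) = \mu + \phi\mu^2$ and a dispersion $\phi$ shared by all
features. The stage mirrors the classic exact-test workflow for small-RNA
counts:

* **Low-count filter**: keep features with at least `min_reads` (default 10)
  reads in at least one sample.
* **Upper-quartile normalisation**: per sample, the 0.75 quantile of counts
  (over features expressed somewhere) divided by library size, rescaled to
  geometric mean one. Dividing by these factors equalises upper quartiles,
  which is robust to the composition effects that dominate small-RNA
  libraries.
* **Library-size equalisation**: the conditional test requires equal
  library sizes, so counts are scaled to the geometric-mean effective
  library size and rounded half-to-even. The package is silent about
  fractional pseudo-counts by construction: everything downstream sees
  integers.
* **Common dispersion** is estimated by maximising the NB likelihood
  conditional on each feature's per-group total (the qCML idea), summed over
  features. The Poisson limit $\phi = 0$ is evaluated in closed form
  ($-z\log n$ per feature-group after dropping $\phi$-free terms) and
  included in the comparison, so equal-variance data return exactly zero.
  Common dispersion (no tagwise shrinkage) is deliberate: it is the minimal
  faithful setting for the exact test, and per-feature empirical-Bayes
  shrinkage is out of scope.
* **The test** conditions on a feature's total $z = z_A + z_B$: under the
  null the group-A sum follows the convolution of NB distributions, and the
  two-sided p-value sums the probabilities of all splits no more probable
  than the observed one (ties included, capped at one). At $\phi = 0$ this
  is exactly the two-sided binomial test, which the test suite checks by
  enumeration; at $\phi > 0$ the suite checks agreement with an independent
  implementation of the same small-p convention to machine precision.
* **Fold changes** use group mean rates with a prior count of 0.125 added
  to both numerator and denominator, so presence/absence features (common
  among lncRNAs, where published |log2FC| exceeds 20) stay finite.
* **BH adjustment** and boundary-inclusive calls: FDR <= 0.05 for lncRNAs,
  <= 0.06 for miRNAs, following the source study's thresholds.

## Overlap analysis

Contrast tables are collapsed to gene level before any counting: a gene is
"up" or "down" when all its transcripts agree in sign and "mixed" otherwise
(e.g. NUTM2A-AS1, whose two transcripts move in opposite directions in the
NwCRC contrast). Mixed genes count once, like any gene. The three-set Venn
partition is computed exactly by membership, keyed by contrast id in a
locale-independent order. The headline "shared by obesity and cancer"
statistic is the union of the DEL and DEM triple intersections; the two
namespaces never collide.

The shipped tables restore a handful of cells that the printed source table
dropped but whose membership the study's text states explicitly; signs were
confirmed from its narrative and magnitudes mirrored from the adjacent
contrast column. Only signs feed the downstream stages.

## Network construction

Three evidence layers are built per contrast, emulating the export formats
of the standard interaction databases:

* **miRNA-mRNA**: validated evidence only (TarBase/miRTarBase style);
  predicted rows are ignored.
* **lncRNA-miRNA**: union of verified evidence and predictions with score
  >= 0.6 (boundary inclusive); when a pair has both, the stored evidence is
  "validated".
* **lncRNA-mRNA**: verified evidence only (ENCORI style).

Every edge additionally requires both endpoints to be differential in the
contrast (the DET filter). The integrated graph is undirected; "degree" is
the incident-edge count across layers. Figure-style display filtering keeps
nodes by their *full-network* degree (the legend semantics of hiding
low-degree nodes, not recomputing degrees), which makes the filter
idempotent. Hubs default to degree >= 6 ("exceeding 5"); the display
threshold is a separate parameter because published figures use both >= 5
and >= 6. A gene appearing as both a miRNA target and a lncRNA target is a
single mRNA node with edges from both layers.

Published absolute network sizes are not reproducible targets: they depend
on database snapshots that are not shipped. The graph stages are instead
validated exactly against planted synthetic structure, including a
264-target high-degree lncRNA emulating the XIST pattern.

## Enrichment

Over-representation uses the hypergeometric distribution with a two-sided
p-value defined as the doubled smaller tail capped at one ("two-sided" is
the stated convention; the combination rule is ours and is documented).
Terms are intersected with the universe first; the universe defaults to the
contrast's differential transcripts — the minimal defensible background —
and is configurable. Significance is strict `p_adj < 0.05` after BH.
Redundant significant terms are grouped by Cohen's kappa >= 0.4 over their
binary overlap-membership vectors, taking connected components as groups
with the best-adjusted-p member as representative. Term fusion and ontology
levelling of GUI tools are intentionally not emulated; the statistical core
is the reproducible part.

## qPCR

Relative expression is 2^-ddCt per assay, with dCt centred on the
*control-group mean* rather than a single calibrator sample — this matches
presentation "normalised to the lean control" and makes the control group's
geometric-mean fold exactly one. Group comparison is one-way ANOVA with
Fisher's LSD post hoc (pooled within-group mean square, unadjusted pairwise
p against the control, unbalanced groups supported since one cohort has
n = 5). The ANOVA response defaults to ddCt (the log2 scale, where Ct noise
is closest to additive), with the fold scale available. Cross-platform
concordance uses Spearman's rho on mid-ranks, with an exact permutation
p-value for n <= 8 and the t approximation otherwise.

## The synthetic-data generator

The generator is first-class, tested code whose defaults encode the study
conditions: four groups of six replicates; miRNA |log2FC| drawn from
[0.48, 1.56], the span of the published differential-miRNA table; lncRNAs
with a separate regime including on/off features that are absent on one
side of their contrast; NB dispersion 0.15; per-sample depth multipliers in
[0.7, 1.3]. The per-sample assigned-read total defaults to 5e5: the study
reports raw sequencing depth above 10M reads, but the count matrix holds
only reads assigned to miRNAs, for which a few hundred thousand is
realistic. Interaction evidence is generated with planted hubs, a planted
264-target lncRNA, decoy rows that fail exactly one filter each, and
prediction scores spanning the cutoff. Every generator is a pure function
of its configuration; stage streams derive from the master seed by fixed
offsets.

What the generator does *not* emulate: correlated features,
sequence-content effects, tagwise dispersion, annotation error, and the
specific content of real interaction databases. Green tests therefore
demonstrate that the implementation is correct under its stated model, not
that the model captures every property of real adipocyte libraries.

## Numerical choices and problem sizes

* Two-sided exact p-values include ties via a 1e-10 log-scale tolerance and
  are capped at one.
* The dispersion search runs on [1e-4, 5] with the analytic $\phi = 0$
  limit compared explicitly.
* Calibration checks use 1,000 features, 6 vs 6 samples, dispersion 0.15,
  with medians over 10-20 seeds; graph recovery uses the default planted
  configuration over 5-20 seeds; the qPCR null calibration uses 200 seeds.
  These sizes give stable medians while keeping the full suite fast.
* Kappa on two constant identical vectors is 1 (0 when constant but
  different); degenerate zero-variance ANOVA returns F = 0, p = 1 when
  means agree.

## Known limitations

* Long-RNA quantification is out of scope; curated DEL/DET tables stand in
  for that side of the pipeline.
* No GLM/quasi-likelihood DE modes and no tagwise dispersion.
* No live database clients; evidence arrives as files.
* No amplification-efficiency correction in the qPCR stage (pure 2^-ddCt).
* Venn analysis is fixed at three sets, the study's design.
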