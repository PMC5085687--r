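---
title: "Methods: phenotype-genotype screening with the differential index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-genotype screening with the differential index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogeno)
```

## The problem

Rare tumors studied through surgical series produce a characteristic data
shape: a large clinical table (a hundred or more patients, dozens of
measured characteristics with substantial missingness) next to a very small
paired expression cohort (tumor and adjacent non-tumorous tissue from the
same patient, often fewer than ten pairs). `phenogeno` implements a screen
that links the two: which clinical phenotypes move together, which genes are
robustly differentially expressed within pairs, which of those genes track a
clinical parameter across patients, and whether the tracked genes form a
connected module in a protein-interaction network.

## The differential index

For a gene and pair $i$, with pseudocount $c$,
$r_i = (t_i + c) / (a_i + c)$ is the tumor/ANPT ratio,
$\mathrm{fold}_i = \max(r_i, 1/r_i) \ge 1$, and the signed normalised value
is $v_i = \mathrm{sign}(r_i - 1)\,(1 - 1/\mathrm{fold}_i) \in (-1, 1)$.
The differential index is the average over the $n$ pairs, and the adjusted
fold change maps it back to a fold scale:

$$\mathrm{DI} = (\pm)\frac{\sum_{i=1}^n (1 - 1/\mathrm{fold}_i)}{n},
\qquad \mathrm{FC} = \frac{1}{1 - |\mathrm{DI}|}.$$

$\mathrm{DI} = 0.6$ corresponds to $\mathrm{FC} = 2.5$; the two transforms
are exact inverses, which the tests assert without tolerance.

**Two aggregation modes.** The formula above leaves the placement of the
sign ambiguous when pairs disagree. The *literal* mode averages the unsigned
values $1 - 1/\mathrm{fold}_i$ and affixes a single sign (the sign of the
summed log-ratios, with an exactly balanced gene reported as DI = 0); this
inflates $|\mathrm{DI}|$ for genes whose pairs move in opposite directions.
The default *signed* mode averages the $v_i$ themselves so that conflicting
pairs cancel. Both modes agree exactly whenever all pairs move one way (the
common case for a true DE gene); the signed mode is the conservative default
and the mode used is recorded in the output metadata. Which aggregation the
original DI-based analyses used cannot be determined from published
descriptions; exposing both makes the choice explicit.

**Coverage.** A DE call additionally requires the change to be seen in
enough individual patients. "Covers a patient" is made operational as: the
pair's direction matches the sign of DI and its normalised fold strictly
exceeds $\tau$ (default $\tau = 0.6$, i.e. per-pair fold > 2.5). The default
minimum coverage is $\lceil 2n/3 \rceil$ — six patients at $n = 9$ — scaling
the customary "six of nine" rule to other cohort sizes. Tie pairs
($r_i = 1$) contribute $v_i = 0$ and are never covered. All threshold
comparisons are strict (`>`), matching the convention "DI > 0.6", "FPKM > 0".

**Pseudocount.** The ratio is undefined when the denominator is zero, and
FPKM values of zero are common. A pseudocount $c = 0.1$ FPKM added to both
members of every pair keeps every ratio defined while leaving genes with
moderate expression essentially untouched. The side effect is a detection
floor: a gene whose control expression is below roughly $0.4$ FPKM cannot
reach an observed fold of 2.5 even when its true fold is 4. This is a
faithful property of the statistic, visible in the recovery tests as the
small set of planted genes that are never called.

## Clinical statistics

*Spearman screen.* Every unordered phenotype pair is correlated on
pairwise-complete patients. Pairs with fewer than `min_pairs` (default 5)
complete observations are reported as untested (missing coefficient), not as
non-significant, and are excluded from the multiple-testing family. P-values
use the exact null distribution for $n < 10$ without ties and the
$t$-approximation otherwise; the Benjamini–Hochberg adjustment is applied
once per screen invocation, and the significance mask marks pairs with
$q < \alpha$ (default 0.05). Binary phenotypes take part only when listed
explicitly: rank correlations of 0/1 variables are point-biserial in
disguise and are better handled by the group-comparison tests.

*Group comparisons.* Continuous phenotypes use the two-sided Mann–Whitney U
test — exact when both groups have at most 8 untied values, otherwise the
tie-corrected normal approximation without continuity correction. Binary
phenotypes use the Pearson chi-squared test on the 2×2 table without
continuity correction; when any expected cell is below 5, Fisher's exact
test is reported alongside rather than silently substituted, because the
uncorrected, corrected and exact variants can disagree noticeably at these
sample sizes and the reader should see both. Wilcoxon signed-rank tests
(one-sample against a reference value, and paired) drop zero differences,
average-rank ties, and are exact up to 25 untied differences.

*BH step-up.* Implemented directly ($q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$,
capped at 1, missing tests passed through without counting toward $m$) and
cross-checked in the tests against both a brute-force prefix scan and
`p.adjust`.

## The association screen

Per-patient expression enters the Pearson correlation as
$\log_2(\text{tumor FPKM} + c)$ by default; a $\log_2$ within-pair
fold-change transform is available for analyses that want to correlate the
*change* rather than the level. Each (gene, phenotype) test uses
pairwise-complete patients (patients without a measurement are dropped per
test), a two-sided p-value from the $t$-transform with $n-2$ degrees of
freedom, and one BH family across the entire gene × phenotype grid.
Zero-variance vectors yield an `undefined` flag rather than an error and are
excluded from the family. A gene is selected when any tested phenotype meets
the significance rule; a raw-p mode (`adjust = "none"`) is provided because
small historical screens often selected on unadjusted p < 0.05.

## Network analysis

The induced subgraph keeps exactly the query genes and the edges internal to
them; query genes absent from the interaction database become isolated
nodes, so the "n query / n with interaction / largest component" funnel is
always well defined. Components are computed with `igraph` and
deterministically ordered (size descending, then lexicographically smallest
member); the tests verify them against brute-force transitive closure.
Overrepresentation uses the upper-tail hypergeometric probability
$P(X \ge k)$ with BH adjustment over the tested sets, filtered at
$p < 0.05$ and $q < 0.1$ by default. The default universe is the set of
genes expressed (FPKM > 0) in at least one sample — a background of
assayable genes, not of all annotated genes.

## What the synthetic cohorts emulate

The generators are first-class, tested code; their defaults describe the
study shape the pipeline targets:

* `simulate_expression()`: $n = 9$ tumor/ANPT pairs over 2000 genes
  (a desk-scale stand-in for a ~30k-gene transcriptome), lognormal FPKM
  noise with $\sigma = 0.5$ on the $\log_2$ scale, per-gene baselines
  $\log_2 \mathrm{FPKM} \sim N(3, 2^2)$, and 5% of genes planted at fold 4,
  half up and half down. A lognormal model is the natural choice for a
  ratio-based statistic: multiplicative noise and scale-invariant folds.
* `simulate_cohort()`: 118 patients × 35 characteristics (tumor size, ACTH,
  cortisol, LH, E2, ten BMD Z-scores at standard skeletal sites, plus
  uncorrelated markers), drawn from a multivariate Gaussian and rescaled to
  plausible clinical units, with 10% missingness completely at random. The
  default correlation structure comes from a three-factor model (disease
  severity; shared bone density; gonadal axis) rather than an ad-hoc pair
  list: ten BMD scores each strongly correlated with tumor size cannot form
  a positive-semidefinite matrix unless the BMD–BMD block is planted too,
  and the factor construction guarantees PSD while producing the expected
  signs — size/ACTH/cortisol positive, size/BMD negative, LH–E2 and
  LH/E2–lumbar-BMD positive. Explicit pairwise targets are accepted and
  validated for positive semidefiniteness (sampling uses an
  eigendecomposition square root, so an exactly singular target is fine).
* `simulate_bmd_gene_link()`: a per-patient latent factor loads on the BMD
  Z-scores (loading 0.8 by default) and on the expression of a subset of the
  planted DE genes. Two deliberate design choices: the factor multiplies
  *both* tissues of a patient — a patient-level effect — so it moves
  per-patient expression without disturbing the within-pair fold (linked
  genes stay exactly as differentially expressed as planted, which is the
  regime the screen assumes: phenotype-related genes are found *among* the
  robust DE genes); and linked genes are drawn from DE genes with median
  control expression above 1 FPKM, since planting the phenotype link below
  the pseudocount detection floor would emulate a study whose own funnel
  could not produce a result.
* `simulate_ppi()`: Erdős–Rényi background edges plus one planted connected
  cluster (random spanning tree with extra in-cluster edges). At background
  probability 0 the graph is exactly the planted cluster.

Everything is bit-reproducible given (seed, config); data and ground-truth
tables are written side by side, truth files marked with a `#truth` header.

What the generators do **not** emulate: count-level sequencing noise and
mean–variance coupling, informative missingness (real BMD measurements are
missing for clinical reasons, not at random), correlated gene–gene
expression beyond the single latent factor, scale-free PPI topology, and
identifier aliasing. Passing recovery tests therefore demonstrate that the
chain is correctly assembled and has the claimed operating characteristics
under its own model — not that those characteristics transfer to any real
cohort.

## Validation conditions and problem sizes

The test suite runs each statistic against an independent oracle on ≥200
random small instances (brute-force DI composition, rank-then-Pearson,
brute-force BH, transitive-closure components), checks FDR control of the
phenotype screen under a global null (21 independent Gaussian phenotypes →
210 pairs, 50 patients, 200 replicates), and checks recovery: DE selection
on the default cohort; association recall and exact end-to-end cluster
recovery at 50 pairs with factor loading 0.9 and background edge
probability 0. Fifty pairs for the association conditions reflects that a
correlation screen BH-adjusted over tens of thousands of tests is
underpowered at $n = 9$ by design — at desk scale the purpose of the
end-to-end check is funnel integrity (each stage feeds the next, the
composition is intersective and deterministic), not a power claim at the
original cohort size.

## Known limitations

* The DI statistic has no variance moderation; a single extreme pair can
  dominate at small $n$. Its null distribution is not provided — selection
  is threshold-based, as in the analyses that introduced it.
* Headline gene counts of any particular published cohort (numbers of DE
  genes, of phenotype-associated genes, of connected genes) depend on
  undeposited patient data and a specific interaction-database version, and
  are not reproduction targets of this package.
* Gene identifiers are opaque case-sensitive strings; no aliasing or
  namespace mapping is attempted.
* The chi-squared/Fisher duality is reported, not resolved; at very small
  expected counts no single 2×2 test is uniformly standard.
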