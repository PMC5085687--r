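# phenogeno

Phenotype–genotype association screening for small paired tumor cohorts.

Rare endocrine tumors — the motivating case is ACTH-secreting pituitary
adenoma (Cushing disease), where hypercortisolism drives osteoporosis — are
typically studied with a handful of surgically paired tumor / adjacent
non-tumorous tissue (ANPT) expression profiles next to a much larger clinical
table. `phenogeno` implements the analysis chain such a study needs, for
analysts who start from an FPKM-scale expression matrix, a tumor/control
pairing, a patient-by-phenotype clinical table, and a protein–protein
interaction (PPI) edge list:

1. **Paired differential expression by the differential index (DI).** For
   gene *g* with tumor/ANPT fold change *fold<sub>i</sub>* in pair *i*
   (*fold* ≥ 1, signed by direction),

   DI = (±) Σ<sub>i=1..n</sub> (1 − 1/fold<sub>i</sub>) / n,

   so each pair contributes a normalised 0–1 value and |DI| maps back to a
   fold-change scale through the adjusted fold change FC = 1 / (1 − |DI|)
   (DI = 0.6 ⇔ FC = 2.5). Genes are selected when DI exceeds a threshold
   (default |DI| > 0.6) in enough pairs ("coverage", default two thirds of
   pairs at per-pair fold > 2.5).
2. **Clinical phenotype screen.** Spearman rank correlation over all
   phenotype pairs, pairwise-complete, with Benjamini–Hochberg FDR control
   and a significance mask for heatmap rendering.
3. **Phenotype–genotype link.** Pearson correlation of per-patient gene
   expression (log2 tumor FPKM by default) against chosen clinical
   parameters — e.g. bone-mineral-density (BMD) Z-scores — with BH
   adjustment over the whole gene × phenotype family.
4. **PPI subnetwork.** Induced subgraph of the associated genes, connected
   components, connectivity summaries.
5. **Overrepresentation.** Hypergeometric gene-set tests against a GMT
   collection, with an expressed-gene universe.

Seeded synthetic-cohort generators (`sim_config()`, `simulate_expression()`,
`simulate_cohort()`, `simulate_bmd_gene_link()`, `simulate_ppi()`) produce
data with this exact structure plus ground truth, so the whole chain is
testable end to end without any external download. Group-comparison
statistics for cohort tables (Mann–Whitney U, chi-squared/Fisher, one-sample
and paired Wilcoxon signed-rank) and ΔΔCt relative quantification round out
the toolbox.

## Worked example

```r
library(phenogeno)

cfg <- sim_config(seed = 1)            # 9 pairs, 2000 genes, 5% DE at fold 4
sim <- simulate_expression(cfg)
fit <- di_fit(sim$expr, sim$design)
fit
#> Differential-index fit: 2000 genes, 9 pairs (mode signed, pseudocount 0.1)
#> DE criteria: |DI| > 0.6 (FC > 2.5) and coverage >= 6 (tau = 0.6)
#> Selected: 93 genes (48 up, 45 down)

head(as.data.frame(fit)[order(-abs(coef(fit))), ], 3)
#>     gene_id        di adjusted_fc direction coverage passed
#> 485  g00485 0.8054205    5.139287        up        9   TRUE
#> 326  g00326 0.7968252    4.921869        up        9   TRUE
#> 975  g00975 0.7949774    4.877512        up        9   TRUE

expressed_gene_counts(sim$expr, c(0, 1))
#>   >0   >1
#> 2000 1931
```

The fit selects 93 of the 100 planted fold-4 genes (the remainder sit below
the pseudocount detection floor or miss the coverage rule), every call in the
planted direction; `di = 0.805` for the top gene means its expression change
corresponds to an adjusted fold change of 1/(1 − 0.805) ≈ 5.1. The clinical
screen on a matching synthetic cohort:

```r
scr <- spearman_screen(simulate_cohort(cfg)$clinical)
scr
#> Spearman phenotype screen: 595 pairs, 595 tested, 111 significant (q < 0.05)
#>    item_a          item_b coefficient        p        q n_used ...
#>  BMD_Z_L4 BMD_Z_total_hip       0.798 8.24e-23 4.90e-20     98 ...
```

The strongest correlations are between BMD Z-scores at different skeletal
sites, as planted; tumor size correlates positively with ACTH and cortisol
and negatively with every BMD Z-score.

A full run — DE → phenotype screen → association → network → enrichment —
is one call (`run_all()`) or one shell command via the installed CLI:

```sh
phenogeno simulate --seed 1 --out sim
phenogeno all --expr sim/expression.tsv --design sim/design.tsv \
  --clinical sim/clinical.csv --ppi sim/ppi.tsv --gmt sim/genesets.gmt \
  --out results
```

`results/report.json` records per-stage input/output counts and all
parameters.

## Documentation

The methods vignette (`vignettes/phenotype-genotype-screening.Rmd`) explains
the model, its assumptions, the tunable parameters, what the synthetic
cohorts do and do not emulate, and known limitations.
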