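# pathstrat

Pathway-level survival stratification and genomic targeting of expression
networks.

## The problem

Genome-wide screens for prognostic biomarkers in cancer expression data
routinely find hundreds of genes whose expression stratifies patients into
different-prognosis groups — and almost none of them replicate across
independent cohorts. `pathstrat` implements the network-level alternative
for multi-cohort studies: express every sample as per-pathway scores
derived from interaction graphs, screen pathways for survival
stratification the same way genes are screened, and keep only features
that are significant in *every* cohort. It also tests whether a pathway's
gene set is preferentially hit by copy-number or methylation alterations,
and characterizes the resulting survival groups (alteration frequencies,
cross-layer and gene-pair correlations).

## The model in brief

* **Gene states.** Each gene's expression across samples is a
  two-component gamma mixture, `(1-w)·Gamma(k_d, θ_d) + w·Gamma(k_u, θ_u)`
  (suppressed states are exponential-like, promoted states near-normal —
  both gammas), fitted by EM with an exact weighted-MLE M-step. The
  per-sample posterior `P(up | x)` feeds all pathway scores.
* **Pathway scores.** Interaction activity is the product of `P(up)` over
  promoter inputs times `1 − P(up)` over inhibitor inputs; consistency is
  `a·q + (1−a)·(1−q)` with `q` the mean output-gene posterior. Pathway
  scores are interaction means, in `[0, 1]`.
* **Survival screen.** Per feature: exact one-dimensional two-means
  clustering (the global K = 2 optimum via best sorted split), then the
  two-group log-rank test; significant means raw `p < 0.05`; robustness
  is the cross-cohort intersection of significant sets.
* **Genomic targeting.** Calls: CNV `|log2 ratio| > 0.3`, methylation
  `beta > 0.5`. Per patient `j` and pathway `i`, a hypergeometric tail
  p-value for the pathway's altered-gene count `x_ij` given `M` tested
  genes, `K_j` altered in the patient and `N_i` in the pathway; combined
  across patients with Fisher's omnibus `−2·Σ ln p ~ χ²(2n)`; flagged
  under Bonferroni `α / #pathways`.
* **Synthetic truth.** A generator plants a driver pathway whose latent
  per-sample state triples the hazard, couples imperfectly to its member
  genes, and is decoupled from a different 30% of them in each cohort —
  so single genes fail the cross-cohort intersection while the pathway
  survives it. See the vignette
  (`vignettes/pathway-survival-stratification.Rmd`) for every modelling
  and default-parameter decision.

## Worked example

```r
library(pathstrat)

cohort <- generate_cohort(cohort_config(seed = 1))
run <- run_cohort_analysis(cohort$datasets, cohort$pathways, seed = 1)
print(run)
```

```
pathstrat_run over 3 dataset(s)
  dataset1: 28 significant genes, 1 significant pathways
  dataset2: 28 significant genes, 2 significant pathways
  dataset3: 20 significant genes, 2 significant pathways
  gene-tier intersection: G0007, G0026 
  pathway-tier intersection: PW_DRIVER 
```

Reading: each cohort alone yields 20–28 "significant" genes, but only two
of the 40 planted driver genes survive the three-cohort intersection —
the single-gene tier is unstable. The pathway tier recovers exactly the
planted driver pathway in all three cohorts. The targeting scan on the
first cohort's copy-number calls flags the same pathway:

```r
subset(run$per_dataset$dataset1$targeting_cnv, targeted,
       c(pathway_id, n_genes, combined_p, bonferroni_alpha))
```

```
  pathway_id n_genes    combined_p bonferroni_alpha
1  PW_DRIVER      40 2.225074e-308            0.005
```

The `analysis/` directory carries the same workflow as a narrated
sequence of scripts (`01_simulate.R` … `06_characterize_driver.R`), each
writing its tables under `results/`; run them in order from the
repository root.

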