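# idicss

Immune driver independent components and the iDICss risk score.

## What this package is for

Driver mutations (BRAF, NRAS, TP53, ...) shape the tumor immune
microenvironment (TIME), and the interplay between the two decides
whether a melanoma patient benefits from immune checkpoint blockade.
`idicss` implements a pipeline for analysts working with matched bulk
expression, somatic mutation and clinical data who want a mutation-aware
immune risk score:

1. **ICA** — decompose the expression matrix `E` (genes × samples) as
   `E_c ≈ S W` by FastICA (logcosh contrast, deterministic sign/scale
   conventions, multi-restart stability scoring).
2. **Key-IC selection** — keep components whose top-loading genes
   (|z| > 3) are enriched in immune gene sets (hypergeometric test, BH
   over the full scan) *and* more densely connected in a reference PPI
   than degree-matched random gene sets (permutation test). A component
   crosstalk network (Jaccard overlap of top-gene sets) is reported for
   inspection.
3. **iDIC profile** — blend z-scored component weights with mutation
   impacts, `iDIC = W̃ + λ·D + (1−λ)·I`, where `D` and `I` are the
   z-scored summed loadings of mutated driver / immune genes and
   `λ ∈ [0,1]` (default 0.7) trades the two channels.
4. **Subgroups and the score** — consensus clustering (k = 2) of the
   profile, subgroup differential expression, LASSO-Cox on the
   candidates, and the per-sample score `iDICss(s) = Σ β_g z_g(s)` with a
   frozen training-median split into high/low risk.
5. **Evaluation** — Kaplan–Meier + log-rank, Harrell's C, AUROC,
   time-dependent AUC (IPCW), classification metrics, a combinatorial
   survival machine-learning benchmark over an adapter registry, simple
   single-gene/gene-pair comparator baselines, and a cell-line drug
   IC50 Spearman screen.

A synthetic-cohort generator (`simulate_cohort()`) plants latent
components, driver-component mutation links, survival and response
signal, so every stage is testable end-to-end without any downloads.

## Worked example

```r
library(idicss)

sim <- simulate_cohort(sim_config(seed = 7))      # 2,000 genes x 300 samples
res <- run_pipeline(sim$bundle, sim$immune_sets, sim$ppi,
                    sim$driver_genes, seed = 42)

res$decomp
#> <ica_decomposition> 2000 genes x 300 samples, k=10 (converged, 42 iterations)

dplyr::filter(res$relevance, selected)[, c("component", "best_set", "best_q", "ppi_p")]
#>   component     best_set   best_q ppi_p
#> 1       IC7 immune_set_2 1.48e-41 0.002
#> 2       IC4 immune_set_3 3.66e-28 0.002
#> 3      IC10 immune_set_1 9.66e-22 0.002

res$subgroups
#> <idic_subgroups> k=2, PAC=0.007; sizes: clusterA=153, clusterB=147
res$signature
#> <gene_signature> 21 genes (penalty 0.1223, threshold -0.1753)
res$survival
#> <survival_comparison> log-rank chisq=312.937 (df=1), p=5e-70
```

The three selected components are exactly the three planted immune
components (tiny enrichment q, PPI permutation p = 0.002), the two
subgroups split the cohort almost unambiguously (PAC 0.007), and the
low-risk group lives far longer than the high-risk group on the training
cohort. Scoring a fresh cohort drawn from the same generative model
shows the signature transfers:

```r
val <- simulate_validation(sim, seed = 99)
vs  <- score_idicss(val$bundle$expression, res$signature)
m   <- dplyr::inner_join(vs$scores, val$bundle$clinical, by = "sample")
concordance_index(m$idicss, m$os_time, m$os_event)
#> held-out C-index: 0.9
response_auc(-m$idicss, m$response)
#> held-out response AUC (-iDICss): 0.824
```

Lower iDICss predicts both longer survival and immunotherapy response
(the response AUC is reported for −iDICss).

Result tables are tibbles; fitted objects have `tidy()`/`glance()`
methods, and `autoplot()` / `plot_benchmark()` / `plot_ic_relevance()`
draw the standard figures. A thin command-line wrapper is installed as
`exec/idicss` (`idicss simulate`, `idicss run`, `idicss score`).

See `vignettes/idicss-methods.Rmd` for the model, parameter meanings,
generator design and known limitations.

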