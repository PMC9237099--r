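# tensorccc

Context-aware deconvolution of cell-cell communication by non-negative
tensor decomposition.

## The problem

Ligand-receptor (LR) mediated communication between cell types changes
with cellular context — disease severity, time point, tissue, subject.
Pairwise per-context analyses discard the correlation structure across
contexts. `tensorccc` organises the communication scores of an entire
study as a labeled four-way array

```
chi  :  contexts (C) x LR pairs (P) x sender cell types (S) x receiver cell types (T)
```

and deconvolves it with a rank-R non-negative CANDECOMP/PARAFAC model

```
chi[i,j,k,l]  ~  sum_r  c_r[i] * p_r[j] * s_r[k] * t_r[l],    all loadings >= 0
```

Each rank-one term is an interpretable *communication module*: the context
loadings `c_r` trace when the module is active, the pair loadings `p_r`
name its LR mediators, and the cell loadings `s_r`, `t_r` its sender and
receiver cell types. Fit quality is the normalized reconstruction error
`||chi - chi_hat||_F^2 / ||chi||_F^2`, the tensor analogue of unexplained
variance.

The package is aimed at computational biologists analysing multi-sample
single-cell (or bulk) transcriptomics: it builds the tensor from counts
(complex-aware min-subunit expression, mean / product / geometric-mean
scores, non-zero-fraction or log-CPM aggregation) or ingests per-context
edge lists produced by external scoring tools, fits the model by
alternating least squares with non-negative (HALS) updates and seeded
restarts, selects the rank at the reconstruction-error elbow, and provides
the standard downstream analyses: CorrIndex decomposition similarity,
factor-specific communication networks with Gini coefficients, Spearman
correlation against ordinal context levels, pairwise t-tests with
Bonferroni correction, Ward clustering of z-scored sample loadings, and
pre-ranked gene-set enrichment of LR-pair loadings.

## Worked example

Simulate the built-in study system — 3 cell types interacting through 300
LR pairs (3 signaling pathways x 100 pairs) across 12 time points, with
four embedded temporal communication patterns (oscillation, pulse,
exponential decay, linear decrease) — then recover the modules:

```r
library(tensorccc)

sim  <- simulate_comm_tensor(seed = 42)
sim$tensor
#> 4D communication tensor (external scores): 12 contexts x 300 LR pairs x 3 senders x 3 receivers
#>   values in [0.05, 1]

scan <- select_rank(sim$tensor, ranks = 1:10, seed = 42)
scan
#> Rank scan over ranks 1 .. 10
#>   normalized errors: 0.6526 0.3944 0.1345 0.0199 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000
#>   selected rank (error-curve elbow): 4

fit <- normalize_loadings(cp_decompose(sim$tensor, rank = scan$selected,
                                       seed = 42))
evaluate_recovery(fit, sim$truth)
#>       pattern factor pearson_context jaccard_pairs
#> 1 oscillation      1       0.9999621             1
#> 2       pulse      3       0.9999773             1
#> 3 exponential      4       0.9999699             1
#> 4      linear      2       0.9999821             1
```

The scan's error curve drops steeply until four factors and flattens; the
elbow selects rank 4, matching the number of embedded patterns. Each
factor's context loadings correlate with their generating curve at
`r > 0.999`, and its 100 top-loaded pairs are exactly the generating
pathway's pairs (Jaccard 1). `plot(fit)` draws the per-factor loading
bars; `summary(fit)` lists top elements per dimension; `fitted()`,
`residuals()` and `coef()` behave as for any fitted model.

Downstream, on your own data:

```r
rho  <- ordinal_correlation(coef(fit, "contexts")[, 1], severity_levels)
stat <- compare_groups(coef(fit, "contexts"), group_labels)
nw   <- factor_network(fit, r = 1)        # rank-1 adjacency + Gini
sets <- build_lr_sets(read_gmt("kegg.gmt"), catalog, min_size = 15)
enr  <- prerank_gsea(coef(fit, "pairs"), sets, n_perm = 999, seed = 1)
```

A thin command-line front end (`inst/scripts/tensorccc`) exposes
`simulate` and full-pipeline `run` subcommands over a YAML/JSON config;
`run_pipeline()` is the same entry point from R and writes loadings TSVs,
a rank-scan CSV, downstream tables, a log and a config snapshot into a run
directory.

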