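# edrw

Entropy-based directed random walk (e-DRW) pathway activity inference and
binary cancer-vs-normal classification from gene expression data.

## What it does, and for whom

Pathway-level features are more reproducible cancer classifiers than
individual gene markers, but most pathway scores ignore the pathway's
internal wiring. `edrw` is for computational biologists who have a genes ×
samples expression matrix with a binary phenotype, one or two directed
gene–gene networks (SIF edge lists, e.g. derived from KEGG and PID), and
pathway membership as GMT gene sets, and who want per-sample pathway
activity scores that weight each gene by both its differential expression
and its topological importance — plus an evaluation protocol that turns
those activities into cross-validated classification AUCs.

## The method

Per gene *g*, differential expression is scored by the **PCT score**
combining the equal-variance two-sample t-statistic and the point-biserial
correlation with the phenotype:

    Z(g) = t(g)^2 + |rho_pb(g)|

PCT scores are min–max mapped to initial weights `W0`, and each gene's
expression distribution across samples yields a normalized Shannon entropy
`E(g)` and entropy weight `ew(g) = (1 - E(g)) / sum(1 - E)`. Each directed
network is converted to a row-stochastic transition matrix `T` that
allocates a node's out-probability proportionally to its targets' entropy
weights, and a **random walk with restart**

    H_{t+1} = (1 - r) T' H_t + r H_0,   H_0 = W0 restricted to the network

is run independently on the two networks (the bi-walk). The stationary
vector `H_inf` then weights the activity of pathway `P_j` in sample *k*
over its significant member genes (raw p < 0.05):

    a_k(P_j) = sum_i H_inf(g_i) Z(g_i) z_k(g_i) / sqrt(sum_i ew(g_i)^2)

Activities from the two networks are concatenated, ranked by |t| on
training samples, and a greedy forward selection keeps a pathway only if it
strictly increases the mean AUC under stratified 10-fold cross-validation
(naive Bayes, KNN or logistic regression); the optimized feature set is
scored on held-out test samples, over 10 repeated stratified 60/20/20
splits. See `vignettes/edrw-methods.Rmd` for assumptions, parameter
defaults and design choices.

## Worked example

The package ships a seeded synthetic-cohort generator so the whole pipeline
runs without external databases: two directed networks (50 pathways each,
10–40 genes, 30% shared genes), 2000 genes, and 60 normal + 60 tumor
samples in which 3 planted pathways carry a 1.5-sd coherent shift.

```r
library(edrw)

spec   <- synthetic_spec(seed = 42)   # reference conditions
cohort <- simulate_cohort(spec)
cohort$planted
#> [1] "K03" "K15" "K45"

result <- run_repeated_experiment(
  cohort$expr, cohort$labels, cohort$networks, cohort$pathways,
  r = 0.5, classifier = "knn", repeats = 10, base_seed = 7)
result
#> e-DRW repeated experiment (10 repeats, knn, r = 0.5)
#>   mean test AUC: 1 (sd 0)
#>   per-repeat AUC: 1 1 1 1 1 1 1 1 1 1
#>   most-selected pathways: KEGG:K15 (10/10)
```

The planted pathways dominate the activity ranking in every repeat (here
`K15` alone already separates the classes perfectly, so the greedy
selection stops after one feature), and the held-out test AUC is 1.0 in all
10 repeats. With permuted labels the same protocol returns a mean test AUC
near 0.5, confirming the evaluation is leakage-free.

Individual stages are exposed as plain functions — `impute_row_mean()`,
`znormalize()`, `score_genes()`, `gene_entropy()`, `entropy_weights()`,
`build_entropy_transition()`, `walk_with_restart()`, `bi_random_walk()`,
`infer_pathway_activity()`, `combine_network_profiles()`,
`rank_top_pathways()`, `greedy_forward_selection()` — with readers/writers
for TSV/GCT expression, SIF networks and GMT gene sets.

A thin command-line wrapper is installed at `exec/edrw`
(`Rscript $(Rscript -e 'cat(system.file("exec","edrw",package="edrw"))')`):
subcommands `run`, `simulate`, `preprocess`, `score`, `walk`, `activity`
and `classify`, driven by a YAML config for `run`. Reruns with the same
config are byte-identical.

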