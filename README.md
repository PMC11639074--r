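# intercell

Who regulates whom, cell by cell: `intercell` models **intercellular gene
regulation** from spatially resolved transcriptomics. It is aimed at
researchers with a spatial expression matrix (10x Visium, Stereo-seq,
Slide-seqV2, or any platform exporting counts + coordinates + cell types)
who want to (i) impute the sparse matrix and (ii) attribute each gene's
expression in each cell to specific ligand-receptor (LR) signals from its
neighbours.

## Model

Given observed counts `X_obs` (n cells × m genes), coordinates `C` and a
cell-type matrix `T` (one-hot or spot proportions), expression is
decomposed as

    X̂ = X̂_b + Σ_{lr ∈ LR_θ} X̂_s^{lr′}

* `X̂_b = MLP(T)` — the cell-type baseline;
* one **communication view** per active LR pair: a directed cell-cell
  graph with weight `E_l[i]·E_r[j] / D[i,j]` (ligand level in the sender,
  receptor level in the receiver, inverse spatial distance), sparsified to
  each sender's k nearest neighbours; a pair is active when ligand and
  receptor are each expressed in more than a fraction θ of cells;
* per-view graph neural networks `H_lr = GNN(T, G_C^lr)` with a shared
  decoder produce `X̂_s^lr`, optionally masked by a GRN/PPI prior
  (`X̂_s^{lr′} = X̂_s^{lr} ⊙ M_lr`) so a pair can only touch genes
  reachable from its receptor;
* training minimises MSE over the observed entries (Adam, early
  stopping); afterwards the active set is **re-screened on the imputed
  matrix**, new views are added, overlapping views blended
  (`α G⁽ⁱ⁾ + (1−α) G⁽ⁱ⁺¹⁾`), and training repeats until no view can be
  added.

The per-view component doubles as a regulatory score,
`ψ(lr, c, g) = X̂_s^{lr′}[c, g]`, and sorting pairs by ψ gives a ranked
regulator list per cell and gene. Defaults: θ = 0.15, d = 32, L = 2,
k = 5, α = 0.2, learning rate 0.01, ≤ 1000 epochs, patience 10.

A synthetic-data generator (`simulate_dataset()`, nine presets) plants
cell-type territories, circular LR communication zones and known
ligand→gene ground truth, and masks counts to a target density, so the
whole method is testable end to end without downloads.

## Worked example

```r
library(intercell)
sim <- simulate_dataset(simulation_setting(1, n_cells = 200,
                                           n_lr_pairs = 10, seed = 42))
sim$data
#> <spatial_expression> 200 cells x 50 genes, 5 cell types; density 0.200

run <- run_pipeline(sim$data, sim$lr, sim$prior, run_config(seed = 42))
run$history
#>   iteration n_views n_new_views train_loss
#> 1         0       9           9   6.007031
#> 2         1      10           1   4.544341
```

Nine LR pairs pass the expression screen on the sparse counts; after the
first training round one more pair becomes active on the imputed matrix
(the iterative densification step), and the next round adds nothing, so
the loop stops. Ranking regulators for a zone cell and its planted target
gene:

```r
hit <- sim$truth[1, ]     # cell C0038, gene G01, planted regulator LR01
rank_lr_pairs(run$result, hit$cell_id, hit$gene)[1:3, ]
#>   lr_id          psi
#> 1  LR02 8.892510e-01
#> 2  LR01 2.375737e-09
#> 3  LR03 0.000000e+00

sc <- score_regulatory_recovery(run$result, sim)
rb <- score_random_baseline(sim, seed = 42)
sprintf("model NDCG %.3f vs random %.3f over %d cell-gene pairs",
        sc$ndcg, rb$ndcg, sc$n_pairs_evaluated)
#> [1] "model NDCG 0.968 vs random 0.454 over 70 cell-gene pairs"
```

For this particular cell the prior mask admits two candidate regulators
and the planted pair lands second; averaged over all 70 planted
(cell, gene) combinations the rankings are near-ideal (NDCG 0.97 against
0.45 for random guessing).

Command-line wrappers live in `inst/cli/intercell.R`
(`simulate` / `run` / `evaluate` / `ablate`), and `benchmark_run()` /
`ablation_sweep()` reproduce the hold-out imputation metrics (L1, RMSE,
cosine) and ranking metrics (precision@K, NDCG, Spearman, Kendall)
programmatically.

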