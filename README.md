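# aghn

Learning the mapping from a brain's **structural connectivity** (SC) to its
resting-state **functional connectivity** (FC) with an attention-weighted
fusion of multi-scale graph heat-kernel networks (A-GHN).

## The model

A subject's SC matrix `A` (symmetric, non-negative streamline densities,
zero diagonal, N regions) defines a combinatorial Laplacian `L = D − A`.
Diffusion over the structural graph at scale γ is the heat kernel
`H_γ = exp(−γL)`: small scales mix locally, large scales globally. One
GraphHeat sub-model per scale learns a free readout of its diffusion
operator,

    Ψ_i = tanh(W_i · exp(−γ_i L) · X),   X = I_N,  i = 1..m,

an attention module scores each output against a shared weight vector,
`α_i = vec(Ψ_i)·W_α`, and the predicted FC is the softmax-weighted,
symmetrized fusion

    C_f = sym( Σ_i Softmax(α)_i · Ψ_i ).

All parameters are shared across subjects and trained end-to-end with Adam
against the empirical FC (mean-squared error); attention is
input-dependent, so different subjects can lean on different diffusion
scales. One layer has `(m+1)·N²` trainable scalars — 60,552 for the
87-region Desikan–Killiany parcellation with the default seven scales
{0.6, 0.8, 1, 2, 4, 6, 8}.

Ablation variants: `m_ghn` (uniform 1/m fusion, no attention) and
`random_aghn` (per-scale weights frozen at initialization). The package
also ships a seeded synthetic SC–FC cohort generator with planted
multi-scale diffusion structure and power-law edge weights, evaluation
statistics (upper-triangle Pearson, MSE, Louvain communities, partition
mutual information in bits), and a power-law SC perturbation experiment.

## Worked example

Generate a synthetic cohort whose FC is produced by a known three-scale
diffusion mixture, train, and evaluate on the held-out test split:

```r
library(aghn)

spec <- synthetic_spec(n_regions = 30, n_subjects = 100,
                       split_sizes = c(40, 10, 50), noise_sigma = 0.05, seed = 7)
cohort <- generate_cohort(spec)
cohort
#> <aghn_cohort> 100 subjects, N = 30 regions (train 40 / val 10 / test 50)

scales <- aghn_config(scales = c(0.6, 2, 6), n_regions = 30)
fit <- aghn_train(cohort, scales,
                  train_config(max_epochs = 1000, patience = 50,
                               dropout_keep = 1, exclude_diagonal = TRUE,
                               seed = 7))
fit
#> <aghn_train_report> variant=aghn, stopped at epoch 373 (best epoch 323, val loss 0.00942821)

preds <- predict_cohort(fit$final_params, cohort, scales, split = "test")
report <- evaluate_cohort(preds, cohort, mi = TRUE)
report
#> <aghn_eval_report> 50 subjects: mean Pearson 0.9151, mean MSE 0.04425
#> communities: empirical 5, predicted 5; MI(emp, pred) = 2.306 bits

round(preds[[1]]$attention_probs, 3)
#> [1] 0.990 0.005 0.005
```

The mean test-set Pearson correlation of 0.915 (upper triangles,
diagonal excluded) is close to the ceiling imposed by the generator's
observation noise, i.e. the planted mixture has been recovered. The
attention probabilities show the fusion leaning on the smallest diffusion
scale for this cohort. The MSE of 0.044 uses the full-matrix convention,
which includes the uninformative unit diagonal of empirical FC.

## Command-line interface

A thin wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/aghn.R", package = "aghn"))')
Rscript $CLI info --regions 87 --scales 7
# A-GHN: N = 87 regions, m = 7 scales, 1 layer(s) -> 60552 trainable parameters
Rscript $CLI simulate --out cohort/ --seed 5
Rscript $CLI train --cohort cohort/ --out model/ --seed 5
Rscript $CLI evaluate --checkpoint model/checkpoint.rds --cohort cohort/ --out eval/
```

Every subcommand is deterministic given its configuration and seed; the
resolved configuration is echoed beside each output directory.

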