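# transaug

GAN-based data augmentation for bulk transcriptomics, with a full battery
of generative-quality indicators — in plain R.

## The problem

Deep classifiers of cancer phenotype from RNA-seq face a *small n, large
p* regime: hundreds of samples per pathology against ~20 000 genes.
Because transcriptomics has no label-invariant transformations (no crops
or rotations), the only general route to data augmentation is a deep
generative model: train a generator on the available expression profiles
and enlarge the training set with synthetic samples that follow the true
distribution.

`transaug` implements and compares the main GAN families used for this
purpose, and — just as importantly — the indicators needed to tell a good
generator from a bad one:

- **Models** — plain GAN (non-saturating min–max loss), conditional GAN
  (covariates age / gender / tissue / cancer concatenated to both
  networks, conditioning restricted to observed covariate patterns),
  **WGAN-GP** (Wasserstein critic with gradient penalty
  `λ·E[(‖∇_x̃ D(x̃)‖₂ − 1)²]` at interpolates `x̃ = u·x + (1−u)·x̂`), and
  an **attention GAN** whose final layer polishes the generator output
  with sparse softmin/L1 self-attention over masked gene pairs:
  `e_ij = |w_k[i] x_i − w_q[j] x_j|`, `α_ij = softmin_j(e_ij)`,
  `y_i = x_i + γ Σ_j α_ij w_v[j] x_j`.
  Masks come from co-expression, PPI edge lists, their union, or a
  degree-preserving random permutation (the lesion control).
- **Unsupervised indicators** — Fréchet distance
  `‖μ_t − μ_g‖² + Tr(Σ_t + Σ_g − 2(Σ_t Σ_g)^{1/2})` on the last hidden
  layer of task classifiers (FD-binary / FD-tissue); manifold
  precision/recall/F1 via k-NN balls (k = 50); adversarial accuracy (1-NN
  real-vs-generated; ≈0 memorization, ≈1 poor generation, ≈0.5 the sweet
  spot); the cosine similarity of gene–gene correlation matrices; PCA
  cumulative-variance spectra.
- **Supervised indicators** — augmentation gain
  `ΔAcc(n, m) = Acc(n, m) − Acc(n, 0)`, reverse validation (train on
  generated, test on held-out true data), and the two augmentation
  schedules (fixed generated count with growing n; fixed true count with
  growing m).
- **Simulator** — a synthetic transcriptome generator (tissue clusters,
  block-correlated gene groups, cancer mean shift, per-sample covariates)
  so everything above is testable without any external cohort.

No deep-learning framework is required: the package carries its own small
MLP engine (Adam, exact critic input gradients, exact gradient-penalty
backprop for ReLU critics), verified against finite differences in the
test suite.

## Worked example

Simulate a 600 × 100 cohort, split it, train a conditional WGAN-GP, and
score the generated data (about 3½ minutes on one CPU):

```r
library(transaug)

ds    <- simulate_transcriptome(sim_config(n_samples = 600, n_genes = 100,
                                           n_tissues = 4, block_size = 10,
                                           cancer_shift = 0.25, seed = 1))
parts <- split_dataset(ds, split_spec(1/6, 1/6, stratify_on = "tissue", seed = 1))

model <- train_gan(parts$train,
                   train_config("wgan_gp", epochs = 500, d_z = 32,
                                g_hidden = c(128, 128), d_hidden = c(128, 128),
                                batch_size = 64, seed = 1))

emb <- list(binary = fit_embedding(parts$train, "binary", seed = 1))
compute_report(model, parts$train, emb, k = 10, n_runs = 3, seed = 1)
#> <metrics_report> k = 10 , n_true = 400 , n_generated = 400 , runs = 3
#>   correlation  ↑  0.9871 +/- 0.0007
#>   precision    ↑  0.9367 +/- 0.0063
#>   recall       ↑  0.8925 +/- 0.0115
#>   f1           ↑  0.9140 +/- 0.0054
#>   fd_binary    ↓  0.7008 +/- 0.0136
#>   aa              0.6950 +/- 0.0141

gen <- generate_expression(model, 1000, covariate_source = parts$train, seed = 2)
reverse_validation(gen, parts$test, task = "binary", seed = 1)
#> [1] 0.93

augmentation_gain(50, 1000, parts$train, model,
                  classifier_spec("binary", hidden_size = 64L, epochs = 30L),
                  parts$test, n_runs = 5, seed_base = 1)$delta_acc
#> [1] 0.12
```

Reading the numbers: the generated data reproduce the gene–gene
correlation structure (0.99), sit on the true manifold (precision 0.94)
while covering most of it (recall 0.89), and are neither copies nor
trivially separable (AA 0.70, between the 0 of memorization and the 1 of
failure). A classifier trained only on generated samples reaches 93% on
held-out true data, and augmenting a 50-sample training set with 1000
generated samples lifts binary accuracy from 0.79 to 0.91
(ΔAcc = +0.12).

## Command line

```sh
transaug simulate  --config sim.json --out data/
transaug split     --data data/expression.tsv --covariates data/covariates.tsv \
                   --val 0.1667 --test 0.1667 --stratify tissue --seed 1 --out splits/
transaug mask      --mode coexp --data splits/train.tsv --threshold 0.6 --out mask.tsv
transaug train     --model wgan-gp --data splits/train.tsv \
                   --covariates splits/train_covariates.tsv \
                   --config train.json --seed 1 --out model.rds
transaug generate  --model model.rds --m 1000 --seed 2 --out gen.tsv
transaug evaluate  --true splits/train.tsv --covariates splits/train_covariates.tsv \
                   --generated gen.tsv --generated-covariates gen.tsv.covariates.tsv \
                   --k 50 --runs 5 --out report.json
transaug benchmark --config bench.json --out results/
```

The `transaug` script lives in `inst/cli/` (so
`$(Rscript -e 'cat(system.file("cli/transaug", package="transaug"))')`
after installation); all config files are JSON.

## Scope

The package ships no cohort data and does not download TCGA; users supply
their own matrices (samples × genes TSV/CSV with a covariate table) or use
the simulator. Desk-scale defaults are tuned for hundreds of genes;
transcriptome-scale runs are supported by the same code paths but need
commensurate compute.
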