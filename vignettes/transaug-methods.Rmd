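---
title: "Models, indicators and design choices in transaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, indicators and design choices in transaug}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transaug)
```

# Why generative augmentation

Phenotype prediction from bulk RNA-seq is a *small n, large p* problem:
cohorts of hundreds of samples against tens of thousands of genes. Since
no label-invariant transformation of an expression profile is known (there
is no transcriptomic analogue of flipping an image), augmentation must
come from a generative model of the expression distribution itself. This
package implements the GAN families most used for the task and — because
a generator can fail silently — an equally careful battery of indicators
for the generated data.

# The models

All models operate on normalized expression in $[0,1]$ (see
*Normalization* below) and are small multilayer perceptrons; the package
carries its own dense-network engine (Adam optimizer, ReLU hidden layers)
rather than depending on a deep-learning framework, and its gradients —
including the exotic ones below — are validated against finite
differences in the test suite.

**GAN.** Generator $G$ maps a latent draw $z \sim N(0, I)$ to an
expression vector through a sigmoid output (bounded like the data);
discriminator $D$ estimates the probability that its input is real. The
objective is the classic min–max cross-entropy game; for optimization the
generator uses the non-saturating variant $-\mathbb{E}[\log D(G(z))]$,
because the saturating form has vanishing gradients exactly when the
generator is losing. Both loss forms are recorded in the training
history.

**Conditional variants.** The covariate pattern (standardized age,
one-hot gender and tissue, binary cancer flag) is concatenated to the
generator input and the discriminator input. Generation samples only
covariate patterns observed in the training data — the empirical pattern
distribution — never interpolated ones.

**WGAN-GP.** The critic estimates a Wasserstein-1 distance instead of a
classification probability; its 1-Lipschitz constraint is enforced with
the gradient penalty $\lambda\,\mathbb{E}[(\lVert\nabla_{\tilde x}
D(\tilde x)\rVert_2 - 1)^2]$ at per-sample interpolates
$\tilde x = u x + (1-u)\hat x$. The critic minimizes
$\mathbb{E}[D(\hat x)] - \mathbb{E}[D(x)] + \text{penalty}$ (the standard
sign convention; the printed form that places the penalty inside
$\max_D$ is not internally consistent). Defaults: $\lambda = 10$,
`n_critic = 5`, Adam $\beta = (0.5, 0.9)$. Because the hidden
activations are piecewise linear, the parameter gradient of the penalty
is computed *exactly* by a frozen-mask double-backward pass (the second
derivative of ReLU vanishes almost everywhere); no finite-difference or
approximate penalty is involved.

**Learning rates.** The supplementary grids of the protocol this package
follows are not published; shipped defaults are therefore design choices.
For the WGAN family we use a two-time-scale update rule — critic
$4\times10^{-4}$, generator $1\times10^{-4}$ — because a critic trained
too slowly makes the Wasserstein estimate meaningless at desk-scale step
budgets; with symmetric rates of $10^{-4}$ the toy benchmarks underfit
within 2000 generator steps. The plain GAN uses $2\times10^{-4}$ for both
networks with $\beta = (0.5, 0.999)$.

**Sparse softmin/L1 attention.** At transcriptome scale a dense
$d \times d$ attention map does not fit in memory, so attention is
restricted to a sparse set of gene pairs (the *attention mask*) plus each
gene's self pair. Genes are scalars, so the similarity score is an L1
discrepancy of key/query-scaled values rather than a dot product, and the
softmax becomes a softmin (small discrepancy = large weight):
$$e_{ij} = |w_k[i] x_i - w_q[j] x_j|,\qquad
  \alpha_{ij} = \frac{e^{-e_{ij}}}{\sum_{l \in N(i)} e^{-e_{il}}},\qquad
  y_i = x_i + \gamma \sum_{j \in N(i)} \alpha_{ij}\, w_v[j]\, x_j.$$
Two details are deliberate choices. First, the aggregated *value* uses
the neighbor $w_v[j] x_j$: the printed formula in the source protocol
aggregates the self value $w_v[i] x_i$, which collapses to a per-gene
rescaling because the weights sum to one; an `as_printed` toggle
reproduces that degenerate form for auditability. Second, the self pair
is always a member of $N(i)$, so the softmin is defined even for isolated
genes. $\gamma$ can be fixed (default 1) or learned (initialized at 0);
an optional attention-free warm-up (`pretrain_epochs`) trains with
$\gamma$ forced to 0 and attention parameters frozen before enabling the
layer. The attention layer is applied once, as a final polish on the
generator output.

**Masks.** Co-expression masks keep pairs with $|r| \ge$ threshold on the
training split (absolute correlation; constant genes are excluded with a
warning); PPI masks come from an edge list filtered by confidence score;
`merge_masks` takes the union; and `random_permutation_mask` applies one
random permutation of gene indices to all pairs, preserving the pair
count and degree multiset exactly — the lesion control that asks whether
attention helps because of *what* the genes are or merely because of the
graph's shape. All masks are stored as coordinate lists and symmetrized.

# The indicators

**Fréchet distance** between Gaussian approximations of classifier
embeddings: $\lVert\mu_t-\mu_g\rVert^2 + \mathrm{Tr}(\Sigma_t + \Sigma_g
- 2(\Sigma_t\Sigma_g)^{1/2})$, with the matrix square root taken by
eigendecomposition of the symmetrized product and negative eigenvalues
from numerical error truncated at zero. FD-binary embeds through the last
hidden layer (256 units) of the cancer classifier, FD-tissue through the
tissue classifier (64 units); all true training samples serve as the
reference side. Covariances use the unbiased $n-1$ estimator.

**Manifold precision/recall** ($k = 50$ by default): each sample owns a
ball whose radius is the distance to its $k$-th nearest neighbor *within
its own set, excluding itself* (including the point itself would make the
radius degenerate — the exclusion is our reading, stated here because the
protocol leaves it open). Precision is the fraction of generated points
inside some true ball, recall the converse; distances are Euclidean in
the original normalized feature space, not in an embedding. F1 is the
harmonic mean, defined as 0 when both are 0.

**Adversarial accuracy**: the accuracy of the implicit 1-NN
real-vs-generated classifier, with *strict* inequality so that
exact-duplicate ties count against separability — exact copies give
AA = 0, fully separated clouds give AA = 1, and a generator in the
desired regime sits near 0.5. On large cohorts the true side is
subsampled (seeded, default cap 2000).

**Correlation score**: cosine similarity between the strictly upper
triangular entries of the true and generated gene–gene Pearson
correlation matrices. The printed formula in the source protocol repeats
the true-data term in the numerator; the cross-product reading
implemented here is the only one that is a similarity equal to 1 at
identity. Constant genes contribute zero correlations.

**PCA cumulative variance** compares intrinsic dimensionality: a
mode-collapsed generator concentrates its variance on few components,
giving a cumulative-variance curve that saturates far earlier than the
true data's.

**Supervised harness.** `augmentation_gain` computes
$\Delta\text{Acc}(n, m)$ by stratified subsampling of $n$ true samples
(stratification keeps all classes present at tiny $n$; per-run seeds are
recorded), appending $m$ generated samples, and training the task
classifier — one hidden layer of 256 (binary) or 64 (tissue) units,
learning rates $10^{-3}$ / $5\times10^{-4}$, batch 32, 40 epochs, fixed
budgets with no early stopping. The $m = 0$ arm reuses the same seeds, so
$\Delta\text{Acc}(n, 0) = 0$ holds exactly, as an identity rather than an
approximation. `reverse_validation` trains the fixed 512-unit classifier
($10^{-4}$, 35 epochs) on generated data alone and reports accuracy on
held-out true data. Mixed true/generated batches are concatenated and
shuffled with no prescribed mixing ratio. "Mean ± sd over five runs"
means five classifier seeds over one generated pool; regenerating per run
is available when a model (rather than a pool) is the source.

# The simulator: what it emulates, what it does not

`simulate_transcriptome` produces a desk-scale caricature of a pan-cancer
compendium: per sample $s$, gene $g$,
$$x_{sg} = \mu_{t(s),g} + \sigma\left(\sqrt{\rho}\, f_{s,b(g)}
          + \sqrt{1-\rho}\,\epsilon_{sg}\right)
          + \delta\,\mathbf{1}[\text{cancer}_s]\,\mathbf{1}[g \in S],$$
with tissue means $\mu_{t,g} \sim U(0.2, 0.8)$, one latent factor per
gene block giving within-block correlation exactly $\rho$, a cancer mean
shift $\delta$ on the first block $S$, and covariates (age
$\sim N(60, 12^2)$ clipped to $[18, 95]$, balanced gender, balanced
tissue allocation, an exact cancer fraction). Values are min–max scaled
per gene to $[0,1]$; the scaling is linear and therefore preserves all
within-tissue correlations. Defaults (600 samples, 200 genes, 6 tissues,
blocks of 20 at $\rho = 0.7$, cancer fraction 0.5, shift 0.15, noise
0.08) were chosen once as a realistic desk-scale rendering of a large
multi-tissue cohort.

What the simulator does *not* reproduce: heavy-tailed count noise,
library-size artifacts, batch effects, tissue-dependent cancer
signatures, or the $\sim$20 000-gene dimensionality. A green test on
simulated data therefore establishes that an algorithm is implemented
correctly and behaves in the right direction — not that its
transcriptome-scale performance matches any published number.

# Normalization

Raw expression passes through $\log_2(1+x)$ and per-gene min–max scaling
to $[0,1]$, fitted on the training split and clipped outside it; the
protocol this package follows presupposes normalized data without
specifying the transform, and a bounded range both matches the bounded
generator output and makes "Gaussian noise with variance 0.1" meaningful.
Fitted statistics are retained for inversion. A dataset already flagged
normalized skips the log step; this makes `normalize_expression`
*exactly* idempotent on its own output — with the log step applied
unconditionally, idempotence would be false (the log is nonlinear on
$[0,1]$), which is why the flag exists. Constant genes map to 0 with a
warning rather than an error. Split sizes use round-to-nearest
(9749 samples at one-sixth fractions give 6499/1625/1625; floor would
give 1624). Stratification by tissue is the default for classification
experiments — whether the original cohort splits were stratified is not
stated anywhere, so this is flagged as a choice.

# Numerical and degenerate-input policy

- GAN losses clamp probabilities to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-7}$; inputs outside $[0,1]$ are a domain error.
- Gradient-penalty norms divide by $\max(\lVert g\rVert, 10^{-12})$.
- The Fréchet square root truncates negative eigenvalues at 0; the result
  is floored at 0.
- k-NN radii exclude the self pair; AA ties resolve as "not farther".
- Noise-augmented and generated values are clipped to $[0,1]$ at the
  *output* boundary (generation, augmentation); clipping is not applied
  inside the training graph, where it would zero gradients.
- Attention on genes with no masked partner reduces to the self pair.
- A non-finite training loss aborts with the epoch and loss components.
- Every seeded operation saves and restores the caller's RNG state, and
  the training stream is re-seeded after network construction so that
  optional parameter blocks (attention) do not shift the batch sequence —
  this is what makes the "$\gamma$ fixed at 0 equals the attention-free
  run" property hold bit-for-bit.

# Open choices made here

- **Permutation null for reverse validation.** A single uniformly random
  label permutation keeps a chance agreement $\neq 1/2$ with the true
  labels, and training on symmetrically noisy labels still generalizes;
  empirically single-permutation reverse validation scatters far outside
  the binomial band around 0.5. The package's null therefore reassigns
  labels orthogonally to the true classes (exactly half of each class
  relabelled) and averages over permutation seeds — the exact null the
  binomial band presumes.
- **Attention applied once, at the output.** The source protocol
  describes attention as polishing the primary generator output; a single
  final layer is implemented, and nothing deeper is guessed.
- **PPI scores are confidences**; the default `min_score = 0` keeps all
  supplied edges, since no published cutoff exists for the protocol.
- **Config files are JSON** (the R stack here has no YAML parser);
  checkpoints are RDS plus a JSON sidecar carrying the config snapshot,
  seed and loss history.

# Known limitations

Training is single-threaded base-R matrix algebra: ample for hundreds of
genes (the scales all tests run at), workable but slow at transcriptome
scale. The attention layer's memory is linear in the number of masked
pairs, as designed, but the simulator and metrics materialize dense
distance or correlation matrices and so assume desk-scale inputs (the AA
subsample cap mitigates the largest of these). No VAE baselines,
multi-head or dot-product attention, or hyperparameter search are
included; fixed documented defaults replace the published grids.
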