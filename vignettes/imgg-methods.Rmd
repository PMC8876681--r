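---
title: "Methods: graph-guided intermediate-batch correction with a WGAN-GP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-guided intermediate-batch correction with a WGAN-GP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `imgg`, the choices made where
the design was genuinely open, and what the package's tests do and do
not establish.

## Model overview

`imgg` corrects batch effects in scRNA-seq by learning a map from every
batch onto a *synthetic intermediate batch*, rather than onto one
preselected anchor batch. The intermediate batch is defined locally:
cohorts of mutually similar cells from different batches are identified
through connected graphs of mutual-nearest-neighbor (MNN) pairs, and
each cohort's synthesis point (elementwise mean, max or min of its
members' expression) is a sample of the intermediate batch. A generator
network trained with a Wasserstein GAN objective plus a reconstruction
term then transports all cells toward that distribution.

The key assumption is the standard MNN one: across batches there exist
shared biological states, and for cells in such states the nearest
cross-batch neighbors in PCA space are biologically matched rather than
artifacts. Cells of batch-specific types simply do not acquire MNN
partners, are absent from the graphs, and are corrected only through
the generator's global map — which is why the method tolerates
non-overlapping designs.

## Preprocessing

Order of operations: gene-prefix filter (`ERCC`, `MT-`, `mt-`,
case-sensitive, anchored at position 0) → cell filter (≥ 600 expressed
genes) → gene filter (≥ 3 expressing cells) → selection of 2000 highly
variable genes → per-cell depth normalization → `log1p` → PCA. The
pipeline applies these exactly once and in this order; a test asserts
the sequencing (normalization must precede the log, HVG selection runs
on the filtered counts).

HVG selection ranks genes by *normalized dispersion*: dispersion =
variance/mean per gene, z-scored within 20 equal-width bins of mean
expression; a gene alone in its bin is scored against its own
dispersion (normalized dispersion 1), so extreme-mean genes are neither
favored nor silently dropped. Selection is computed once on the
concatenated multi-batch matrix — the preprocessing is a single pass,
not per batch. Normalization scales each cell to `target_sum = 1e4`
(the ecosystem convention; no exclusion of highly expressed genes from
the size factor). PCA is computed by SVD of the gene-centered matrix,
without scaling, with `n_pcs = 50` by default (configurable; the
dimensionality is an ecosystem default, not a tuned value).

## Cross-batch graphs

The MNN search runs `n_rounds = 3` times (early-stopping on an empty
round); each round samples at most `sample_cap = 3000` not-yet-paired
cells per batch and removes newly paired cells afterwards. Repetition
with removal increases the diversity of paired cells; the cap bounds
the per-round cost. Defaults `k_mnn = 20` and within-batch `k = 10`
follow common MNN practice; both are exposed.

Graph assembly: every MNN pair is an edge; closed-loop and transmitting
connections are exactly the connected components of that edge set, so
they need no special casing. The *weak transmitting* rule adds an edge
B–C when same-batch anchors A, A′ are **mutual** members of each
other's within-batch k-NN lists and have MNN partners B, C lying in two
distinct further batches. Mutual membership (rather than
one-directional) was chosen for symmetry with the MNN construction
itself; a flag restores the looser reading. Components spanning a
single batch are discarded. By construction the weak rule only merges
components, never splits them (a property test asserts this
coarsening).

Cohort draws pick a component with probability proportional to its cell
count — larger, better-supported components contribute proportionally
more training pairs — then one uniform cell per batch present in the
component. Nearest-neighbor search is exact (dense distance
computations); at the package's intended problem sizes (thousands of
cells after per-round capping at 3000) exact search is both faster to
validate and trivially satisfies any recall contract.

## Intermediate-batch synthesis

Sources and targets live in the normalized-log HVG space (the graphs
are found in PCA space, then mapped back to HVG space). For each cohort
draw, every member's expression vector becomes one training source, all
sharing the cohort's synthesis target. `Mean` equalizes batch
differences without leaving the observed range; `Max` combines the
sensitivity of different protocols; `Min` is included for completeness.
The default sampling budget is 5 draws per component, capped at 100,000
training rows.

## WGAN-GP

* Generator: residual fully connected blocks
  (Linear → BatchNorm → Mish), additive skips across equal-width
  blocks, a full-width skip from the input to the pre-activation
  output, and a final ReLU guaranteeing non-negative expression.
  Default hidden widths `c(1024, 1024)`.
* Critic: fully connected LeakyReLU(0.2) network with a scalar,
  unconstrained output and **no normalization layers** — batch
  normalization would couple samples and invalidate the per-sample
  gradient penalty. The critic's activation had to be chosen (only the
  generator's blocks are prescribed); LeakyReLU is the standard WGAN-GP
  critic activation and, being piecewise-linear, admits an *exact*
  analytic double-backprop for the penalty: the second derivative of
  the activation vanishes almost everywhere, so only the explicit
  weight appearances in the backward recursion contribute, and biases
  receive zero penalty gradient. Finite-difference tests verify all
  gradients.
* Losses: critic `E[D(x̃)] − E[D(x)] + λ E[(‖∇_x̂D(x̂)‖₂ − 1)²]` with
  `λ = 10` (the WGAN-GP reference default) and x̂ uniform per-sample
  interpolates between target and generated vectors (a flag moves the
  penalty to the generated samples instead, matching a literal reading
  of the adversarial loss's penalty distribution); generator
  `−E[D(x̃)] + rec_weight · E[‖x̃ − x‖₂] · n` with `rec_weight = 1`.
  The reconstruction norm is the per-sample Euclidean norm times the
  gene count `n` (not RMSE × n), the literal reading of the loss as
  written.
* Optimization: Adam, learning rate 0.0002, β = (0.5, 0.9) (GAN
  convention), 5 critic steps per generator step, batch size 256,
  300 epochs by default; all exposed. Training is bit-reproducible
  given the seed (pure CPU matrix code, single RNG stream).
* Correction runs the generator in evaluation mode (BatchNorm frozen at
  running statistics), so a cell's corrected value does not depend on
  which other cells are corrected alongside it, and cells outside any
  cohort are corrected too.

Numerical guards: per-sample gradient norms are floored at 1e-12 before
division; reconstruction gradients likewise; non-finite losses abort
training with a diagnostic rather than continuing silently.

## Evaluation metrics

Scores follow the convention that higher is better on every axis:
`1 − ASW_batch` and `ASW_celltype` (silhouette, Euclidean),
`1 − ARI_batch` and `ARI_celltype` (k-means with k = number of common
cell types, 10 restarts, fixed seed — the clustering algorithm is a
package choice), `1 − cLISI` and `iLISI`. Raw LISI (perplexity-30
Gaussian-kernel inverse Simpson index over the 3×perplexity nearest
neighbors) lies in [1, K]; it is rescaled to [0, 1] via
`(L − 1)/(K − 1)` so that the `1 − cLISI` complement is meaningful.
Metrics on wide corrected matrices are computed after reduction to 20
PCs (distance-based scores on 2000-dimensional vectors are noisy); a
flag scores the raw space. When cell-type labels are present, scoring
is restricted to types observed in **every** batch; batch-specific
cells are excluded from scoring only, never from correction.

## Synthetic data

The simulator draws per-gene log-normal base means, multiplicative
log-normal DE factors for a `de_fraction` subset of genes per type,
multiplicative log-normal *batch* factors on all genes
(`batch_effect_scale` is their log-sd), gamma per-cell library sizes,
and negative-binomial counts (`size = 10`, a typical scRNA-seq
overdispersion). It emulates the features the pipeline must respond
to — shared types across batches, gene-level multiplicative batch
distortion, realistic count noise — but not ambient RNA, doublets,
dropout beyond NB sampling, nor batch effects that are nonlinear in
log space. Passing the end-to-end tests therefore shows the machinery
behaves as designed under multiplicative batch distortion; it is not a
claim about every real-data regime.

## Test problem sizes

The end-to-end study configuration used by the tests and by
`scripts/acceptance.R` is: 2 batches × 1000 cells, 500 genes, 3 shared
types, batch-factor log-sd 1.0; pipeline with 300 HVGs, 30 PCs,
generator 256/256, critic 128/128, 100 epochs, batch size 256. One
hundred epochs is where the reconstruction loss plateaus at this scale;
identity-recovery experiments use 500 cells × 200 genes. These sizes
were chosen so the whole suite runs in a few minutes on one CPU while
leaving every qualitative conclusion unchanged at larger scale.

## Known limitations

* The graphs deliberately do not cover all cells; coverage buys speed,
  and uncovered cells rely on the generator generalizing.
* One unconditional generator serves all batches; there is no
  batch-specific conditioning.
* The corrected output is an expression matrix; the method does not
  claim a meaningful low-dimensional latent representation.
* Exact neighbor search scales quadratically per round; the per-round
  3000-cell cap keeps this tractable, but an approximate-NN backend
  would be needed for atlas-scale single rounds.
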