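---
title: "DGFSD: methods, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DGFSD: methods, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

DGFSD assesses in-hospital mortality risk for ICU sepsis patients from a
patient-by-indicator matrix $S \in \mathbb{R}^{n \times d}$ (rows:
admissions; columns: worst-value laboratory measurements and vital signs).
Its premise is that septic patients accumulate too little individual record
for purely per-patient models, so the model also exploits the *similarity
structure* between diagnosed patients and patients still to be assessed.

**Patient similarity graph.** Pairwise similarity uses the Gaussian kernel

$$X_{ij} = \exp\!\left(-\tfrac{1}{2}\lVert S_i - S_j\rVert^2\right),$$

computed on z-scored indicators. Each patient nominates its top-$k$ most
similar peers (default $k = 10$); the edge set is the union of nominations,
giving an undirected graph in which every node has degree at least $k$.
With self-loops added, $\tilde A = A + I$ and degree matrix
$\tilde D_{ii} = \sum_j \tilde A_{ij}$, every propagation step uses the
symmetric normalization $\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}$,
whose spectral radius is at most 1.

**Two coupled towers.** An autoencoder learns each patient's individual
representation, $H^{(l)} = \phi(H^{(l-1)} W_e^{(l)} + b_e^{(l)})$ with
$H^{(0)} = S$, a mirrored decoder (linear final layer) reconstructing $S$;
and a GCN learns the structural representation,
$G^{(1)} = \phi(\hat A\, S\, W^{(1)})$ and

$$\tilde G^{(l-1)} = (1-\epsilon)\, G^{(l-1)} + \epsilon\, H^{(l-1)}, \qquad
G^{(l)} = \phi(\hat A\, \tilde G^{(l-1)} W^{(l)}),$$

so the per-patient representation is re-injected into the graph propagation
at every layer. The equilibrium coefficient is fixed at $\epsilon = 0.5$ —
both representations equally weighted, no extra hyperparameter search. The
final layer maps the fused representation to two units (survived / died) and
row-normalizes, giving a probability $P_h$ of death per patient.

**Training.** The regime is transductive: the graph spans training and test
patients alike, but only training labels enter the loss

$$\mathcal{L} = \mathrm{CE}\big(\mathrm{output}_{\text{labeled}},\,
y_{\text{labeled}}\big) + \lambda\, \mathrm{MSE}(\hat S, S),$$

minimized full-batch by Adam. The reconstruction term spans all nodes by
default (an unsupervised signal from unlabeled patients; restrictable to
labeled nodes via `recon_nodes`). Optional autoencoder-only pretraining
(default 50 epochs) precedes joint training.

## Design decisions

Several pieces of the architecture are underdetermined and were fixed as
follows; all are exposed as arguments.

* **Output normalization.** A ReLU output layer cannot be a probability
  distribution. The final layer is therefore a two-unit row softmax; the
  representation entering it is the fused representation of the last hidden
  layer.
* **Propagation operator.** The symmetric normalization
  $\tilde D^{-1/2}\tilde A\tilde D^{-1/2}$ is used in *every* layer,
  including the first.
* **Loss and optimizer.** Cross-entropy on labeled nodes plus
  $\lambda \cdot$ reconstruction MSE ($\lambda = 1$ by default), Adam at
  learning rate $10^{-3}$, 200 epochs, early stopping with patience 20 on
  the training loss (best parameters kept). Training is deterministic given
  the seed: full batch, no dropout, seeded Glorot-uniform initialization.
* **Activation.** $\phi =$ ReLU in all hidden layers. A consequence worth
  knowing: very narrow layers can be initialized dead (all pre-activations
  negative); with a width-1 bottleneck this happens for a noticeable share
  of seeds, and the reconstruction then plateaus at the bias-only solution.
* **Layer sizes.** Encoder $d \to 64 \to 32 \to 16$, mirrored decoder, GCN
  $d \to 64 \to 32 \to 16 \to 2$; encoder and GCN widths must match for the
  fusion to be conformable.
* **Prediction.** Hard labels by arg-max over the two outcome columns; a
  tie (probability exactly 0.5) resolves to "survived".
* **Graph defaults.** $k = 10$: sparse at realistic cohort sizes yet
  comfortably connected at the sizes used here. Similarity ties break toward
  the smaller patient index, making graph construction fully deterministic.
* **SMOTE placement.** Oversampling is applied to the *training* partition
  only: balancing before the split would leak interpolated copies of test
  patients into training. SMOTE-synthetic rows also never become graph nodes
  (they are not patients); classical baselines and the importance ranking
  train on the balanced data, and evaluation is always on the untouched,
  un-oversampled test set.
* **Missingness filter.** "More than 30% missing" is read strictly: an
  indicator missing in exactly 30% of patients is retained.
* **Scaling.** Indicators are z-scored with train-fitted statistics before
  similarity and modelling — the Euclidean kernel is scale-sensitive, and
  raw clinical units would let wide-ranged indicators (ALP, glucose)
  dominate narrow ones (pH).
* **Core indicators.** Gain-based importance from a gradient-boosted tree
  ensemble fitted on SMOTE-balanced training data; the top 12 of the 21
  baseline indicators form the core set, after optional expert-override
  inclusions/exclusions (the harness models expert input as an explicit
  list, since no algorithm for it exists).
* **Ablations.** `DGFSD-G` uses *only* similarity-graph structure: the GCN
  runs on identity (one-hot) node features with fusion and reconstruction
  off — pure label propagation. `DGFSD-D-LR` uses *only* individual
  information: an autoencoder on the features with a logistic classifier on
  its bottleneck. All models share cohort, split, graph and seed.

## The synthetic cohort generator

Real credentialed ICU data cannot ship with a package, so every stage is
exercised on synthetic cohorts whose ground truth is known. The generator
emulates the *structure* of a sepsis ICU cohort, not its numbers:

* outcomes drawn Bernoulli with death rate 0.204 by default, the mortality
  scale typical of large sepsis cohorts;
* per-outcome indicator mean profiles from a packaged 21-indicator schema
  (plausible clinical units; placeholders, not estimates of any real
  cohort);
* latent sub-phenotype clusters *within* each outcome class, with centroid
  separation `graph_signal_strength`, measured in units of the
  within-cluster RMS radius — this is what makes nearest-neighbour graphs
  carry label signal;
* missingness injected completely at random, plus designated indicators
  forced strictly above the 30% filter threshold.

Two centroid layouts exist. `"random"` draws each cluster offset
independently. `"xor"` (two clusters per class) interleaves the classes at
the corners of a square in a random 2-D subspace: neighbourhoods remain
label-informative while the classes are *not* linearly separable in feature
space. The xor layout exists because with random draws in $d \approx 20$
dimensions, cluster identity is almost surely linearly decodable, so a
"graph-only" condition built from random centroids would leak its signal to
linear feature models and could not isolate the graph's contribution.

What the generator does **not** emulate: real marginal distributions (heavy
tails, detection limits), informative missingness, repeated measurements,
treatment effects, or inter-site variation. Passing tests therefore
demonstrate correctness of the pipeline and the *qualitative* behaviour of
the models under controlled signal, not clinical performance.

## Study scenarios and what the tests check

The test suite evaluates four preset scenarios at $n = 1000$ (700 train /
300 test) over five fixed seeds — sizes chosen so the whole suite runs
comfortably on a single CPU while keeping the binomial noise of a 300-patient
test set (~±0.03 per seed) small against the effects of interest:

* **both_signal** — half-strength outcome contrasts plus clusters at
  separation 0.8: DGFSD should do at least as well as both ablations.
* **graph_only** — no mean contrast, xor clusters at 0.8: DGFSD must beat
  the feature-only ablation by more than 5 accuracy points.
* **feature_only** — contrasts only, no clusters: DGFSD and the no-graph
  ablation should agree within 5 points (the graph adds nothing).
* **null** — no contrast, no clusters, *balanced* outcome, labels shuffled:
  every model should sit within 0.5 ± 0.08. The null cohort is balanced
  because chance-level accuracy equals the majority-class frequency;
  at a 20% death rate a majority guesser scores 0.8 and "accuracy 0.5" would
  be the wrong chance reference.

A caveat the package states plainly: because the similarity graph is *built
from* the feature matrix, the two information channels are never independent
on these Gaussian cohorts — wherever one channel's signal is strong, either
ablation alone approaches the attainable accuracy, and the full fused model
tracks the better ablation rather than exceeding it by a wide margin. The
dual-signal comparison is therefore a weak-dominance check, not a
large-margin one; margins of a percent or two on a single split are seed
noise.

## Numerical choices

* Kernel distances are computed via the cross-product identity with negative
  values clamped at zero; the matrix is symmetrized and its diagonal set to
  exactly 1. Kernel and normalized adjacency agree with brute-force dense
  computations to $10^{-12}$.
* Softmax and cross-entropy use the log-sum-exp form; gradients are analytic
  (verified against central finite differences away from ReLU kinks, where
  the subgradient convention legitimately differs from a finite difference).
* Constant indicator columns get scale 1 during z-scoring rather than
  dividing by zero.
* Checkpoints serialize weights as JSON at 17 significant digits, which
  round-trips IEEE-754 doubles bit-exactly.
* SMOTE neighbour search is an exact Euclidean distance matrix over the
  minority class; $k$ is capped at minority size minus one, and a singleton
  minority falls back to duplication with a warning.

## Limitations

* Accuracy is the only metric, matching the evaluation design this package
  follows; no AUROC or calibration is reported.
* Full-batch dense training is intended for desk-scale cohorts (up to a few
  thousand patients); there is no minibatching or approximate
  nearest-neighbour search.
* The synthetic generator's Gaussian structure makes the graph and feature
  channels partially redundant (see above); demonstrating a large fusion
  advantage requires data whose similarity structure carries information the
  per-patient features do not — which is precisely the situation claimed for
  real clinical records and which synthetic Gaussians cannot fully imitate.
* Model interpretability is out of scope.
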