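# dgfsd

Mortality-risk assessment for ICU sepsis patients with an autoencoder-fused
graph convolutional network.

## The problem

Sepsis kills roughly one in five of the ICU patients it affects, and the
short, information-poor clinical record of a rapidly deteriorating patient
makes individual-level risk models unreliable. `dgfsd` implements **DGFSD**, a
semi-supervised deep model that compensates for thin individual records by
borrowing strength from *similar* patients: a patient-similarity graph links
each admission to the ones with the most alike laboratory and vital-sign
profiles, and a graph convolutional network (GCN) propagates outcome
information across that graph while an autoencoder keeps each patient's
individual representation in the loop.

The package ships the whole surrounding study pipeline so the method can be
exercised end to end on synthetic cohorts with known ground truth:

* **Synthetic cohorts** — class- and cluster-conditional Gaussian indicator
  profiles (about 20.4% mortality), latent sub-phenotype clusters that give
  the similarity graph its signal, and injected missingness, including whole
  indicators missing in more than 30% of patients.
* **Preprocessing** — indicator-level missingness filtering (strictly more
  than 30% missing drops the indicator), population reference-value
  imputation, stratified 7:3 train/test split with train-fitted z-scoring,
  and SMOTE oversampling of the minority (death) class.
* **Similarity graph** — Gaussian kernel `X_ij = exp(-||S_i - S_j||^2 / 2)`,
  union-symmetrized top-k neighbourhoods, and the renormalized propagation
  operator `A_hat = D~^{-1/2} (A + I) D~^{-1/2}`.
* **DGFSD model** — encoder layers `H(l) = relu(H(l-1) We + be)` with a
  mirrored decoder, GCN layers `G(l) = relu(A_hat G~(l-1) W(l))`, and the
  layer-wise fusion `G~(l) = (1 - eps) G(l) + eps H(l)` with `eps = 0.5`;
  trained full-batch and transductively (test nodes in the graph, their
  labels withheld) on cross-entropy plus a reconstruction penalty.
* **Evaluation harness** — accuracy `ACC = (S_r + D_r) / (S_r + D_r + S_f +
  D_f)`, gradient-boosting importance ranking with top-12 core-indicator
  selection and expert overrides, decision-tree / KNN / logistic-regression
  baselines, and the two ablations `DGFSD-G` (graph structure only) and
  `DGFSD-D-LR` (individual features only).

## Worked example

```r
library(dgfsd)

cohort <- generate_cohort(scenario_config("both_signal", n_patients = 500, seed = 42))
cohort
#> patient_table: 500 patients x 21 indicators
#>   deaths: 103 (20.6%)   missing cells: 12.1%

res <- run_pipeline(cohort, seed = 42)
res$dropped_indicators
#> [1] "alp_max"            "serum_calcium_max"  "serum_chloride_max"
res$metrics[, c("model", "acc", "S_r", "D_r", "S_f", "D_f")]
#>        model       acc S_r D_r S_f D_f
#> 1      DGFSD 0.9466667 117  25   2   6
#> 2    DGFSD-G 0.9533333 117  26   2   5
#> 3 DGFSD-D-LR 0.9200000 115  23   4   8
#> 4         DT 0.8866667 109  24  10   7
#> 5        KNN 0.8866667 105  28  14   3
#> 6         LR 0.8933333 109  25  10   6
```

Reading the output: the cohort generator produced 500 admissions over the 21
baseline indicators at the configured ~20% mortality with injected
missingness; three indicators exceeded the 30% missingness cutoff and were
dropped before imputation. On the held-out 150-patient test set the
graph-based models (DGFSD and the structure-only DGFSD-G) beat the
feature-only ablation and all three classical baselines; `S_r`/`D_r` count
correctly classified survivors/decedents and `S_f`/`D_f` the two error types.
Single-split differences of a percent or two between DGFSD and DGFSD-G are
within seed noise; the test suite compares them as means over five seeds.

A thin command-line front end over the same functions is installed at
`inst/scripts/dgfsd-cli.R` (subcommands `simulate`, `preprocess`, `graph`,
`rank`, `train`, `predict`, `evaluate`, `ablate`).

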