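#' Preset synthetic study scenarios
#'
#' Named cohort configurations used throughout the test harness, each isolating
#' one source of signal:
#' \describe{
#'   \item{both_signal}{outcome-conditional mean profiles (the packaged
#'     schema's survivor/decedent contrasts at half strength, keeping the
#'     per-patient Bayes accuracy off its ceiling) *and* class-specific latent
#'     clusters (`graph_signal_strength = 0.8`, random centroid layout):
#'     individual features and the similarity graph are both informative.}
#'   \item{graph_only}{class means equalized (survivor profile for everyone)
#'     with separated class-specific clusters in an XOR centroid layout
#'     (`graph_signal_strength = 0.8`): neighbourhoods carry label signal
#'     but the classes are not linearly separable in feature space.}
#'   \item{feature_only}{outcome-conditional means, no cluster structure
#'     (`graph_signal_strength = 0`): the graph is uninformative beyond the
#'     feature signal it reflects.}
#'   \item{null}{no feature signal, no cluster signal, balanced outcome
#'     (`death_rate = 0.5`): every classifier should sit at chance. Balance
#'     matters because chance-level accuracy equals the majority-class
#'     frequency; at 0.5 it is exactly the coin-flip rate.}
#' }
#' All scenarios use 5% cellwise missingness and force about 10% of the
#' indicators above the 30% missingness threshold, so the preprocessing steps
#' are exercised end-to-end.
#'
#' @param scenario Scenario name.
#' @param n_patients Cohort size, default 1000.
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
scenario_config <- function(scenario = c("both_signal", "graph_only",
                                         "feature_only", "null"),
                            n_patients = 1000L, seed = 1L) {
  scenario <- match.arg(scenario)
  schema <- default_schema()
  no_feature <- schema
  no_feature$decedent_mean <- no_feature$survivor_mean
  half_feature <- schema
  half_feature$decedent_mean <- half_feature$survivor_mean +
    0.5 * (half_feature$decedent_mean - half_feature$survivor_mean)
  switch(scenario,
    both_signal = cohort_config(
      n_patients, schema = half_feature, death_rate = 0.204,
      n_latent_clusters = 2L, graph_signal_strength = 0.8,
      cluster_layout = "random",
      missing_indicator_fraction = 0.1, cellwise_missing_rate = 0.05,
      seed = seed),
    graph_only = cohort_config(
      n_patients, schema = no_feature, death_rate = 0.204,
      n_latent_clusters = 2L, graph_signal_strength = 0.8,
      cluster_layout = "xor",
      missing_indicator_fraction = 0.1, cellwise_missing_rate = 0.05,
      seed = seed),
    feature_only = cohort_config(
      n_patients, schema = schema, death_rate = 0.204,
      n_latent_clusters = 1L, graph_signal_strength = 0,
      missing_indicator_fraction = 0.1, cellwise_missing_rate = 0.05,
      seed = seed),
    null = cohort_config(
      n_patients, schema = no_feature, death_rate = 0.5,
      n_latent_clusters = 1L, graph_signal_strength = 0,
      missing_indicator_fraction = 0.1, cellwise_missing_rate = 0.05,
      seed = seed)
  )
}

#' Shuffle outcome labels (permutation null)
#'
#' Returns the same table with outcome labels randomly permuted across
#' patients, severing any feature-outcome association while preserving the
#' label marginal.
#'
#' @param table A [patient_table()].
#' @param seed Integer seed.
#' @return A [patient_table()].
#' @export
shuffle_labels <- function(table, seed = 1L) {
  stopifnot(inherits(table, "patient_table"))
  set.seed(seed)
  patient_table(values = table$values,
                labels = sample(table$labels),
                patient_ids = table$patient_ids,
                indicator_names = table$indicator_names,
                missing_mask = table$missing_mask)
}

#' Run the full mortality-risk pipeline on one cohort
#'
#' Chains every stage: indicator missingness filtering, reference-value
#' imputation, stratified 7:3 split with train-fitted standardization,
#' SMOTE-balanced importance ranking with core-indicator selection, the
#' classical baselines, and DGFSD with its two ablations on a transductive
#' top-k similarity graph.
#'
#' @param cohort A [patient_table()] (e.g. from [generate_cohort()]).
#' @param reference Reference values for imputation (schema data.frame or
#'   named vector), default the packaged schema.
#' @param missing_threshold Indicator missingness cutoff, default 0.30.
#' @param split_ratio Training fraction, default 0.7.
#' @param k Graph neighbours per node, default 10.
#' @param core_size Core-indicator count, default 12.
#' @param use_core_indicators Restrict modelling to the selected core set
#'   (default FALSE: model on every indicator surviving the filter).
#' @param hidden,epsilon,lambda,epochs,pretrain_epochs,lr,patience DGFSD
#'   settings, see [train_dgfsd()].
#' @param seed Integer seed driving split, SMOTE, ranking and model fits.
#' @return A list with `dropped_indicators`, `split`, `ranking`, `baselines`,
#'   `ablations` and `metrics` (one data.frame over all models).
#' @export
run_pipeline <- function(cohort, reference = default_schema(),
                         missing_threshold = 0.30, split_ratio = 0.7,
                         k = 10L, core_size = 12L,
                         use_core_indicators = FALSE,
                         hidden = c(64L, 32L, 16L), epsilon = 0.5, lambda = 1,
                         epochs = 200L, pretrain_epochs = 50L, lr = 1e-3,
                         patience = 20L, seed = 1L) {
  filt <- filter_indicators(cohort, missing_threshold)
  imputed <- impute_reference(filt$table, reference)
  split <- split_train_test(imputed, split_ratio = split_ratio,
                            standardize = TRUE, seed = seed)
  ranking <- rank_indicators(split$train$values, split$train$labels,
                             core_size = core_size, seed = seed)
  if (use_core_indicators) {
    keep <- match(ranking$core, split$train$indicator_names)
    split$train <- patient_table(
      split$train$values[, keep, drop = FALSE], split$train$labels,
      split$train$patient_ids, ranking$core)
    split$test <- patient_table(
      split$test$values[, keep, drop = FALSE], split$test$labels,
      split$test$patient_ids, ranking$core)
  }
  baselines <- run_baselines(split, seed = seed)
  ablations <- run_ablations(split, k = k, hidden = hidden, epsilon = epsilon,
                             lambda = lambda, epochs = epochs,
                             pretrain_epochs = pretrain_epochs, lr = lr,
                             patience = patience, seed = seed)
  list(dropped_indicators = filt$dropped,
       split = split,
       ranking = ranking,
       baselines = baselines,
       ablations = ablations,
       metrics = rbind(ablations, baselines))
}
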