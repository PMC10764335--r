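# Shared fixture builders and independent dense oracles. The oracles use
# explicit loops / literal arithmetic so they share no code path with the
# package implementation they check.

# schema with tripled outcome contrasts: classes essentially separable
separable_schema <- function() {
  sc <- default_schema()
  sc$decedent_mean <- sc$survivor_mean + 3 * (sc$decedent_mean - sc$survivor_mean)
  sc
}

# brute-force Gaussian kernel, double loop
brute_kernel <- function(S) {
  n <- nrow(S)
  X <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    X[i, j] <- exp(-sum((S[i, ] - S[j, ])^2) / 2)
  X
}

# brute-force symmetric normalization with self-loops, dense
brute_normalize <- function(A) {
  At <- as.matrix(A) + diag(nrow(as.matrix(A)))
  dis <- 1 / sqrt(rowSums(At))
  diag(dis) %*% At %*% diag(dis)
}

# independent plain GCN (no fusion, no autoencoder): relu hidden layers,
# final linear layer + row softmax
plain_gcn <- function(S, A_hat, Wg) {
  Ah <- as.matrix(A_hat)
  h <- as.matrix(S)
  L <- length(Wg)
  for (l in seq_len(L)) {
    h <- Ah %*% h %*% Wg[[l]]
    if (l < L) h <- pmax(h, 0)
  }
  e <- exp(h - apply(h, 1, max))
  e / rowSums(e)
}

# generate a scenario cohort, preprocess it and split it
scenario_split <- function(scenario, n, seed, shuffle = FALSE) {
  tab <- generate_cohort(scenario_config(scenario, n_patients = n, seed = seed))
  if (shuffle) tab <- shuffle_labels(tab, seed = seed + 100L)
  filt <- filter_indicators(tab)
  split_train_test(impute_reference(filt$table), seed = seed)
}

# fully observed toy table with chosen labels
toy_table <- function(n = 20, d = 3, labels = rep(c(0, 1), length.out = n),
                      seed = 1) {
  set.seed(seed)
  patient_table(values = matrix(rnorm(n * d), n, d,
                                dimnames = list(NULL, paste0("ind", seq_len(d)))),
                labels = labels,
                patient_ids = sprintf("T%03d", seq_len(n)))
}
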