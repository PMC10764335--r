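#' Drop indicators with excessive missingness
#'
#' Removes every indicator whose missing fraction exceeds `threshold`
#' (strictly: an indicator missing in exactly `threshold` of patients is
#' retained). Column order of the survivors is preserved.
#'
#' @param table A [patient_table()].
#' @param threshold Missing-fraction cutoff in (0, 1); default 0.30.
#' @return A list with elements `table` (the filtered [patient_table()]) and
#'   `dropped` (character vector of removed indicator names).
#' @export
filter_indicators <- function(table, threshold = 0.30) {
  stopifnot(inherits(table, "patient_table"))
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  miss_frac <- colMeans(!table$missing_mask)
  keep <- miss_frac <= threshold
  if (!any(keep))
    stop("all indicators exceed the missingness threshold; nothing to model")
  out <- patient_table(
    values = table$values[, keep, drop = FALSE],
    labels = table$labels,
    patient_ids = table$patient_ids,
    indicator_names = table$indicator_names[keep],
    missing_mask = table$missing_mask[, keep, drop = FALSE]
  )
  list(table = out, dropped = table$indicator_names[!keep])
}

#' Impute missing cells with population reference values
#'
#' Replaces every missing cell by the indicator's population reference value
#' (the "normal" value a clinician would assume in the absence of a
#' measurement). Observed cells are untouched; afterwards the table is fully
#' observed.
#'
#' @param table A [patient_table()].
#' @param reference Either a schema data.frame (see [read_schema()]) or a named
#'   numeric vector of reference values. Every indicator in `table` must be
#'   covered.
#' @return A fully observed [patient_table()].
#' @export
impute_reference <- function(table, reference = default_schema()) {
  stopifnot(inherits(table, "patient_table"))
  if (is.data.frame(reference)) {
    ref <- stats::setNames(reference$reference_value, reference$indicator)
  } else {
    ref <- reference
  }
  missing_ref <- setdiff(table$indicator_names, names(ref))
  if (length(missing_ref))
    stop("no reference value for indicator(s): ",
         paste(missing_ref, collapse = ", "))
  vals <- table$values
  for (j in seq_along(table$indicator_names)) {
    nm <- table$indicator_names[j]
    fill <- !table$missing_mask[, j]
    if (any(fill)) vals[fill, j] <- ref[[nm]]
  }
  patient_table(values = vals, labels = table$labels,
                patient_ids = table$patient_ids,
                indicator_names = table$indicator_names,
                missing_mask = matrix(TRUE, nrow(vals), ncol(vals)))
}

#' Stratified train/test split with optional train-fitted standardization
#'
#' Splits a fully observed cohort into training and test partitions stratified
#' by outcome, so the death proportion in each partition matches the cohort
#' within one patient per class. When `standardize = TRUE` each indicator is
#' z-scored using the training mean and standard deviation (applied to both
#' partitions); constant training columns get scale 1 to stay finite.
#'
#' @param table A fully observed [patient_table()].
#' @param split_ratio Training fraction in (0, 1); default 0.7.
#' @param standardize Z-score indicators using train statistics (default TRUE).
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `split_cohort`: list with `train` and `test`
#'   [patient_table()]s and `scaler_stats` (per-indicator `center`, `scale`).
#' @export
split_train_test <- function(table, split_ratio = 0.7, standardize = TRUE,
                             seed = 1L) {
  stopifnot(inherits(table, "patient_table"))
  if (!(split_ratio > 0 && split_ratio < 1))
    stop("split_ratio must lie in (0, 1)")
  if (!all(table$missing_mask))
    stop("split requires a fully observed table; impute first")
  if (any(tabulate(table$labels + 1L, 2L) < 2L))
    stop("each outcome class needs at least 2 patients to split")
  set.seed(seed)
  n <- length(table$labels)
  train_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(table$labels == cl)
    n_tr <- round(split_ratio * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx)[seq_len(n_tr)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)

  take <- function(idx, vals) {
    patient_table(values = vals[idx, , drop = FALSE],
                  labels = table$labels[idx],
                  patient_ids = table$patient_ids[idx],
                  indicator_names = table$indicator_names)
  }
  vals <- table$values
  center <- colMeans(vals[train_idx, , drop = FALSE])
  scale_ <- apply(vals[train_idx, , drop = FALSE], 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  if (standardize)
    vals <- sweep(sweep(vals, 2, center), 2, scale_, "/")
  structure(list(
    train = take(train_idx, vals),
    test = take(test_idx, vals),
    scaler_stats = list(center = center, scale = scale_,
                        applied = standardize)
  ), class = "split_cohort")
}

#' @export
print.split_cohort <- function(x, ...) {
  cat(sprintf("split_cohort: train %d (deaths %d) / test %d (deaths %d)%s\n",
              length(x$train$labels), sum(x$train$labels),
              length(x$test$labels), sum(x$test$labels),
              if (isTRUE(x$scaler_stats$applied)) ", standardized" else ""))
  invisible(x)
}

#' SMOTE oversampling of the minority class
#'
#' Balances a binary-labelled feature matrix by synthetic minority
#' oversampling: each synthetic sample is an interpolation `x + u * (nn - x)`,
#' `u ~ Uniform(0, 1)`, between a random minority point `x` and one of its `k`
#' nearest minority neighbours `nn` (Euclidean distance). Original rows are
#' preserved verbatim and synthetic rows are appended, yielding equal class
#' counts.
#'
#' @param x Numeric feature matrix.
#' @param y Binary label vector (0/1), one per row of `x`.
#' @param k Neighbour count (default 5); capped at minority size - 1.
#' @param seed Integer seed.
#' @return List with `x` (augmented matrix), `y` (augmented labels),
#'   `n_synthetic` (rows added) and `synthetic` (logical marker per row).
#' @export
smote_oversample <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y disagree on sample count")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  counts <- tabulate(y + 1L, 2L)
  if (any(counts == 0L))
    stop("SMOTE requires both classes to be present")
  if (k < 1L) stop("k must be >= 1")
  set.seed(seed)
  minority <- if (counts[1L] <= counts[2L]) 0L else 1L
  n_syn <- abs(counts[1L] - counts[2L])
  if (n_syn == 0L)
    return(list(x = x, y = as.integer(y), n_synthetic = 0L,
                synthetic = rep(FALSE, nrow(x))))
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min == 1L) {
    warning("minority class has a single member; duplicating it instead of interpolating")
    syn <- x[rep(min_idx, n_syn), , drop = FALSE]
  } else {
    k_eff <- min(as.integer(k), n_min - 1L)
    xm <- x[min_idx, , drop = FALSE]
    dm <- as.matrix(stats::dist(xm))
    diag(dm) <- Inf
    # k nearest minority neighbours per minority point, ties by smaller index
    nn <- do.call(rbind, lapply(seq_len(n_min),
                                function(i) order(dm[i, ])[seq_len(k_eff)]))
    base <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_eff, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    syn <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  list(x = rbind(x, syn),
       y = c(as.integer(y), rep(minority, n_syn)),
       n_synthetic = n_syn,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_syn)))
}
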