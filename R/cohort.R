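#' @importFrom stats rbinom rnorm runif
NULL

#' Read an indicator schema
#'
#' A schema describes each clinical indicator by its outcome-conditional means
#' (survivors vs. decedents), a common within-class standard deviation, and a
#' population reference value used for imputing missing measurements.
#'
#' @param path Path to a YAML schema file with a top-level `indicators` mapping
#'   of `name: {survivor_mean, decedent_mean, sd, reference_value}`. Indicator
#'   order in the file is preserved.
#' @return A data.frame with columns `indicator`, `survivor_mean`,
#'   `decedent_mean`, `sd`, `reference_value`.
#' @seealso [default_schema()] for the packaged 21-indicator baseline schema.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$indicators) || length(raw$indicators) == 0L)
    stop("schema file has no 'indicators' entries: ", path)
  ind <- raw$indicators
  need <- c("survivor_mean", "decedent_mean", "sd", "reference_value")
  for (nm in names(ind)) {
    miss <- setdiff(need, names(ind[[nm]]))
    if (length(miss))
      stop("schema indicator '", nm, "' lacks field(s): ",
           paste(miss, collapse = ", "))
  }
  out <- data.frame(
    indicator       = names(ind),
    survivor_mean   = vapply(ind, function(x) as.numeric(x$survivor_mean), 0),
    decedent_mean   = vapply(ind, function(x) as.numeric(x$decedent_mean), 0),
    sd              = vapply(ind, function(x) as.numeric(x$sd), 0),
    reference_value = vapply(ind, function(x) as.numeric(x$reference_value), 0),
    row.names = NULL
  )
  validate_schema(out)
  out
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema))
  if (anyDuplicated(schema$indicator))
    stop("schema indicator names must be unique")
  if (any(!is.finite(schema$sd)) || any(schema$sd <= 0))
    stop("schema standard deviations must all be positive")
  invisible(schema)
}

#' Packaged baseline indicator schema
#'
#' Returns the default schema of 21 baseline indicators (worst-value laboratory
#' measurements plus age) commonly used for ICU sepsis mortality-risk
#' modelling. The numeric values are plausible placeholders in conventional
#' clinical units, intended to drive the synthetic cohort generator; they are
#' not estimates from any real cohort.
#'
#' @return A schema data.frame, see [read_schema()].
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "indicator_schema.yaml",
                          package = "dgfsd", mustWork = TRUE))
}

#' Configuration for a synthetic sepsis-like cohort
#'
#' The generator draws a cohort from a class- and cluster-conditional Gaussian
#' model: each patient gets a binary outcome (died = 1) with probability
#' `death_rate`, is assigned uniformly to one of `n_latent_clusters`
#' sub-phenotype clusters *within its outcome class*, and its indicator vector
#' is drawn from a normal centred on the class mean plus a cluster-specific
#' centroid offset. Because clusters are class-specific, nearest-neighbour
#' graphs over the indicators carry label signal whenever
#' `graph_signal_strength > 0`.
#'
#' @param n_patients Number of ICU admissions to simulate.
#' @param schema Indicator schema data.frame (see [read_schema()]); defaults to
#'   the packaged 21-indicator schema.
#' @param death_rate Probability of in-hospital death; default 0.204, the
#'   approximate mortality of large sepsis ICU cohorts.
#' @param n_latent_clusters Sub-phenotype clusters per outcome class (>= 1).
#' @param graph_signal_strength Separation of cluster centroids from the class
#'   mean, in units of the within-cluster root-mean-square radius (0 = clusters
#'   indistinguishable).
#' @param cluster_layout `"random"` draws each centroid offset independently;
#'   `"xor"` (requires exactly 2 clusters per class) interleaves the two
#'   classes' centroids at the corners of a square in a random 2-D subspace, so
#'   cluster structure is informative for a neighbourhood graph but the classes
#'   are not linearly separable in indicator space.
#' @param missing_indicator_fraction Fraction of indicators forced to have
#'   strictly more than 30% missing cells (emulating indicators that fail the
#'   usual missingness filter).
#' @param cellwise_missing_rate Independent per-cell missingness rate applied
#'   to all indicators.
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          schema = default_schema(),
                          death_rate = 0.204,
                          n_latent_clusters = 2L,
                          graph_signal_strength = 1.5,
                          cluster_layout = c("random", "xor"),
                          missing_indicator_fraction = 0,
                          cellwise_missing_rate = 0,
                          seed = 1L) {
  cluster_layout <- match.arg(cluster_layout)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("n_patients must be a positive integer")
  validate_schema(schema)
  if (!(death_rate > 0 && death_rate < 1))
    stop("death_rate must lie in (0, 1)")
  if (n_latent_clusters < 1)
    stop("n_latent_clusters must be >= 1")
  if (graph_signal_strength < 0)
    stop("graph_signal_strength must be nonnegative")
  if (cluster_layout == "xor" && n_latent_clusters != 2L)
    stop("cluster_layout = 'xor' requires exactly 2 clusters per class")
  if (missing_indicator_fraction < 0 || missing_indicator_fraction >= 1)
    stop("missing_indicator_fraction must lie in [0, 1)")
  if (cellwise_missing_rate < 0 || cellwise_missing_rate >= 1)
    stop("cellwise_missing_rate must lie in [0, 1)")
  structure(list(
    n_patients = as.integer(n_patients),
    schema = schema,
    death_rate = death_rate,
    n_latent_clusters = as.integer(n_latent_clusters),
    graph_signal_strength = graph_signal_strength,
    cluster_layout = cluster_layout,
    missing_indicator_fraction = missing_indicator_fraction,
    cellwise_missing_rate = cellwise_missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Construct a patient table
#'
#' The central data container: an n x d matrix of indicator values (`NA` where
#' unobserved) with an observation mask, binary outcome labels and patient
#' identifiers.
#'
#' @param values n x d numeric matrix; `NA` entries are missing.
#' @param labels Length-n binary outcome vector (0 = survived, 1 = died).
#' @param patient_ids Length-n unique identifiers.
#' @param indicator_names Length-d indicator names (default: column names of
#'   `values`).
#' @param missing_mask Optional n x d logical matrix, `TRUE` = observed;
#'   derived from `is.na(values)` when omitted.
#' @return An object of class `patient_table`.
#' @export
patient_table <- function(values, labels, patient_ids,
                          indicator_names = colnames(values),
                          missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); d <- ncol(values)
  if (is.null(indicator_names) || length(indicator_names) != d)
    stop("indicator_names must name all ", d, " columns")
  if (anyDuplicated(indicator_names))
    stop("indicator names must be unique")
  if (length(labels) != n || !all(labels %in% c(0, 1)))
    stop("labels must be a length-n vector over {0, 1}")
  if (length(patient_ids) != n)
    stop("patient_ids must have one entry per row")
  if (anyDuplicated(patient_ids))
    stop("duplicate patient id: ",
         patient_ids[duplicated(patient_ids)][1L])
  if (is.null(missing_mask)) missing_mask <- !is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop("missing_mask must match the dimensions of values")
  if (any(!is.finite(values[missing_mask])))
    stop("observed cells must be finite")
  dimnames(values) <- list(NULL, indicator_names)
  dimnames(missing_mask) <- list(NULL, indicator_names)
  structure(list(
    values = values,
    missing_mask = missing_mask,
    labels = as.integer(labels),
    indicator_names = as.character(indicator_names),
    patient_ids = as.character(patient_ids)
  ), class = "patient_table")
}

#' @export
print.patient_table <- function(x, ...) {
  n <- length(x$patient_ids); d <- length(x$indicator_names)
  miss <- if (n * d) mean(!x$missing_mask) else 0
  cat(sprintf("patient_table: %d patients x %d indicators\n", n, d))
  cat(sprintf("  deaths: %d (%.1f%%)   missing cells: %.1f%%\n",
              sum(x$labels), 100 * mean(x$labels), 100 * miss))
  invisible(x)
}

#' @export
dim.patient_table <- function(x) dim(x$values)

#' Generate a synthetic sepsis-like cohort
#'
#' Draws outcomes, latent sub-phenotype clusters, indicator values and missing
#' cells according to a [cohort_config()]. The latent cluster assignment (the
#' generator's ground truth) is attached as attribute `"clusters"`, and the
#' names of the indicators designated to exceed 30% missingness as attribute
#' `"high_missing_indicators"`.
#'
#' @param config A [cohort_config()].
#' @return A [patient_table()].
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config object")
  set.seed(config$seed)
  n <- config$n_patients
  schema <- config$schema
  d <- nrow(schema)
  m <- config$n_latent_clusters
  gss <- config$graph_signal_strength

  labels <- rbinom(n, 1L, config$death_rate)
  clusters <- sample.int(m, n, replace = TRUE)

  # centroid offsets in standardized (per-sd) coordinates: one d-vector per
  # (class, cluster); expected norm gss * sqrt(d) in both layouts
  offsets <- array(0, dim = c(2L, m, d))
  if (gss > 0) {
    if (config$cluster_layout == "random") {
      for (cl in 1:2) for (g in seq_len(m))
        offsets[cl, g, ] <- rnorm(d, 0, gss)
    } else { # xor: square corners in a random 2-D subspace, classes interleaved
      u <- rnorm(d); u <- u / sqrt(sum(u^2))
      v <- rnorm(d); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
      delta <- gss * sqrt(d) / sqrt(2)
      offsets[1, 1, ] <- delta * (u + v)
      offsets[1, 2, ] <- -delta * (u + v)
      offsets[2, 1, ] <- delta * (u - v)
      offsets[2, 2, ] <- -delta * (u - v)
    }
  }

  class_means <- rbind(schema$survivor_mean, schema$decedent_mean) # 2 x d
  values <- matrix(NA_real_, n, d)
  noise <- matrix(rnorm(n * d), n, d)
  for (i in seq_len(n)) {
    cl <- labels[i] + 1L
    values[i, ] <- class_means[cl, ] +
      schema$sd * (offsets[cl, clusters[i], ] + noise[i, ])
  }

  # missingness: MCAR cellwise, plus designated indicators forced above the
  # 30% threshold (realized fraction strictly > 0.30 by construction)
  observed <- matrix(runif(n * d) >= config$cellwise_missing_rate, n, d)
  n_hi <- ceiling(config$missing_indicator_fraction * d)
  hi_idx <- integer(0)
  if (n_hi > 0) {
    hi_idx <- sort(sample.int(d, n_hi))
    for (j in hi_idx) {
      n_miss <- max(floor(0.30 * n) + 1L, round(runif(1, 0.35, 0.55) * n))
      n_miss <- min(n_miss, n)
      observed[sample.int(n, n_miss), j] <- FALSE
    }
  }
  values[!observed] <- NA_real_

  tab <- patient_table(
    values = values,
    labels = labels,
    patient_ids = sprintf("P%06d", seq_len(n)),
    indicator_names = schema$indicator,
    missing_mask = observed
  )
  attr(tab, "clusters") <- clusters
  attr(tab, "high_missing_indicators") <- schema$indicator[hi_idx]
  tab
}

#' Write / read a cohort as CSV
#'
#' The on-disk format is a plain CSV with header
#' `patient_id,<indicator...>,outcome`; an empty field encodes a missing cell
#' and `outcome` is 0 (survived) or 1 (died). Values are written with full
#' double precision (15 significant digits).
#'
#' @param table A [patient_table()].
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   [patient_table()].
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "patient_table"))
  df <- data.frame(patient_id = table$patient_ids,
                   table$values,
                   outcome = table$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "patient_id" ||
      names(df)[ncol(df)] != "outcome")
    stop("malformed cohort CSV: expected header patient_id,<indicators>,outcome")
  ids <- as.character(df$patient_id)
  if (anyDuplicated(ids))
    stop("duplicate patient id in ", path, ": ", ids[duplicated(ids)][1L])
  ind_cols <- names(df)[-c(1L, ncol(df))]
  vals <- df[ind_cols]
  for (j in ind_cols) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) & is.na(suppressWarnings(as.numeric(vals[[j]]))))
      stop("non-numeric cell in column '", j, "', row ",
           if (length(bad)) bad[1L] else "?", " of ", path)
    }
  }
  outcome <- df$outcome
  if (!is.numeric(outcome) || !all(outcome %in% c(0, 1)))
    stop("outcome column must contain only 0/1 in ", path)
  patient_table(values = as.matrix(vals), labels = outcome,
                patient_ids = ids, indicator_names = ind_cols)
}
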