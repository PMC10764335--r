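#' Confusion counts for binary mortality prediction
#'
#' Tallies the four outcomes: `S_r` survivors predicted alive, `D_r` deaths
#' predicted dead, `S_f` survivors predicted dead, `D_f` deaths predicted
#' alive.
#'
#' @param truth True outcome vector (0 = survived, 1 = died).
#' @param pred Predicted outcome vector of the same length.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("truth and pred must be binary 0/1")
  structure(list(
    S_r = sum(truth == 0 & pred == 0),
    D_r = sum(truth == 1 & pred == 1),
    S_f = sum(truth == 0 & pred == 1),
    D_f = sum(truth == 1 & pred == 0)
  ), class = "confusion_counts")
}

#' Classification accuracy
#'
#' \deqn{ACC = (S_r + D_r) / (S_r + D_r + S_f + D_f).}
#'
#' @param counts A [confusion_counts()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$S_r + counts$D_r + counts$S_f + counts$D_f
  if (total == 0) stop("accuracy undefined: no evaluated patients")
  (counts$S_r + counts$D_r) / total
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: S_r=%d D_r=%d S_f=%d D_f=%d (ACC %.4f)\n",
              x$S_r, x$D_r, x$S_f, x$D_f, accuracy(x)))
  invisible(x)
}

## label vault ---------------------------------------------------------------

#' Seal test labels until final scoring
#'
#' The evaluation harness never reads held-out labels while models are being
#' fitted; labels live inside a vault whose fields cannot be read directly.
#' [score_against()] is the only way to consume them, and it immediately
#' reduces them to confusion counts.
#'
#' @param labels Held-out outcome labels.
#' @return An object of class `label_vault`.
#' @export
label_vault <- function(labels) {
  force(labels)
  env <- new.env(parent = emptyenv())
  env$labels <- labels
  env$n <- length(labels)
  structure(list(n = length(labels),
                 .score = function(pred) confusion_counts(env$labels, pred)),
            class = "label_vault")
}

#' @export
`$.label_vault` <- function(x, name) {
  if (name %in% c("n", ".score")) return(unclass(x)[[name]])
  stop("test labels are sealed; use score_against() for final scoring")
}

#' @export
`[[.label_vault` <- function(x, name) `$.label_vault`(x, name)

#' @rdname label_vault
#' @param vault A [label_vault()].
#' @param pred Predicted labels.
#' @export
score_against <- function(vault, pred) {
  stopifnot(inherits(vault, "label_vault"))
  vault$.score(pred)
}

## importance ranking --------------------------------------------------------

#' Rank indicator importance and select the core set
#'
#' Fits a gradient-boosted tree ensemble (xgboost, binary logistic objective)
#' on balanced training data and extracts gain-based importance per
#' indicator. Indicators never used in a split get importance 0. The core set
#' is the top `core_size` indicators after applying any expert overrides
#' (forced inclusions are kept, forced exclusions removed, then the list is
#' truncated to `core_size`).
#'
#' @param x Training feature matrix (columns = indicators).
#' @param y Binary training labels.
#' @param core_size Number of core indicators to select, default 12.
#' @param expert_include,expert_exclude Optional indicator names forced into /
#'   out of the core set (clinical-expert overrides).
#' @param balance Apply [smote_oversample()] before fitting (default TRUE, the
#'   conventional order: balance, then rank).
#' @param nrounds,max_depth,eta xgboost hyperparameters.
#' @param seed Integer seed (single-threaded fit, deterministic).
#' @return An object of class `importance_ranking`: list with `scores` (named,
#'   descending), `order`, `core`.
#' @export
rank_indicators <- function(x, y, core_size = 12L,
                            expert_include = NULL, expert_exclude = NULL,
                            balance = TRUE, nrounds = 50L, max_depth = 4L,
                            eta = 0.3, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("ind_", seq_len(ncol(x)))
  if (length(unique(y)) < 2L) stop("importance ranking needs both classes")
  if (balance) {
    bal <- smote_oversample(x, y, seed = seed)
    x <- bal$x; y <- bal$y
  }
  set.seed(seed)
  booster <- xgboost::xgboost(
    x, factor(y, levels = c(0, 1)), objective = "binary:logistic",
    nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
    nthreads = 1L, seed = as.integer(seed), verbosity = 0L
  )
  imp <- xgboost::xgb.importance(model = booster)
  scores <- stats::setNames(rep(0, ncol(x)), colnames(x))
  scores[imp$Feature] <- imp$Gain
  ord <- names(sort(scores, decreasing = TRUE))
  core <- setdiff(ord, expert_exclude)
  core <- unique(c(intersect(core, expert_include),
                   setdiff(core, expert_include)))
  core <- core[seq_len(min(core_size, length(core)))]
  structure(list(scores = sort(scores, decreasing = TRUE),
                 order = ord, core = core,
                 expert_overrides = list(include = expert_include,
                                         exclude = expert_exclude)),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance_ranking: %d indicators, core set of %d\n",
              length(x$scores), length(x$core)))
  cat("  core:", paste(x$core, collapse = ", "), "\n")
  invisible(x)
}

## baselines -----------------------------------------------------------------

#' Run the classical baseline classifiers
#'
#' Trains decision tree (rpart, unlimited depth with minimum leaf 5), K
#' nearest neighbours (`class::knn`, K = 5) and L2-free logistic regression
#' (`stats::glm`) on identical SMOTE-balanced training data and scores all of
#' them on the untouched held-out test partition. Test labels stay in a
#' [label_vault()] until scoring.
#'
#' @param split A [split_train_test()] result.
#' @param smote_k SMOTE neighbour count, default 5.
#' @param knn_k K for the KNN baseline, default 5.
#' @param minbucket Minimum leaf size for the decision tree, default 5.
#' @param seed Integer seed.
#' @return A data.frame with one row per model: `model`, `acc`, `S_r`, `D_r`,
#'   `S_f`, `D_f`; failed fits are reported with `NA` metrics.
#' @export
run_baselines <- function(split, smote_k = 5L, knn_k = 5L, minbucket = 5L,
                          seed = 1L) {
  stopifnot(inherits(split, "split_cohort"))
  x_tr <- split$train$values
  y_tr <- split$train$labels
  x_te <- split$test$values
  vault <- label_vault(split$test$labels)
  bal <- smote_oversample(x_tr, y_tr, k = smote_k, seed = seed)

  fits <- list(
    DT = function() {
      df <- data.frame(bal$x, y = factor(bal$y, levels = c(0, 1)))
      fit <- rpart::rpart(y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minbucket = minbucket, cp = 0, xval = 0,
                            maxdepth = 30))
      as.integer(as.character(
        stats::predict(fit, data.frame(x_te), type = "class")))
    },
    KNN = function() {
      set.seed(seed) # knn() breaks distance ties at random
      as.integer(as.character(
        class::knn(bal$x, x_te, factor(bal$y, levels = c(0, 1)), k = knn_k)))
    },
    LR = function() {
      df <- data.frame(bal$x, y = bal$y)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)))
      p <- suppressWarnings(
        stats::predict(fit, data.frame(x_te), type = "response"))
      as.integer(p > 0.5)
    }
  )

  rows <- lapply(names(fits), function(nm) {
    pred <- tryCatch(fits[[nm]](), error = function(e) {
      warning(nm, " baseline failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(pred))
      return(data.frame(model = nm, acc = NA_real_, S_r = NA_integer_,
                        D_r = NA_integer_, S_f = NA_integer_,
                        D_f = NA_integer_))
    cc <- score_against(vault, pred)
    data.frame(model = nm, acc = accuracy(cc), S_r = cc$S_r, D_r = cc$D_r,
               S_f = cc$S_f, D_f = cc$D_f)
  })
  do.call(rbind, rows)
}

## ablations -----------------------------------------------------------------

#' Run DGFSD and its ablations on one split
#'
#' Fits three models sharing data, split, graph and seed:
#' \describe{
#'   \item{DGFSD}{the full fused model;}
#'   \item{DGFSD-G}{graph-structure only: individual clinical information is
#'     not considered, so the GCN runs on identity (one-hot) node features —
#'     pure label propagation through the similarity structure — with fusion
#'     and reconstruction disabled (`epsilon = 0`, `lambda = 0`);}
#'   \item{DGFSD-D-LR}{individual information only: an autoencoder trained on
#'     the features, with a logistic classifier on its bottleneck
#'     representation and no graph.}
#' }
#' The similarity graph is built transductively over train + test nodes
#' (standardized features); test labels stay sealed until scoring.
#'
#' @param split A [split_train_test()] result.
#' @param k Neighbours per node for the similarity graph, default 10.
#' @param hidden Hidden layer sizes, default `c(64, 32, 16)`.
#' @param epsilon Fusion coefficient for the full model, default 0.5.
#' @param lambda Reconstruction weight for the full model, default 1.
#' @param epochs,pretrain_epochs,lr,patience Training-loop settings, see
#'   [train_dgfsd()].
#' @param seed Integer seed shared by the three fits.
#' @param models Subset of `c("DGFSD", "DGFSD-G", "DGFSD-D-LR")` to run.
#' @return A data.frame with one row per model (`model`, `acc`, `S_r`, `D_r`,
#'   `S_f`, `D_f`).
#' @export
run_ablations <- function(split, k = 10L, hidden = c(64L, 32L, 16L),
                          epsilon = 0.5, lambda = 1, epochs = 200L,
                          pretrain_epochs = 50L, lr = 1e-3, patience = 20L,
                          seed = 1L,
                          models = c("DGFSD", "DGFSD-G", "DGFSD-D-LR")) {
  stopifnot(inherits(split, "split_cohort"))
  models <- match.arg(models, several.ok = TRUE)
  n_tr <- length(split$train$labels)
  n_te <- length(split$test$labels)
  S_all <- rbind(split$train$values, split$test$values)
  labels_masked <- c(split$train$labels, rep(NA_integer_, n_te))
  test_rows <- n_tr + seq_len(n_te)
  vault <- label_vault(split$test$labels)

  graph <- NULL
  if (any(models %in% c("DGFSD", "DGFSD-G")))
    graph <- build_topk_graph(compute_kernel(S_all), k = k)

  fit_graph_model <- function(S_in, eps, lam, pre) {
    m <- train_dgfsd(S_in, labels_masked, graph$A_hat, hidden = hidden,
                     epsilon = eps, lambda = lam, epochs = epochs,
                     pretrain_epochs = pre, lr = lr, patience = patience,
                     seed = seed)
    stats::predict(m, S_in, graph$A_hat)$label[test_rows]
  }

  rows <- lapply(models, function(nm) {
    pred <- tryCatch(switch(
      nm,
      "DGFSD" = fit_graph_model(S_all, epsilon, lambda, pretrain_epochs),
      # structure only: one-hot node identities instead of clinical features
      "DGFSD-G" = fit_graph_model(diag(nrow(S_all)), 0, 0, 0L),
      "DGFSD-D-LR" = {
        ae <- train_autoencoder(split$train$values, hidden = hidden,
                                epochs = epochs, lr = lr, seed = seed)
        z_tr <- encoder_forward(split$train$values, ae$params)
        z_te <- encoder_forward(split$test$values, ae$params)
        L <- length(hidden)
        df <- data.frame(z_tr[[L]], y = split$train$labels)
        lr_fit <- suppressWarnings(
          stats::glm(y ~ ., data = df, family = stats::binomial(),
                     control = stats::glm.control(maxit = 50)))
        p <- suppressWarnings(
          stats::predict(lr_fit, data.frame(z_te[[L]]), type = "response"))
        as.integer(p > 0.5)
      }
    ), error = function(e) {
      warning(nm, " ablation failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(pred))
      return(data.frame(model = nm, acc = NA_real_, S_r = NA_integer_,
                        D_r = NA_integer_, S_f = NA_integer_,
                        D_f = NA_integer_))
    cc <- score_against(vault, pred)
    data.frame(model = nm, acc = accuracy(cc), S_r = cc$S_r, D_r = cc$D_r,
               S_f = cc$S_f, D_f = cc$D_f)
  })
  do.call(rbind, rows)
}
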