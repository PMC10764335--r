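## DGFSD network ------------------------------------------------------------
##
## Two coupled towers over the same patients:
##   encoder   H^(l) = relu(H^(l-1) We_l + be_l),          H^(0) = S
##   decoder   mirrors the encoder; final layer linear -> reconstruction of S
##   GCN       G^(1) = relu(A_hat S W_1)
##             G^(l) = relu(A_hat G~^(l-1) W_l),  l = 2..L
##             logits = A_hat G~^(L) W_{L+1},     row softmax -> P(outcome)
## with the layer-wise fusion  G~^(l) = (1 - eps) G^(l) + eps H^(l).
## A_hat is the symmetric-normalized adjacency with self-loops. Training
## minimizes  CE(softmax logits, labels | labeled nodes) + lambda * MSE(recon, S)
## by full-batch Adam; the graph is transductive (test nodes present, labels
## withheld).

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

logsumexp_rows <- function(z) {
  m <- apply(z, 1L, max)
  m + log(rowSums(exp(z - m)))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize DGFSD parameters
#'
#' Creates Glorot-uniform weights for the encoder, the mirrored decoder and
#' the GCN tower. Encoder and GCN share hidden dimensions so their layer
#' representations are conformable for fusion; the final GCN layer has 2
#' output units (survived / died).
#'
#' @param d Input dimension (number of indicators).
#' @param hidden Hidden layer sizes, default `c(64, 32, 16)`.
#' @param epsilon Fusion coefficient in `[0, 1]` weighting the autoencoder
#'   representation against the GCN representation; default 0.5 (both towers
#'   equally important).
#' @param seed Integer seed for the weight draw.
#' @return An object of class `dgfsd_params`.
#' @export
init_dgfsd_params <- function(d, hidden = c(64L, 32L, 16L), epsilon = 0.5,
                              seed = 1L) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (length(hidden) < 1L) stop("need at least one hidden layer")
  set.seed(seed)
  enc_dims <- c(d, hidden)
  L <- length(hidden)
  We <- be <- vector("list", L)
  for (l in seq_len(L)) {
    We[[l]] <- glorot(enc_dims[l], enc_dims[l + 1L])
    be[[l]] <- numeric(enc_dims[l + 1L])
  }
  dec_dims <- rev(enc_dims)
  Wd <- bd <- vector("list", L)
  for (l in seq_len(L)) {
    Wd[[l]] <- glorot(dec_dims[l], dec_dims[l + 1L])
    bd[[l]] <- numeric(dec_dims[l + 1L])
  }
  gcn_dims <- c(d, hidden, 2L)
  Wg <- vector("list", L + 1L)
  for (l in seq_len(L + 1L))
    Wg[[l]] <- glorot(gcn_dims[l], gcn_dims[l + 1L])
  structure(list(
    We = We, be = be, Wd = Wd, bd = bd, Wg = Wg,
    layer_sizes = as.integer(c(d, hidden)),
    epsilon = epsilon,
    activation = "relu",
    seed = as.integer(seed)
  ), class = "dgfsd_params")
}

#' Encoder forward pass
#'
#' Applies the stacked affine + ReLU encoder layers to the patient matrix.
#'
#' @param S n x d feature matrix (layer-0 input).
#' @param params A `dgfsd_params` object.
#' @return List of layer representations `H[[l]]`, `l = 1..L`.
#' @export
encoder_forward <- function(S, params) {
  S <- as.matrix(S)
  if (ncol(S) != params$layer_sizes[1L])
    stop("S has ", ncol(S), " columns but the encoder expects ",
         params$layer_sizes[1L])
  H <- vector("list", length(params$We))
  h <- S
  for (l in seq_along(params$We)) {
    h <- relu(sweep(h %*% params$We[[l]], 2L, params$be[[l]], "+"))
    H[[l]] <- h
  }
  H
}

#' Decoder forward pass
#'
#' Reconstructs the input matrix from the top encoder representation. Hidden
#' decoder layers use ReLU; the final layer is linear so reconstructions can
#' take any real value.
#'
#' @param H_top n x h matrix, the deepest encoder representation.
#' @param params A `dgfsd_params` object.
#' @return n x d reconstruction matrix.
#' @export
decoder_forward <- function(H_top, params) {
  h <- as.matrix(H_top)
  L <- length(params$Wd)
  if (ncol(h) != nrow(params$Wd[[1L]]))
    stop("H_top width ", ncol(h), " does not match the decoder input ",
         nrow(params$Wd[[1L]]))
  for (l in seq_len(L)) {
    h <- sweep(h %*% params$Wd[[l]], 2L, params$bd[[l]], "+")
    if (l < L) h <- relu(h)
  }
  h
}

#' Fuse autoencoder and GCN layer representations
#'
#' Elementwise convex combination
#' \deqn{\tilde{G} = (1 - \epsilon) G + \epsilon H.}
#'
#' @param G_prev GCN representation.
#' @param H_prev Autoencoder representation of matching shape.
#' @param epsilon Fusion coefficient in `[0, 1]`.
#' @return Fused matrix of the same shape.
#' @export
fuse <- function(G_prev, H_prev, epsilon) {
  G_prev <- as.matrix(G_prev); H_prev <- as.matrix(H_prev)
  if (!identical(dim(G_prev), dim(H_prev)))
    stop("fuse: shape mismatch between GCN and encoder representations")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  (1 - epsilon) * G_prev + epsilon * H_prev
}

#' GCN forward pass with layer fusion
#'
#' Propagates patient features through the graph operator, fusing in the
#' encoder representation before every layer after the first. The final layer
#' produces two logits per patient which are row-softmaxed into outcome
#' probabilities.
#'
#' @param S n x d feature matrix.
#' @param A_hat Normalized adjacency over the same n patients (see
#'   [normalize_adjacency()]).
#' @param params A `dgfsd_params` object.
#' @param H Encoder representations from [encoder_forward()]; when `NULL`
#'   they are computed internally.
#' @return List with `G` (per-layer GCN representations), `G_fused` (fused
#'   inputs to layers 2..L+1), `logits`, `output` (n x 2, rows sum to 1) and
#'   `P_h` (death probability per patient).
#' @export
gcn_forward <- function(S, A_hat, params, H = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != nrow(A_hat))
    stop("S and A_hat disagree on the number of patients")
  if (is.null(H)) H <- encoder_forward(S, params)
  eps <- params$epsilon
  L <- length(params$We)
  G <- vector("list", L)
  G_fused <- vector("list", L)
  AS <- as.matrix(A_hat %*% S)
  G[[1L]] <- relu(AS %*% params$Wg[[1L]])
  if (L >= 2L) for (l in 2:L) {
    G_fused[[l - 1L]] <- fuse(G[[l - 1L]], H[[l - 1L]], eps)
    G[[l]] <- relu(as.matrix(A_hat %*% G_fused[[l - 1L]]) %*% params$Wg[[l]])
  }
  G_fused[[L]] <- fuse(G[[L]], H[[L]], eps)
  logits <- as.matrix(A_hat %*% G_fused[[L]]) %*% params$Wg[[L + 1L]]
  output <- softmax_rows(logits)
  colnames(output) <- c("survived", "died")
  list(G = G, G_fused = G_fused, logits = logits, output = output,
       P_h = output[, 2L])
}

#' Full DGFSD forward trace
#'
#' Runs encoder, decoder and fused GCN and returns every intermediate
#' representation.
#'
#' @inheritParams gcn_forward
#' @return List with `H`, `reconstruction`, and the [gcn_forward()] fields.
#' @export
dgfsd_forward <- function(S, A_hat, params) {
  H <- encoder_forward(S, params)
  recon <- decoder_forward(H[[length(H)]], params)
  c(list(H = H, reconstruction = recon), gcn_forward(S, A_hat, params, H))
}

## loss + analytic gradients -------------------------------------------------

dgfsd_loss_grads <- function(params, S, A_hat, labels, lambda = 1,
                             recon_nodes = c("all", "labeled")) {
  recon_nodes <- match.arg(recon_nodes)
  S <- as.matrix(S)
  n <- nrow(S); d <- ncol(S)
  L <- length(params$We)
  eps <- params$epsilon
  labeled <- which(!is.na(labels))
  if (length(labeled) == 0L) stop("no labeled nodes to train on")
  y <- labels[labeled]

  ## GCN-only fast path: with no fusion and no reconstruction term the
  ## autoencoder receives no gradient and never influences the output
  if (eps == 0 && lambda == 0)
    return(gcn_only_loss_grads(params, S, A_hat, labeled, y))

  ## forward with caches
  Pe <- H <- vector("list", L)
  h <- S
  for (l in seq_len(L)) {
    Pe[[l]] <- sweep(h %*% params$We[[l]], 2L, params$be[[l]], "+")
    H[[l]] <- relu(Pe[[l]])
    h <- H[[l]]
  }
  Dec <- Pd <- vector("list", L)
  dcur <- H[[L]]
  dec_in <- vector("list", L)
  for (l in seq_len(L)) {
    dec_in[[l]] <- dcur
    Pd[[l]] <- sweep(dcur %*% params$Wd[[l]], 2L, params$bd[[l]], "+")
    dcur <- if (l < L) relu(Pd[[l]]) else Pd[[l]]
    Dec[[l]] <- dcur
  }
  recon <- Dec[[L]]

  G <- Pg <- Tm <- AT <- vector("list", L + 1L)
  AS <- as.matrix(A_hat %*% S)
  Pg[[1L]] <- AS %*% params$Wg[[1L]]
  G[[1L]] <- relu(Pg[[1L]])
  if (L >= 2L) for (l in 2:L) {
    Tm[[l - 1L]] <- (1 - eps) * G[[l - 1L]] + eps * H[[l - 1L]]
    AT[[l - 1L]] <- as.matrix(A_hat %*% Tm[[l - 1L]])
    Pg[[l]] <- AT[[l - 1L]] %*% params$Wg[[l]]
    G[[l]] <- relu(Pg[[l]])
  }
  Tm[[L]] <- (1 - eps) * G[[L]] + eps * H[[L]]
  AT[[L]] <- as.matrix(A_hat %*% Tm[[L]])
  logits <- AT[[L]] %*% params$Wg[[L + 1L]]

  ## losses
  lse <- logsumexp_rows(logits[labeled, , drop = FALSE])
  picked <- logits[cbind(labeled, y + 1L)]
  ce <- mean(lse - picked)
  rnodes <- if (recon_nodes == "all") seq_len(n) else labeled
  resid <- recon[rnodes, , drop = FALSE] - S[rnodes, , drop = FALSE]
  mse <- mean(resid^2)
  loss <- ce + lambda * mse

  ## backward
  O <- softmax_rows(logits)
  dZ <- matrix(0, n, 2L)
  dZ[labeled, ] <- O[labeled, , drop = FALSE]
  dZ[cbind(labeled, y + 1L)] <- dZ[cbind(labeled, y + 1L)] - 1
  dZ <- dZ / length(labeled)

  gWg <- vector("list", L + 1L)
  dH <- lapply(seq_len(L), function(l) 0)

  gWg[[L + 1L]] <- crossprod(AT[[L]], dZ)
  dT <- as.matrix(A_hat %*% tcrossprod(dZ, params$Wg[[L + 1L]]))
  dG <- (1 - eps) * dT
  dH[[L]] <- dH[[L]] + eps * dT
  if (L >= 2L) for (l in L:2) {
    dP <- dG * (Pg[[l]] > 0)
    gWg[[l]] <- crossprod(AT[[l - 1L]], dP)
    dT <- as.matrix(A_hat %*% tcrossprod(dP, params$Wg[[l]]))
    dG <- (1 - eps) * dT
    dH[[l - 1L]] <- dH[[l - 1L]] + eps * dT
  }
  dP1 <- dG * (Pg[[1L]] > 0)
  gWg[[1L]] <- crossprod(AS, dP1)

  ## decoder backward (MSE term)
  gWd <- gbd <- vector("list", L)
  dDec <- matrix(0, n, d)
  dDec[rnodes, ] <- 2 * lambda * resid / length(resid)
  for (l in L:1) {
    dP <- if (l < L) dDec * (Pd[[l]] > 0) else dDec
    gWd[[l]] <- crossprod(dec_in[[l]], dP)
    gbd[[l]] <- colSums(dP)
    dDec <- tcrossprod(dP, params$Wd[[l]])
  }
  dH[[L]] <- dH[[L]] + dDec

  ## encoder backward with accumulated fusion/decoder contributions
  gWe <- gbe <- vector("list", L)
  grad <- dH[[L]]
  for (l in L:1) {
    dP <- grad * (Pe[[l]] > 0)
    gWe[[l]] <- crossprod(if (l > 1L) H[[l - 1L]] else S, dP)
    gbe[[l]] <- colSums(dP)
    grad <- tcrossprod(dP, params$We[[l]])
    if (l > 1L) grad <- grad + dH[[l - 1L]]
  }

  list(loss = loss, ce = ce, mse = mse,
       grads = list(We = gWe, be = gbe, Wd = gWd, bd = gbd, Wg = gWg),
       output = O)
}

gcn_only_loss_grads <- function(params, S, A_hat, labeled, y) {
  L <- length(params$We)
  n <- nrow(S)
  G <- Pg <- AT <- vector("list", L + 1L)
  AT[[1L]] <- as.matrix(A_hat %*% S)
  for (l in seq_len(L)) {
    Pg[[l]] <- AT[[l]] %*% params$Wg[[l]]
    G[[l]] <- relu(Pg[[l]])
    AT[[l + 1L]] <- as.matrix(A_hat %*% G[[l]])
  }
  logits <- AT[[L + 1L]] %*% params$Wg[[L + 1L]]
  lse <- logsumexp_rows(logits[labeled, , drop = FALSE])
  ce <- mean(lse - logits[cbind(labeled, y + 1L)])
  O <- softmax_rows(logits)
  dZ <- matrix(0, n, 2L)
  dZ[labeled, ] <- O[labeled, , drop = FALSE]
  dZ[cbind(labeled, y + 1L)] <- dZ[cbind(labeled, y + 1L)] - 1
  dZ <- dZ / length(labeled)
  gWg <- vector("list", L + 1L)
  gWg[[L + 1L]] <- crossprod(AT[[L + 1L]], dZ)
  dG <- as.matrix(A_hat %*% tcrossprod(dZ, params$Wg[[L + 1L]]))
  for (l in L:1) {
    dP <- dG * (Pg[[l]] > 0)
    gWg[[l]] <- crossprod(AT[[l]], dP)
    if (l > 1L) dG <- as.matrix(A_hat %*% tcrossprod(dP, params$Wg[[l]]))
  }
  zero <- function(ms) lapply(ms, function(m) m * 0)
  list(loss = ce, ce = ce, mse = 0,
       grads = list(We = zero(params$We), be = zero(params$be),
                    Wd = zero(params$Wd), bd = zero(params$bd), Wg = gWg),
       output = O)
}

## Adam over the nested parameter list ---------------------------------------

adam_init <- function(params, fields) {
  st <- list(t = 0L, m = list(), v = list())
  for (f in fields) {
    st$m[[f]] <- lapply(params[[f]], function(w) w * 0)
    st$v[[f]] <- lapply(params[[f]], function(w) w * 0)
  }
  st
}

adam_step <- function(params, grads, st, fields, lr,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (f in fields) {
    for (l in seq_along(params[[f]])) {
      g <- grads[[f]][[l]]
      st$m[[f]][[l]] <- beta1 * st$m[[f]][[l]] + (1 - beta1) * g
      st$v[[f]][[l]] <- beta2 * st$v[[f]][[l]] + (1 - beta2) * g^2
      mhat <- st$m[[f]][[l]] / corr1
      vhat <- st$v[[f]][[l]] / corr2
      params[[f]][[l]] <- params[[f]][[l]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
  }
  list(params = params, state = st)
}

#' Train the DGFSD model
#'
#' Joint full-batch training of the autoencoder and the fused GCN in the
#' transductive regime: `S` and `A_hat` cover all patients (train and test
#' nodes alike); `labels` carries the outcome for training nodes and `NA` for
#' nodes whose labels are withheld. The objective is cross-entropy over the
#' labeled nodes plus `lambda` times the autoencoder reconstruction MSE
#' (over all nodes by default), minimized by Adam. Optionally the autoencoder
#' is pretrained alone for `pretrain_epochs` before joint training.
#'
#' @param S n x d feature matrix over all graph nodes.
#' @param labels Length-n vector in \{0, 1, NA\}; NA = unlabeled node.
#' @param A_hat Normalized adjacency from [build_topk_graph()] /
#'   [normalize_adjacency()].
#' @param hidden Hidden layer sizes shared by encoder and GCN.
#' @param epsilon Fusion coefficient, default 0.5.
#' @param lambda Weight of the reconstruction term, default 1.
#' @param epochs Joint training epochs, default 200.
#' @param pretrain_epochs Autoencoder-only warm-up epochs, default 50.
#' @param lr Adam learning rate, default 1e-3.
#' @param patience Early-stopping patience on the training loss (epochs
#'   without improvement > 1e-6), default 20; the best parameters are kept.
#' @param recon_nodes Nodes contributing to the reconstruction loss: `"all"`
#'   (default, unsupervised term over the whole graph) or `"labeled"`.
#' @param seed Seed for weight initialization; training itself is
#'   deterministic (full batch, no dropout).
#' @return An object of class `dgfsd_model`: the trained `params`, a
#'   `history` data.frame (epoch, loss, ce, mse, train_acc) and the training
#'   configuration.
#' @export
train_dgfsd <- function(S, labels, A_hat, hidden = c(64L, 32L, 16L),
                        epsilon = 0.5, lambda = 1, epochs = 200L,
                        pretrain_epochs = 50L, lr = 1e-3, patience = 20L,
                        recon_nodes = c("all", "labeled"), seed = 1L) {
  recon_nodes <- match.arg(recon_nodes)
  S <- as.matrix(S)
  dimnames(S) <- NULL # keep weight matrices free of propagated dimnames
  if (nrow(S) != nrow(A_hat)) stop("S and A_hat disagree on node count")
  if (length(labels) != nrow(S)) stop("labels must cover every node")
  if (all(is.na(labels))) stop("no labeled nodes to train on")
  params <- init_dgfsd_params(ncol(S), hidden = hidden, epsilon = epsilon,
                              seed = seed)
  labeled <- which(!is.na(labels))

  if (pretrain_epochs > 0L && lambda > 0) {
    ae_fields <- c("We", "be", "Wd", "bd")
    st <- adam_init(params, ae_fields)
    for (ep in seq_len(pretrain_epochs)) {
      ae <- autoencoder_loss_grads(params, S)
      upd <- adam_step(params, ae$grads, st, ae_fields, lr)
      params <- upd$params; st <- upd$state
    }
  }

  fields <- c("We", "be", "Wd", "bd", "Wg")
  st <- adam_init(params, fields)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        ce = numeric(0), mse = numeric(0),
                        train_acc = numeric(0))
  best <- list(loss = Inf, params = params)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    lg <- dgfsd_loss_grads(params, S, A_hat, labels, lambda = lambda,
                           recon_nodes = recon_nodes)
    if (!is.finite(lg$loss))
      stop("non-finite training loss at epoch ", ep,
           " (ce = ", lg$ce, ", mse = ", lg$mse, ")")
    pred <- as.integer(lg$output[labeled, 2L] > 0.5)
    history <- rbind(history, data.frame(
      epoch = ep, loss = lg$loss, ce = lg$ce, mse = lg$mse,
      train_acc = mean(pred == labels[labeled])))
    if (lg$loss < best$loss - 1e-6) {
      best <- list(loss = lg$loss, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    upd <- adam_step(params, lg$grads, st, fields, lr)
    params <- upd$params; st <- upd$state
  }
  structure(list(
    params = best$params,
    history = history,
    config = list(hidden = hidden, epsilon = epsilon, lambda = lambda,
                  epochs = epochs, pretrain_epochs = pretrain_epochs,
                  lr = lr, patience = patience, recon_nodes = recon_nodes,
                  seed = seed),
    trained = TRUE
  ), class = "dgfsd_model")
}

autoencoder_loss_grads <- function(params, S) {
  L <- length(params$We)
  Pe <- H <- vector("list", L)
  h <- S
  for (l in seq_len(L)) {
    Pe[[l]] <- sweep(h %*% params$We[[l]], 2L, params$be[[l]], "+")
    H[[l]] <- relu(Pe[[l]])
    h <- H[[l]]
  }
  Pd <- dec_in <- vector("list", L)
  dcur <- H[[L]]
  for (l in seq_len(L)) {
    dec_in[[l]] <- dcur
    Pd[[l]] <- sweep(dcur %*% params$Wd[[l]], 2L, params$bd[[l]], "+")
    dcur <- if (l < L) relu(Pd[[l]]) else Pd[[l]]
  }
  resid <- dcur - S
  mse <- mean(resid^2)
  gWd <- gbd <- gWe <- gbe <- vector("list", L)
  dDec <- 2 * resid / length(resid)
  for (l in L:1) {
    dP <- if (l < L) dDec * (Pd[[l]] > 0) else dDec
    gWd[[l]] <- crossprod(dec_in[[l]], dP)
    gbd[[l]] <- colSums(dP)
    dDec <- tcrossprod(dP, params$Wd[[l]])
  }
  grad <- dDec
  for (l in L:1) {
    dP <- grad * (Pe[[l]] > 0)
    gWe[[l]] <- crossprod(if (l > 1L) H[[l - 1L]] else S, dP)
    gbe[[l]] <- colSums(dP)
    grad <- tcrossprod(dP, params$We[[l]])
  }
  list(mse = mse, grads = list(We = gWe, be = gbe, Wd = gWd, bd = gbd), H = H)
}

#' Train a plain autoencoder
#'
#' Fits only the encoder/decoder tower by Adam on the reconstruction MSE.
#' Used by the no-graph ablation, which classifies on the bottleneck
#' representation.
#'
#' @inheritParams train_dgfsd
#' @return A `dgfsd_model`-like object with autoencoder weights and an
#'   `history` of the reconstruction loss.
#' @export
train_autoencoder <- function(S, hidden = c(64L, 32L, 16L), epochs = 200L,
                              lr = 1e-3, seed = 1L) {
  S <- as.matrix(S)
  dimnames(S) <- NULL
  params <- init_dgfsd_params(ncol(S), hidden = hidden, seed = seed)
  fields <- c("We", "be", "Wd", "bd")
  st <- adam_init(params, fields)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ae <- autoencoder_loss_grads(params, S)
    if (!is.finite(ae$mse)) stop("non-finite reconstruction loss at epoch ", ep)
    history[ep] <- ae$mse
    upd <- adam_step(params, ae$grads, st, fields, lr)
    params <- upd$params; st <- upd$state
  }
  structure(list(params = params, history = history,
                 config = list(hidden = hidden, epochs = epochs, lr = lr,
                               seed = seed),
                 trained = TRUE),
            class = "dgfsd_autoencoder")
}

#' Predict mortality risk with a trained DGFSD model
#'
#' Runs the forward pass and returns the death probability and a hard label
#' per patient. Ties (probability exactly 0.5) resolve to "survived".
#'
#' @param object A trained `dgfsd_model`.
#' @param S Feature matrix over the graph nodes.
#' @param A_hat Normalized adjacency over the same nodes.
#' @param ... Unused.
#' @return A data.frame with `p_death` and `label` (0/1) per patient.
#' @export
predict.dgfsd_model <- function(object, S, A_hat, ...) {
  if (!isTRUE(object$trained)) stop("model has not been trained")
  fwd <- dgfsd_forward(S, A_hat, object$params)
  data.frame(p_death = fwd$P_h, label = as.integer(fwd$P_h > 0.5))
}

#' @export
print.dgfsd_model <- function(x, ...) {
  cat(sprintf(
    "dgfsd_model: layers %s -> 2, epsilon = %g, lambda = %g, %d epochs run\n",
    paste(x$params$layer_sizes, collapse = " -> "),
    x$params$epsilon, x$config$lambda, nrow(x$history)))
  if (nrow(x$history))
    cat(sprintf("  final loss %.5f (ce %.5f, mse %.5f), train ACC %.3f\n",
                utils::tail(x$history$loss, 1), utils::tail(x$history$ce, 1),
                utils::tail(x$history$mse, 1),
                utils::tail(x$history$train_acc, 1)))
  invisible(x)
}

## checkpointing -------------------------------------------------------------

#' Save / load a DGFSD checkpoint
#'
#' Serializes all weight matrices, layer sizes, the fusion coefficient and the
#' training configuration to versioned JSON at full double precision, so that
#' `load_dgfsd(save_dgfsd(m, p))` round-trips bit-exactly.
#'
#' @param model A `dgfsd_model`.
#' @param path Output path.
#' @return `save_dgfsd` returns `path` invisibly; `load_dgfsd` the model.
#' @export
save_dgfsd <- function(model, path) {
  stopifnot(inherits(model, "dgfsd_model"))
  ser_mats <- function(ms) lapply(ms, function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
    else list(dim = NULL, data = as.numeric(m))
  })
  payload <- list(
    format = "dgfsd-checkpoint",
    version = 1L,
    layer_sizes = model$params$layer_sizes,
    epsilon = model$params$epsilon,
    activation = model$params$activation,
    seed = model$params$seed,
    config = model$config,
    weights = lapply(model$params[c("We", "be", "Wd", "bd", "Wg")], ser_mats)
  )
  # I(17) significant digits: exact IEEE-754 double round trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dgfsd
#' @export
load_dgfsd <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "dgfsd-checkpoint"))
    stop("not a DGFSD checkpoint: ", path)
  deser <- function(entries) lapply(entries, function(e) {
    dat <- vapply(e$data, as.numeric, 0)
    if (!is.null(e$dim) && length(e$dim) == 2L)
      matrix(dat, as.integer(e$dim[[1L]]), as.integer(e$dim[[2L]]))
    else dat
  })
  params <- structure(list(
    We = deser(payload$weights$We), be = deser(payload$weights$be),
    Wd = deser(payload$weights$Wd), bd = deser(payload$weights$bd),
    Wg = deser(payload$weights$Wg),
    layer_sizes = as.integer(unlist(payload$layer_sizes)),
    epsilon = payload$epsilon,
    activation = payload$activation,
    seed = as.integer(payload$seed)
  ), class = "dgfsd_params")
  config <- payload$config
  config$hidden <- as.integer(unlist(config$hidden))
  structure(list(params = params, history = data.frame(),
                 config = config, trained = TRUE),
            class = "dgfsd_model")
}
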