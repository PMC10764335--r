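zeroed_params <- function(d, hidden) {
  p <- init_dgfsd_params(d, hidden = hidden, seed = 1)
  for (f in c("We", "be", "Wd", "bd", "Wg"))
    p[[f]] <- lapply(p[[f]], function(w) w * 0)
  p
}

test_that("encoder forward applies affine maps and ReLU as specified", {
  S <- rbind(c(1, 2), c(0, 1), c(-1, 0.5))
  # zero weights and biases: all representations vanish
  pz <- zeroed_params(2, c(3, 2))
  Hz <- encoder_forward(S, pz)
  expect_true(all(vapply(Hz, function(h) all(h == 0), TRUE)))
  # identity single layer on nonnegative input reproduces the input
  pid <- init_dgfsd_params(2, hidden = 2, seed = 1)
  pid$We[[1]] <- diag(2); pid$be[[1]] <- c(0, 0)
  Snn <- abs(S)
  expect_equal(encoder_forward(Snn, pid)[[1]], Snn)
  # hand-computed affine + ReLU on a 3 x 2 input
  ph <- init_dgfsd_params(2, hidden = 2, seed = 1)
  ph$We[[1]] <- rbind(c(1, -1), c(2, 0.5))
  ph$be[[1]] <- c(0.5, -1)
  expect_equal(encoder_forward(S, ph)[[1]],
               rbind(c(5.5, 0), c(2.5, 0), c(0.5, 0.25)))
  expect_error(encoder_forward(cbind(S, 1), ph), "expects")
})

test_that("decoder mirrors the encoder with a linear final layer", {
  S <- abs(matrix(rnorm(12), 4, 3))
  pz <- zeroed_params(3, c(2))
  expect_true(all(decoder_forward(matrix(1, 4, 2), pz) == 0))
  # identity single-layer autoencoder reconstructs exactly
  pid <- init_dgfsd_params(3, hidden = 3, seed = 1)
  pid$We[[1]] <- diag(3); pid$be[[1]] <- rep(0, 3)
  pid$Wd[[1]] <- diag(3); pid$bd[[1]] <- rep(0, 3)
  H <- encoder_forward(S, pid)
  expect_equal(decoder_forward(H[[1]], pid), S)
})

test_that("a bottleneck-1 autoencoder compresses rank-1 data losslessly", {
  set.seed(7)
  S <- outer(abs(rnorm(40)) + 0.2, abs(rnorm(4)) + 0.2)
  ae <- train_autoencoder(S, hidden = c(3, 1), epochs = 3000, lr = 1e-2,
                          seed = 3)
  expect_lt(tail(ae$history, 1) / mean(S^2), 0.01)
})

test_that("fusion is the elementwise convex combination at its limits", {
  G <- matrix(rnorm(12), 4, 3)
  H <- matrix(rnorm(12), 4, 3)
  expect_identical(fuse(G, H, 0), G)
  expect_identical(fuse(G, H, 1), H)
  expect_equal(fuse(H, H, 0.5), H)
  expect_equal(fuse(G, H, 0.25), 0.75 * G + 0.25 * H)
  expect_error(fuse(G, H[1:2, ], 0.5), "shape mismatch")
  expect_error(fuse(G, H, 1.5), "epsilon")
})

test_that("GCN forward matches hand calculations on a 3-node path graph", {
  A_hat_hand <- rbind(c(1 / 2, 1 / sqrt(6), 0),
                      c(1 / sqrt(6), 1 / 3, 1 / sqrt(6)),
                      c(0, 1 / sqrt(6), 1 / 2))
  A_hat <- normalize_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  S <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W1 <- rbind(c(1, 2), c(0, 1))
  p <- init_dgfsd_params(2, hidden = 2, seed = 1)
  p$Wg[[1]] <- W1
  fwd <- gcn_forward(S, A_hat, p)
  expect_equal(fwd$G[[1]], pmax(A_hat_hand %*% S %*% W1, 0),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(fwd$output)), rep(1, 3), tolerance = 1e-6)
})

test_that("an isolated node reduces the GCN to a per-node forward pass", {
  S <- matrix(c(0.3, -1.2, 0.5), 1, 3)
  A_hat <- normalize_adjacency(matrix(0, 1, 1)) # single self-loop
  p <- init_dgfsd_params(3, hidden = c(4, 2), seed = 2)
  fwd <- dgfsd_forward(S, A_hat, p)
  # no-graph oracle: same layer algebra with the propagation operator removed
  H1 <- pmax(S %*% p$We[[1]] + rep(1, 1) %o% p$be[[1]], 0)
  H2 <- pmax(H1 %*% p$We[[2]] + rep(1, 1) %o% p$be[[2]], 0)
  G1 <- pmax(S %*% p$Wg[[1]], 0)
  G2 <- pmax((0.5 * G1 + 0.5 * H1) %*% p$Wg[[2]], 0)
  Z <- (0.5 * G2 + 0.5 * H2) %*% p$Wg[[3]]
  O <- exp(Z - max(Z)); O <- O / sum(O)
  expect_equal(unname(fwd$output), O, tolerance = 1e-12)
})

test_that("identical fully connected patients receive identical predictions", {
  S <- rbind(c(1, 2, 3), c(1, 2, 3))
  A_hat <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2))
  p <- init_dgfsd_params(3, hidden = c(4, 2), seed = 3)
  fwd <- dgfsd_forward(S, A_hat, p)
  expect_equal(fwd$output[1, ], fwd$output[2, ])
  expect_equal(fwd$P_h[1], fwd$P_h[2])
  for (G in fwd$G) expect_equal(G[1, ], G[2, ])
})

test_that("with fusion off the forward pass equals an independent plain GCN", {
  set.seed(11)
  S <- matrix(rnorm(30), 10, 3)
  g <- build_topk_graph(compute_kernel(S), k = 3)
  p <- init_dgfsd_params(3, hidden = c(5, 4), epsilon = 0, seed = 4)
  fwd <- dgfsd_forward(S, g$A_hat, p)
  expect_equal(unname(fwd$output), plain_gcn(S, g$A_hat, p$Wg),
               tolerance = 1e-9)
})

test_that("with fusion fully on, the final layer consumes the encoder path", {
  set.seed(12)
  S <- matrix(rnorm(24), 8, 3)
  g <- build_topk_graph(compute_kernel(S), k = 2)
  p <- init_dgfsd_params(3, hidden = c(5, 4), epsilon = 1, seed = 5)
  fwd <- dgfsd_forward(S, g$A_hat, p)
  L <- length(fwd$H)
  expect_equal(fwd$G_fused[[L]], fwd$H[[L]], tolerance = 1e-9)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  n <- 7; d <- 3
  S <- matrix(rnorm(n * d), n, d)
  g <- build_topk_graph(compute_kernel(S), k = 2)
  params <- init_dgfsd_params(d, hidden = c(4, 3), epsilon = 0.5, seed = 5)
  # random biases keep pre-activations off the ReLU kink, where the
  # subgradient convention and a finite difference legitimately differ
  params$be <- lapply(params$be, function(b) b + rnorm(length(b), 0, 0.1))
  params$bd <- lapply(params$bd, function(b) b + rnorm(length(b), 0, 0.1))
  labels <- c(0, 1, 0, 1, NA, NA, 1)
  lg <- dgfsd:::dgfsd_loss_grads(params, S, g$A_hat, labels, lambda = 0.7)
  loss_at <- function(p)
    dgfsd:::dgfsd_loss_grads(p, S, g$A_hat, labels, lambda = 0.7)$loss
  h <- 1e-6
  for (fld in c("We", "be", "Wd", "bd", "Wg")) {
    for (l in seq_along(params[[fld]])) {
      w <- params[[fld]][[l]]
      for (i in sample(length(w), min(3L, length(w)))) {
        up <- params; up[[fld]][[l]][i] <- w[i] + h
        dn <- params; dn[[fld]][[l]][i] <- w[i] - h
        numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * h)
        expect_equal(lg$grads[[fld]][[l]][i], numeric_grad,
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic and keeps finite losses across seeds", {
  set.seed(13)
  S <- matrix(rnorm(90), 30, 3)
  lab <- c(rep(c(0, 1), 10), rep(NA, 10))
  g <- build_topk_graph(compute_kernel(S), k = 3)
  m1 <- train_dgfsd(S, lab, g$A_hat, hidden = c(6, 3), epochs = 40,
                    pretrain_epochs = 10, seed = 7)
  m2 <- train_dgfsd(S, lab, g$A_hat, hidden = c(6, 3), epochs = 40,
                    pretrain_epochs = 10, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  for (s in 1:3) {
    m <- train_dgfsd(S, lab, g$A_hat, hidden = c(6, 3), epochs = 25,
                     pretrain_epochs = 5, seed = s)
    expect_true(all(is.finite(m$history$loss)))
    expect_true(all(is.finite(m$history$mse)))
  }
})

test_that("a single labeled node is fit to near-zero loss without the decoder", {
  set.seed(5)
  S <- matrix(rnorm(15), 5, 3)
  g <- build_topk_graph(compute_kernel(S), k = 2)
  m <- train_dgfsd(S, c(1, NA, NA, NA, NA), g$A_hat, hidden = 4, lambda = 0,
                   epochs = 300, pretrain_epochs = 0, lr = 5e-3,
                   patience = 50, seed = 5)
  expect_lt(tail(m$history$ce, 1), 0.05)
})

test_that("a separable cohort is fit to high training accuracy", {
  cfg <- cohort_config(150, schema = separable_schema(), death_rate = 0.3,
                       n_latent_clusters = 1, graph_signal_strength = 0,
                       seed = 3)
  sp <- split_train_test(generate_cohort(cfg), seed = 3)
  S <- rbind(sp$train$values, sp$test$values)
  lab <- c(sp$train$labels, rep(NA_integer_, length(sp$test$labels)))
  g <- build_topk_graph(compute_kernel(S), k = 5)
  m <- train_dgfsd(S, lab, g$A_hat, epochs = 120, pretrain_epochs = 20,
                   seed = 3)
  expect_gte(tail(m$history$train_acc, 1), 0.95)
})

test_that("prediction ties resolve toward survival", {
  p <- zeroed_params(3, c(4, 2))  # all-zero weights: output is (0.5, 0.5)
  m <- structure(list(params = p, history = data.frame(),
                      config = list(), trained = TRUE),
                 class = "dgfsd_model")
  A_hat <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2))
  pr <- predict(m, matrix(rnorm(6), 2, 3), A_hat)
  expect_equal(pr$p_death, c(0.5, 0.5))
  expect_identical(pr$label, c(0L, 0L))
  m$trained <- FALSE
  expect_error(predict(m, matrix(rnorm(6), 2, 3), A_hat), "trained")
})

test_that("predictions are equivariant under patient permutation", {
  set.seed(14)
  S <- matrix(rnorm(60), 20, 3)
  g <- build_topk_graph(compute_kernel(S), k = 3)
  p <- init_dgfsd_params(3, hidden = c(5, 3), seed = 6)
  fwd <- dgfsd_forward(S, g$A_hat, p)
  perm <- sample(20)
  A_perm <- g$A_hat[perm, perm]
  fwd_p <- dgfsd_forward(S[perm, ], A_perm, p)
  expect_equal(fwd_p$output, fwd$output[perm, ], tolerance = 1e-9)
  expect_equal(fwd_p$P_h, fwd$P_h[perm], tolerance = 1e-9)
})

test_that("checkpoints round-trip bit-exactly", {
  set.seed(1)
  S <- matrix(abs(rnorm(80)), 20, 4, dimnames = list(NULL, letters[1:4]))
  g <- build_topk_graph(compute_kernel(S), k = 3)
  lab <- c(rep(c(0L, 1L), 7), rep(NA_integer_, 6))
  m <- train_dgfsd(S, lab, g$A_hat, hidden = c(6, 3), epochs = 25,
                   pretrain_epochs = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_dgfsd(m, path)
  m2 <- load_dgfsd(path)
  expect_identical(m2$params[c("We", "be", "Wd", "bd", "Wg")],
                   m$params[c("We", "be", "Wd", "bd", "Wg")])
  expect_identical(m2$params$epsilon, m$params$epsilon)
  expect_identical(predict(m2, S, g$A_hat), predict(m, S, g$A_hat))
  expect_error(load_dgfsd(withr::local_tempfile(fileext = ".json",
                                                lines = "{\"format\": \"x\"}")),
               "checkpoint")
})
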