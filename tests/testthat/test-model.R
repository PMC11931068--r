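# The network: ZLPR loss closed forms and stability, gradient correctness,
# determinism contracts and the capacity to fit.

test_that("ZLPR loss matches its closed forms", {
  expect_equal(zlpr_loss(numeric(), integer()), 0)
  expect_equal(zlpr_loss(0, 1), log(2))
  expect_equal(zlpr_loss(c(10, -10), c(1, 0)), 2 * log(1 + exp(-10)))
  # one negative at 0 is symmetric to one positive at 0
  expect_equal(zlpr_loss(0, 0), log(2))
  expect_error(zlpr_loss(c(1, 2), c(1, 2)), class = "dga_contract_error")
})

test_that("stabilized ZLPR agrees with the naive formula and survives +-1e4", {
  naive <- function(scores, labels, s0 = 0) {
    log(exp(s0) + sum(exp(scores[labels == 0]))) +
      log(exp(-s0) + sum(exp(-scores[labels == 1])))
  }
  set.seed(8)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    sc <- rnorm(n, sd = 5)
    lab <- rbinom(n, 1, 0.5)
    expect_equal(zlpr_loss(sc, lab), naive(sc, lab), tolerance = 1e-9)
  }
  big <- zlpr_loss(c(1e4, -1e4), c(0, 1))
  expect_true(is.finite(big))
  expect_equal(big, 2e4, tolerance = 1e-9)
  expect_true(is.finite(zlpr_loss(c(-1e4, 1e4), c(0, 1))))
})

test_that("ZLPR gradient pushes positives up and negatives down", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    sc <- rnorm(n, sd = 3)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5))  # guarantee both classes
    g <- dganet:::zlpr_grad(sc, lab)
    expect_true(all(g[lab == 1] < 0))
    expect_true(all(g[lab == 0] > 0))
    # analytic gradient matches numerical differentiation
    eps <- 1e-6
    for (j in sample(n, min(3, n))) {
      up <- sc; up[j] <- up[j] + eps
      dn <- sc; dn[j] <- dn[j] - eps
      expect_equal(g[j], (zlpr_loss(up, lab) - zlpr_loss(dn, lab)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("backpropagation matches numerical gradients for every parameter", {
  set.seed(42)
  cfg <- dganet_config(lsn_hidden = 7L, head_hidden = 5L, emb_dim = 4L,
                       dropout = 0, conv_channels = c(2L, 3L, 4L),
                       proj_d = 6L, proj_s = 5L, seed = 3L)
  B <- 4L; Pd <- 8L; Ps <- 9L
  Xd <- matrix(rnorm(B * Pd), B)
  Xs <- matrix(rnorm(B * Ps), B)
  labels <- c(1, 0, 1, 0)
  drugs <- c("d1", "d1", "d2", "d2")
  params <- dganet:::init_params(cfg, Pd, Ps)
  loss_fn <- function(p) {
    f <- dganet:::forward_pass(p, cfg, Xd, Xs, train = FALSE)
    dganet:::zlpr_batch(f$scores, labels, drugs, cfg$s0)$loss
  }
  f <- dganet:::forward_pass(params, cfg, Xd, Xs, train = FALSE)
  z <- dganet:::zlpr_batch(f$scores, labels, drugs, cfg$s0)
  grads <- dganet:::backward_pass(params, cfg, f$cache, z$grad)
  eps <- 1e-6
  paths <- list("proj_d", "proj_s",
                c("lsn_d", "W1"), c("lsn_d", "b1"), c("lsn_d", "W2"),
                c("lsn_s", "W1"), c("lsn_s", "W2"), c("lsn_s", "b2"),
                c("conv1", "W"), c("conv1", "b"), c("conv2", "W"),
                c("conv3", "W"), c("conv3", "b"),
                c("head", "W1"), c("head", "b1"), c("head", "W2"),
                c("head", "b2"))
  for (path in paths) {
    p <- if (length(path) > 1) params[[path[1]]][[path[2]]] else params[[path[1]]]
    g <- if (length(path) > 1) grads[[path[1]]][[path[2]]] else grads[[path[1]]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- params
      if (length(path) > 1) pp[[path[1]]][[path[2]]][i] <- p[i] + eps
      else pp[[path[1]]][i] <- p[i] + eps
      lp <- loss_fn(pp)
      if (length(path) > 1) pp[[path[1]]][[path[2]]][i] <- p[i] - eps
      else pp[[path[1]]][i] <- p[i] - eps
      lm <- loss_fn(pp)
      expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   label = paste(path, collapse = "$"))
    }
  }
})

test_that("embeddings are deterministic in evaluation mode and zero for zero weights", {
  set.seed(5)
  we <- worked_example()
  feats <- build_feature_blocks(we)
  dfe <- assemble_features(feats$drug)
  afe <- assemble_features(feats$adr)
  pairs <- expand.grid(drug_id = we$drugs, adr_id = we$adrs,
                       stringsAsFactors = FALSE)
  pairs$label <- rbinom(nrow(pairs), 1, 0.5)
  cfg <- tiny_cfg(epochs = 2L, seed = 4L)
  m <- train_dganet(dfe, afe, pairs, cfg)

  e1 <- lsn_embed(m, dfe, "drug")
  e2 <- lsn_embed(m, dfe, "drug")
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(3L, cfg$emb_dim))
  expect_error(lsn_embed(m, afe, "drug"), class = "dga_shape_error")

  p1 <- predict_dganet(m, dfe, afe, pairs)
  p2 <- predict_dganet(m, dfe, afe, pairs)
  expect_identical(p1$score, p2$score)

  # zero weights propagate to zero scores (linearity sanity)
  zero <- m
  zero$params <- rapply(m$params, function(x) x * 0, how = "replace")
  p0 <- predict_dganet(zero, dfe, afe, pairs)
  expect_equal(p0$score, rep(0, nrow(pairs)))
  ez <- csn_embed(zero, feature_cross(dfe[1, ], afe[1, ],
                                      proj_d = m$params$proj_d,
                                      proj_s = m$params$proj_s))
  expect_equal(as.numeric(ez), rep(0, length(ez)))
})

test_that("CSN spatial reduction follows the three-pool arithmetic", {
  set.seed(6)
  cfg <- dganet_config(proj_d = 64L, proj_s = 64L, epochs = 1L,
                       conv_channels = c(8L, 16L, 32L))
  params <- dganet:::init_params(cfg, 10L, 10L)
  # 64 -> 32 -> 16 -> 8 per side, so the flattened width is 8*8*32
  expect_equal(attr(params, "dims")$flat, 8L * 8L * 32L)
  m <- structure(list(params = params, cfg = cfg), class = "dganet_model")
  emb <- csn_embed(m, array(rnorm(64 * 64), c(64, 64, 1, 1)))
  expect_equal(ncol(emb), 8L * 8L * 32L)
  expect_error(csn_embed(m, matrix(0, 2, 2)), class = "dga_config_error")
})

test_that("training reduces the loss and reproduces bitwise under one seed", {
  set.seed(31)
  nd <- 8L; na <- 6L
  dfe <- matrix(rnorm(nd * 10), nd, dimnames = list(sprintf("d%d", 1:nd), NULL))
  afe <- matrix(rnorm(na * 9), na, dimnames = list(sprintf("a%d", 1:na), NULL))
  pairs <- expand.grid(drug_id = rownames(dfe), adr_id = rownames(afe),
                       stringsAsFactors = FALSE)
  pairs$label <- rbinom(nrow(pairs), 1L, 0.5)
  cfg <- tiny_cfg(epochs = 25L, seed = 12L)
  m1 <- train_dganet(dfe, afe, pairs, cfg)
  expect_lt(utils::tail(m1$history, 1), m1$history[1])
  m2 <- train_dganet(dfe, afe, pairs, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$head$W1, m2$params$head$W1)
  # different seed, different trajectory
  m3 <- train_dganet(dfe, afe, pairs, tiny_cfg(epochs = 25L, seed = 13L))
  expect_false(identical(m1$history, m3$history))
})

test_that("a relu head clips scores at zero while identity keeps both signs", {
  set.seed(77)
  nd <- 6L; na <- 5L
  dfe <- matrix(rnorm(nd * 8), nd, dimnames = list(sprintf("d%d", 1:nd), NULL))
  afe <- matrix(rnorm(na * 8), na, dimnames = list(sprintf("a%d", 1:na), NULL))
  pairs <- expand.grid(drug_id = rownames(dfe), adr_id = rownames(afe),
                       stringsAsFactors = FALSE)
  pairs$label <- rbinom(nrow(pairs), 1L, 0.5)
  m <- train_dganet(dfe, afe, pairs,
                    tiny_cfg(epochs = 5L, seed = 2L,
                             final_activation = "relu"))
  pr <- predict_dganet(m, dfe, afe, pairs)
  expect_true(all(pr$score >= 0))
})
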