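# The DGANet model: two linear subnetworks (LSN) embedding the drug and ADR
# similarity-feature rows, a six-layer convolutional subnetwork (CSN) over the
# drug x ADR feature cross, and a fully connected classifier head, trained
# with the ZLPR multi-label rank loss and Adam.

#' Model configuration
#'
#' Hyperparameters of the DGANet network. The convolutional subnetwork is six
#' layers: three 3x3 convolutions (ReLU) each followed by 2x2 max pooling.
#' `proj_d`/`proj_s` are the dimensions of the trained linear projections that
#' bound the feature cross fed to the CSN; `NULL` feeds the raw outer product
#' (feasible for narrow feature widths). At full production scale (feature
#' widths in the thousands) 64 x 64 is the recommended projection; the default
#' 16 x 16 is sized to the feature widths used throughout this package's
#' examples and simulations.
#'
#' @param lsn_hidden width n1 of the LSN hidden layer.
#' @param head_hidden width n2 of the classifier head hidden layer.
#' @param emb_dim output dimension of each LSN embedding.
#' @param dropout dropout probability p in `[0, 1)`.
#' @param conv_channels output channels of the three convolution stages.
#' @param proj_d,proj_s projection dims for the feature cross (`NULL` = raw).
#' @param learning_rate Adam learning rate (0.005 is the published setting).
#' @param epochs,batch_size training schedule.
#' @param s0 ZLPR anchor score.
#' @param final_activation `"identity"` (default) or `"relu"`. A ReLU head
#'   clips all negative evidence to zero, which breaks ranking below the
#'   decision threshold; ranking metrics always use pre-threshold scores.
#' @param seed integer seed governing initialization, batch order and dropout.
#' @return a `dganet_config` list.
#' @export
dganet_config <- function(lsn_hidden = 256L, head_hidden = 128L, emb_dim = 64L,
                          dropout = 0.3, conv_channels = c(8L, 16L, 32L),
                          proj_d = 16L, proj_s = 16L,
                          learning_rate = 0.005, epochs = 50L, batch_size = 128L,
                          s0 = 0, final_activation = c("identity", "relu"),
                          seed = 1L) {
  final_activation <- match.arg(final_activation)
  stopifnot(lsn_hidden >= 1L, head_hidden >= 1L, emb_dim >= 1L,
            dropout >= 0, dropout < 1, length(conv_channels) == 3L,
            learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(lsn_hidden = as.integer(lsn_hidden),
                 head_hidden = as.integer(head_hidden),
                 emb_dim = as.integer(emb_dim), dropout = dropout,
                 conv_channels = as.integer(conv_channels),
                 proj_d = if (is.null(proj_d)) NULL else as.integer(proj_d),
                 proj_s = if (is.null(proj_s)) NULL else as.integer(proj_s),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), s0 = s0,
                 final_activation = final_activation, seed = as.integer(seed)),
            class = "dganet_config")
}

#' ZLPR multi-label rank loss
#'
#' The zero-anchored log-sum-exp pairwise rank loss over one label set:
#' `L = log(e^s0 + sum_neg e^s) + log(e^-s0 + sum_pos e^-s)`. It pushes every
#' positive score above the anchor `s0` and every negative score below it,
#' while ranking positives above negatives jointly. Computed with log-sum-exp
#' stabilization, so it stays finite for scores far outside the overflow range
#' of the naive formula.
#'
#' @param scores numeric vector of per-label model scores.
#' @param labels 0/1 vector partitioning `scores` into negatives/positives.
#' @param s0 anchor score.
#' @return scalar loss (>= 0 when `s0 = 0`).
#' @export
zlpr_loss <- function(scores, labels, s0 = 0) {
  if (length(scores) != length(labels)) {
    dga_stop("scores and labels differ in length", "dga_contract_error")
  }
  if (length(labels) > 0 && !all(labels %in% c(0, 1))) {
    dga_stop("labels must partition scores into 0 (negative) and 1 (positive)",
             "dga_contract_error")
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  logsumexp(c(s0, neg)) + logsumexp(c(-s0, -pos))
}

# Gradient of zlpr_loss wrt each score (softmax weights of the two LSE terms).
zlpr_grad <- function(scores, labels, s0 = 0) {
  g <- numeric(length(scores))
  neg <- which(labels == 0)
  pos <- which(labels == 1)
  lse_neg <- logsumexp(c(s0, scores[neg]))
  lse_pos <- logsumexp(c(-s0, -scores[pos]))
  if (length(neg) > 0) g[neg] <- exp(scores[neg] - lse_neg)
  if (length(pos) > 0) g[pos] <- -exp(-scores[pos] - lse_pos)
  g
}

# ---------------------------------------------------------------------------

init_params <- function(cfg, in_d, in_s) {
  cc <- cfg$conv_channels
  pd <- cfg$proj_d %||% in_d
  ps <- cfg$proj_s %||% in_s
  if (pd < 4L || ps < 4L) {
    dga_stop("feature cross smaller than the CSN receptive field (need >= 4 x 4)",
             "dga_config_error")
  }
  flat <- ceiling(ceiling(ceiling(pd / 2) / 2) / 2) *
    ceiling(ceiling(ceiling(ps / 2) / 2) / 2) * cc[3L]
  concat <- 2L * cfg$emb_dim + flat
  params <- list(
    proj_d = if (is.null(cfg$proj_d)) NULL else he_init(c(in_d, pd), in_d),
    proj_s = if (is.null(cfg$proj_s)) NULL else he_init(c(in_s, ps), in_s),
    lsn_d = list(W1 = he_init(c(in_d, cfg$lsn_hidden), in_d),
                 b1 = numeric(cfg$lsn_hidden),
                 W2 = he_init(c(cfg$lsn_hidden, cfg$emb_dim), cfg$lsn_hidden),
                 b2 = numeric(cfg$emb_dim)),
    lsn_s = list(W1 = he_init(c(in_s, cfg$lsn_hidden), in_s),
                 b1 = numeric(cfg$lsn_hidden),
                 W2 = he_init(c(cfg$lsn_hidden, cfg$emb_dim), cfg$lsn_hidden),
                 b2 = numeric(cfg$emb_dim)),
    conv1 = list(W = he_init(c(3L, 3L, 1L, cc[1L]), 9L), b = numeric(cc[1L])),
    conv2 = list(W = he_init(c(3L, 3L, cc[1L], cc[2L]), 9L * cc[1L]),
                 b = numeric(cc[2L])),
    conv3 = list(W = he_init(c(3L, 3L, cc[2L], cc[3L]), 9L * cc[2L]),
                 b = numeric(cc[3L])),
    head = list(W1 = he_init(c(concat, cfg$head_hidden), concat),
                b1 = numeric(cfg$head_hidden),
                W2 = he_init(c(cfg$head_hidden, 1L), cfg$head_hidden),
                b2 = numeric(1L))
  )
  attr(params, "dims") <- list(in_d = in_d, in_s = in_s, pd = pd, ps = ps,
                               flat = flat, concat = concat)
  params
}

# Full forward pass over a batch. Xd: (B x in_d), Xs: (B x in_s).
forward_pass <- function(params, cfg, Xd, Xs, train = FALSE) {
  B <- nrow(Xd)
  p <- if (train) cfg$dropout else 0
  cache <- list(Xd = Xd, Xs = Xs, B = B)

  lsn_fwd <- function(w, X, key) {
    A1 <- sweep(X %*% w$W1, 2L, w$b1, "+")
    H1 <- relu(A1)
    mask <- dropout_mask(dim(H1), p)
    D1 <- if (is.null(mask)) H1 else H1 * mask
    E <- sweep(D1 %*% w$W2, 2L, w$b2, "+")
    cache[[key]] <<- list(A1 = A1, D1 = D1, mask = mask)
    E
  }
  Ed <- lsn_fwd(params$lsn_d, Xd, "lsn_d")
  Es <- lsn_fwd(params$lsn_s, Xs, "lsn_s")

  Ud <- if (is.null(params$proj_d)) Xd else Xd %*% params$proj_d
  Us <- if (is.null(params$proj_s)) Xs else Xs %*% params$proj_s
  pd <- ncol(Ud); ps <- ncol(Us)
  # batched outer products: cross[a, b, 1, i] = Ud[i, a] * Us[i, b]
  cross <- array(0, c(pd, ps, 1L, B))
  for (i in seq_len(B)) cross[, , 1L, i] <- tcrossprod(Ud[i, ], Us[i, ])
  cache$Ud <- Ud; cache$Us <- Us

  c1 <- conv2d_forward(cross, params$conv1$W, params$conv1$b)
  r1 <- relu(c1$out)
  p1 <- maxpool2_forward(r1)
  c2 <- conv2d_forward(p1$out, params$conv2$W, params$conv2$b)
  r2 <- relu(c2$out)
  p2 <- maxpool2_forward(r2)
  c3 <- conv2d_forward(p2$out, params$conv3$W, params$conv3$b)
  r3 <- relu(c3$out)
  p3 <- maxpool2_forward(r3)
  Fm <- t(matrix(p3$out, ncol = B))           # (B x flat), sample-major rows
  cache$conv <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                     c3 = c3, r3 = r3, p3 = p3, dim_p3 = dim(p3$out))

  Z <- cbind(Ed, Fm, Es)
  A1 <- sweep(Z %*% params$head$W1, 2L, params$head$b1, "+")
  H1 <- relu(A1)
  maskh <- dropout_mask(dim(H1), p)
  D1 <- if (is.null(maskh)) H1 else H1 * maskh
  y <- as.numeric(sweep(D1 %*% params$head$W2, 2L, params$head$b2, "+"))
  ylin <- y
  if (cfg$final_activation == "relu") y <- pmax(y, 0)
  if (any(!is.finite(y))) dga_stop("non-finite activation in classifier head",
                                   "dga_numeric_error")
  cache$head <- list(Z = Z, A1 = A1, D1 = D1, mask = maskh, ylin = ylin)
  cache$emb <- list(Ed = Ed, Es = Es, Fm = Fm)
  list(scores = y, cache = cache)
}

# Backward pass: dy is dLoss/dscore per sample. Returns gradients shaped like
# params.
backward_pass <- function(params, cfg, cache, dy) {
  B <- cache$B
  if (cfg$final_activation == "relu") dy <- dy * (cache$head$ylin > 0)
  dy <- matrix(dy, ncol = 1L)

  h <- cache$head
  dW2h <- crossprod(h$D1, dy); db2h <- sum(dy)
  dD1 <- tcrossprod(dy, params$head$W2)
  if (!is.null(h$mask)) dD1 <- dD1 * h$mask
  dA1 <- dD1 * (h$A1 > 0)
  dW1h <- crossprod(h$Z, dA1); db1h <- colSums(dA1)
  dZ <- tcrossprod(dA1, params$head$W1)

  k <- cfg$emb_dim
  flat <- ncol(cache$emb$Fm)
  dEd <- dZ[, seq_len(k), drop = FALSE]
  dFm <- dZ[, k + seq_len(flat), drop = FALSE]
  dEs <- dZ[, k + flat + seq_len(k), drop = FALSE]

  lsn_bwd <- function(w, cc, X, dE) {
    dW2 <- crossprod(cc$D1, dE); db2 <- colSums(dE)
    dD1 <- tcrossprod(dE, w$W2)
    if (!is.null(cc$mask)) dD1 <- dD1 * cc$mask
    dA1 <- dD1 * (cc$A1 > 0)
    list(W1 = crossprod(X, dA1), b1 = colSums(dA1), W2 = dW2, b2 = db2)
  }
  g_lsn_d <- lsn_bwd(params$lsn_d, cache$lsn_d, cache$Xd, dEd)
  g_lsn_s <- lsn_bwd(params$lsn_s, cache$lsn_s, cache$Xs, dEs)

  cv <- cache$conv
  dP3 <- array(t(dFm), cv$dim_p3)
  dR3 <- maxpool2_backward(dP3, cv$p3$cache)
  dC3 <- dR3 * (cv$c3$out > 0)
  b3 <- conv2d_backward(dC3, cv$c3$cache)
  dR2 <- maxpool2_backward(b3$dX, cv$p2$cache)
  dC2 <- dR2 * (cv$c2$out > 0)
  b2 <- conv2d_backward(dC2, cv$c2$cache)
  dR1 <- maxpool2_backward(b2$dX, cv$p1$cache)
  dC1 <- dR1 * (cv$c1$out > 0)
  b1 <- conv2d_backward(dC1, cv$c1$cache)

  dcross <- b1$dX                          # (pd, ps, 1, B)
  Ud <- cache$Ud; Us <- cache$Us
  dUd <- matrix(0, B, ncol(Ud)); dUs <- matrix(0, B, ncol(Us))
  for (i in seq_len(B)) {
    G <- dcross[, , 1L, i]
    dUd[i, ] <- G %*% Us[i, ]
    dUs[i, ] <- crossprod(G, Ud[i, ])
  }
  grads <- list(
    proj_d = if (is.null(params$proj_d)) NULL else crossprod(cache$Xd, dUd),
    proj_s = if (is.null(params$proj_s)) NULL else crossprod(cache$Xs, dUs),
    lsn_d = g_lsn_d, lsn_s = g_lsn_s,
    conv1 = list(W = b1$dW, b = b1$db),
    conv2 = list(W = b2$dW, b = b2$db),
    conv3 = list(W = b3$dW, b = b3$db),
    head = list(W1 = dW1h, b1 = db1h, W2 = dW2h, b2 = db2h)
  )
  grads
}

# Batch loss: drugs present in the batch each contribute one ZLPR term over
# their positive/negative scores; the batch loss is the mean over drug groups.
zlpr_batch <- function(scores, labels, drugs, s0) {
  groups <- split(seq_along(scores), drugs)
  loss <- 0
  grad <- numeric(length(scores))
  for (idx in groups) {
    loss <- loss + zlpr_loss(scores[idx], labels[idx], s0)
    grad[idx] <- zlpr_grad(scores[idx], labels[idx], s0)
  }
  list(loss = loss / length(groups), grad = grad / length(groups))
}

#' Train the DGANet model
#'
#' Fits the full network (projections, both LSNs, CSN, head) on labeled
#' drug-ADR pairs with the ZLPR loss and Adam. Within each mini-batch the
#' pairs of one drug form one multi-label group: its positive ADRs are pushed
#' above the anchor score and its negatives below, jointly.
#'
#' @param drug_feats numeric matrix of assembled drug features (rownames =
#'   drug ids), from [assemble_features()].
#' @param adr_feats numeric matrix of assembled ADR features (rownames =
#'   adr ids).
#' @param pairs data.frame with columns `drug_id`, `adr_id`, `label` (0/1).
#' @param cfg a [dganet_config()].
#' @param verbose print per-epoch loss.
#' @return a `dganet_model`: list with `params`, `cfg`, `history` (per-epoch
#'   mean training loss) and the feature dimensions.
#' @export
train_dganet <- function(drug_feats, adr_feats, pairs, cfg = dganet_config(),
                         verbose = FALSE) {
  stopifnot(is.matrix(drug_feats), is.matrix(adr_feats))
  missing_d <- setdiff(pairs$drug_id, rownames(drug_feats))
  missing_a <- setdiff(pairs$adr_id, rownames(adr_feats))
  if (length(missing_d) + length(missing_a) > 0L) {
    dga_stop(sprintf("pairs reference unknown entities: %s",
                     paste(c(missing_d, missing_a), collapse = ", ")),
             "dga_data_error")
  }
  n <- nrow(pairs)
  if (n == 0L) dga_stop("no training pairs", "dga_data_error")
  with_local_seed(cfg$seed, {
    params <- init_params(cfg, ncol(drug_feats), ncol(adr_feats))
    state <- adam_init(params)
    history <- numeric(cfg$epochs)
    t_step <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / cfg$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
        Xd <- drug_feats[pairs$drug_id[idx], , drop = FALSE]
        Xs <- adr_feats[pairs$adr_id[idx], , drop = FALSE]
        fw <- forward_pass(params, cfg, Xd, Xs, train = TRUE)
        zb <- zlpr_batch(fw$scores, pairs$label[idx], pairs$drug_id[idx], cfg$s0)
        if (!is.finite(zb$loss)) {
          dga_stop(sprintf("training diverged (non-finite loss) at epoch %d",
                           epoch), "dga_numeric_error")
        }
        grads <- backward_pass(params, cfg, fw$cache, zb$grad)
        t_step <- t_step + 1L
        upd <- adam_update(params, grads, state, cfg$learning_rate, t_step)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + zb$loss
      }
      history[epoch] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch, history[epoch]))
    }
    structure(list(params = params, cfg = cfg, history = history,
                   in_d = ncol(drug_feats), in_s = ncol(adr_feats)),
              class = "dganet_model")
  })
}

#' @export
print.dganet_model <- function(x, ...) {
  cat(sprintf("<dganet_model: drug width %d, ADR width %d, %d epochs, final loss %.4f>\n",
              x$in_d, x$in_s, length(x$history), utils::tail(x$history, 1L)))
  invisible(x)
}

#' Score drug-ADR pairs with a trained model
#'
#' Deterministic evaluation-mode forward pass (dropout disabled). Scores above
#' the anchor (0 by default) are interpreted as predicted associations.
#'
#' @param model a `dganet_model` from [train_dganet()].
#' @param drug_feats,adr_feats feature matrices as in [train_dganet()].
#' @param pairs data.frame with columns `drug_id`, `adr_id`.
#' @param batch_size evaluation batch size.
#' @return `pairs` with columns `score` and `predicted` (score > anchor).
#' @export
predict_dganet <- function(model, drug_feats, adr_feats, pairs,
                           batch_size = 512L) {
  stopifnot(inherits(model, "dganet_model"))
  if (ncol(drug_feats) != model$in_d || ncol(adr_feats) != model$in_s) {
    dga_stop("feature width mismatch with trained model", "dga_shape_error")
  }
  n <- nrow(pairs)
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    Xd <- drug_feats[pairs$drug_id[idx], , drop = FALSE]
    Xs <- adr_feats[pairs$adr_id[idx], , drop = FALSE]
    scores[idx] <- forward_pass(model$params, model$cfg, Xd, Xs,
                                train = FALSE)$scores
  }
  out <- pairs
  out$score <- scores
  out$predicted <- as.integer(scores > model$cfg$s0)
  out
}

#' Embed entity feature rows through a linear subnetwork
#'
#' Evaluation-mode LSN forward: `Linear(Dropout(ReLU(FC(x))))` with dropout
#' disabled, exposing the drug or ADR embeddings of a trained model.
#'
#' @param model a `dganet_model`.
#' @param x numeric matrix of feature rows (entities x width).
#' @param which `"drug"` or `"adr"`.
#' @return numeric matrix (entities x `emb_dim`).
#' @export
lsn_embed <- function(model, x, which = c("drug", "adr")) {
  which <- match.arg(which)
  w <- if (which == "drug") model$params$lsn_d else model$params$lsn_s
  need <- nrow(w$W1)
  if (ncol(x) != need) {
    dga_stop(sprintf("feature width %d does not match LSN input width %d",
                     ncol(x), need), "dga_shape_error")
  }
  H <- relu(sweep(x %*% w$W1, 2L, w$b1, "+"))
  sweep(H %*% w$W2, 2L, w$b2, "+")
}

#' Embed feature crosses through the convolutional subnetwork
#'
#' Evaluation-mode CSN forward: three (3x3 convolution + ReLU + 2x2 max pool)
#' stages followed by flattening.
#'
#' @param model a `dganet_model`.
#' @param crosses array of shape `(pd, ps, 1, B)` or a single `(pd, ps)`
#'   matrix from [feature_cross()].
#' @return numeric matrix (B x flattened width).
#' @export
csn_embed <- function(model, crosses) {
  if (is.matrix(crosses)) crosses <- array(crosses, c(dim(crosses), 1L, 1L))
  d <- dim(crosses)
  if (d[1L] < 4L || d[2L] < 4L) {
    dga_stop("cross smaller than the CSN receptive field (need >= 4 x 4)",
             "dga_config_error")
  }
  p <- model$params
  a <- relu(conv2d_forward(crosses, p$conv1$W, p$conv1$b, keep_cache = FALSE)$out)
  a <- maxpool2_forward(a)$out
  a <- relu(conv2d_forward(a, p$conv2$W, p$conv2$b, keep_cache = FALSE)$out)
  a <- maxpool2_forward(a)$out
  a <- relu(conv2d_forward(a, p$conv3$W, p$conv3$b, keep_cache = FALSE)$out)
  a <- maxpool2_forward(a)$out
  t(matrix(a, ncol = dim(a)[4L]))
}
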