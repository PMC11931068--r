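# Minimal neural-network primitives on base-R arrays, used by the DGANet
# model. Feature maps are arrays of shape (H, W, C, B): spatial dims first so
# shifted-window slices are contiguous, batch last. Convolutions are realized
# as im2col + one BLAS matmul; every op has a hand-derived backward pass that
# is validated against numerical differentiation in the test suite.

# -- 2d convolution, 3x3 kernel, stride 1, zero 'same' padding --------------

# W: array (kh, kw, Cin, Cout); returns list(out, cache) in train mode.
conv2d_forward <- function(X, W, b, keep_cache = TRUE) {
  d <- dim(X); H <- d[1L]; Wd <- d[2L]; C <- d[3L]; B <- d[4L]
  kh <- dim(W)[1L]; kw <- dim(W)[2L]
  stopifnot(dim(W)[3L] == C)
  OC <- dim(W)[4L]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Xp <- array(0, c(H + 2L * ph, Wd + 2L * pw, C, B))
  Xp[ph + seq_len(H), pw + seq_len(Wd), , ] <- X
  # im2col: one column block of width C per kernel shift
  M <- matrix(0, nrow = H * Wd * B, ncol = kh * kw * C)
  s <- 0L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      blk <- Xp[ki:(ki + H - 1L), kj:(kj + Wd - 1L), , , drop = FALSE]
      M[, s * C + seq_len(C)] <- matrix(aperm(blk, c(1L, 2L, 4L, 3L)),
                                        nrow = H * Wd * B)
      s <- s + 1L
    }
  }
  Wmat <- matrix(aperm(W, c(3L, 1L, 2L, 4L)), ncol = OC)  # rows: shift-major, channel within
  Ymat <- M %*% Wmat
  Ymat <- sweep(Ymat, 2L, b, "+")
  Y <- aperm(array(Ymat, c(H, Wd, B, OC)), c(1L, 2L, 4L, 3L))
  list(out = Y, cache = if (keep_cache) list(M = M, dimX = d, W = W) else NULL)
}

conv2d_backward <- function(dY, cache) {
  d <- cache$dimX; H <- d[1L]; Wd <- d[2L]; C <- d[3L]; B <- d[4L]
  W <- cache$W
  kh <- dim(W)[1L]; kw <- dim(W)[2L]; OC <- dim(W)[4L]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dYmat <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), nrow = H * Wd * B)
  dWmat <- crossprod(cache$M, dYmat)                      # (kh*kw*C, OC)
  dW <- aperm(array(dWmat, c(C, kh, kw, OC)), c(2L, 3L, 1L, 4L))
  db <- colSums(dYmat)
  Wmat <- matrix(aperm(W, c(3L, 1L, 2L, 4L)), ncol = OC)
  dM <- tcrossprod(dYmat, Wmat)                           # (HWB, kh*kw*C)
  dXp <- array(0, c(H + 2L * ph, Wd + 2L * pw, C, B))
  s <- 0L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      blk <- aperm(array(dM[, s * C + seq_len(C)], c(H, Wd, B, C)),
                   c(1L, 2L, 4L, 3L))
      dXp[ki:(ki + H - 1L), kj:(kj + Wd - 1L), , ] <-
        dXp[ki:(ki + H - 1L), kj:(kj + Wd - 1L), , , drop = FALSE] + blk
      s <- s + 1L
    }
  }
  dX <- dXp[ph + seq_len(H), pw + seq_len(Wd), , , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# -- 2x2 max pooling, stride 2; odd extents padded with -Inf (ceil mode) ----

maxpool2_forward <- function(X) {
  d <- dim(X); H <- d[1L]; Wd <- d[2L]; C <- d[3L]; B <- d[4L]
  Ho <- as.integer(ceiling(H / 2)); Wo <- as.integer(ceiling(Wd / 2))
  Xp <- array(-Inf, c(2L * Ho, 2L * Wo, C, B))
  Xp[seq_len(H), seq_len(Wd), , ] <- X
  ri <- seq(1L, 2L * Ho, by = 2L); ci <- seq(1L, 2L * Wo, by = 2L)
  s <- list(Xp[ri, ci, , , drop = FALSE], Xp[ri + 1L, ci, , , drop = FALSE],
            Xp[ri, ci + 1L, , , drop = FALSE], Xp[ri + 1L, ci + 1L, , , drop = FALSE])
  Y <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  arg <- array(1L, dim(Y))
  arg[s[[2L]] > s[[1L]] & s[[2L]] >= s[[3L]] & s[[2L]] >= s[[4L]]] <- 2L
  arg[s[[3L]] > s[[1L]] & s[[3L]] > s[[2L]] & s[[3L]] >= s[[4L]]] <- 3L
  arg[s[[4L]] > s[[1L]] & s[[4L]] > s[[2L]] & s[[4L]] > s[[3L]]] <- 4L
  list(out = Y, cache = list(arg = arg, dimX = d))
}

maxpool2_backward <- function(dY, cache) {
  d <- cache$dimX; H <- d[1L]; Wd <- d[2L]; C <- d[3L]; B <- d[4L]
  Ho <- dim(dY)[1L]; Wo <- dim(dY)[2L]
  dXp <- array(0, c(2L * Ho, 2L * Wo, C, B))
  ri <- seq(1L, 2L * Ho, by = 2L); ci <- seq(1L, 2L * Wo, by = 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    mask <- cache$arg == k
    if (!any(mask)) next
    sub <- dXp[ri + offs[[k]][1L], ci + offs[[k]][2L], , , drop = FALSE]
    sub[mask] <- sub[mask] + dY[mask]
    dXp[ri + offs[[k]][1L], ci + offs[[k]][2L], , ] <- sub
  }
  dXp[seq_len(H), seq_len(Wd), , , drop = FALSE]
}

# -- misc ---------------------------------------------------------------------

relu <- function(x) pmax(x, 0)

dropout_mask <- function(dims, p) {
  if (p <= 0) return(NULL)
  array(stats::rbinom(prod(dims), 1L, 1 - p) / (1 - p), dims)
}

# He-scaled Gaussian initialization
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) adam_init(p)
    else list(m = array(0, dim(p) %||% length(p)),
              v = array(0, dim(p) %||% length(p)))
  })
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    if (is.null(params[[nm]])) next
    if (is.list(params[[nm]]) && !is.null(names(params[[nm]]))) {
      upd <- adam_update(params[[nm]], grads[[nm]], state[[nm]], lr, t,
                         beta1, beta2, eps)
      params[[nm]] <- upd$params
      state[[nm]] <- upd$state
    } else {
      g <- grads[[nm]]
      state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
      state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
      mhat <- state[[nm]]$m / (1 - beta1^t)
      vhat <- state[[nm]]$v / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
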