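# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (double loops, path enumeration) so they share no code
# path with the implementations they check.

naive_jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

naive_tanimoto <- function(x, y) {
  num <- sum(x * y)
  den <- sum(x^2) + sum(y^2) - num
  if (den == 0) 0 else num / den
}

naive_cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) 0 else sum(x * y) / (nx * ny)
}

# pairwise similarity matrix from a per-pair function, diagonal forced to 1
naive_pairwise <- function(items, fun) {
  n <- length(items)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j) 1 else fun(items[[i]], items[[j]])
    }
  }
  m
}

# all-paths semantic contribution: C_s(n) = max over directed paths s->n of
# delta^length, found by exhaustive depth-first enumeration
brute_semantic_contributions <- function(dag, s, delta) {
  best <- stats::setNames(1, s)
  recurse <- function(node, value) {
    for (p in dag$parents[[node]]) {
      v <- value * delta
      if (is.na(best[p]) || v > best[[p]]) best[p] <<- v
      recurse(p, v)
    }
  }
  recurse(s, 1)
  best
}

# AUROC as the fraction of (positive, negative) score pairs ranked correctly,
# ties counting one half
brute_auroc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (n in ns) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

# AUPRC by walking thresholds at the end of each tied-score block
brute_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  total <- 0
  npos <- sum(labels == 1)
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    total <- total + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  total
}

# random parent-list DAG (node i may only point to earlier nodes -> acyclic)
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[1L]] <- character()
  for (i in seq_len(n)[-1L]) {
    k <- sample(1:min(2L, i - 1L), 1L)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
  }
  ontology_dag(parents)
}

# write a small TSV fixture and return its path
tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small random gene-set collection
random_sets <- function(n_sets, universe_size, max_size, seed) {
  set.seed(seed)
  genes <- paste0("g", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(0:max_size, 1L))
  })
  stats::setNames(sets, paste0("e", seq_len(n_sets)))
}

# bare numeric matrix of a sim_matrix (drop class/kind for value comparisons)
sim_values <- function(x) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# compact model configuration for fast training in tests
tiny_cfg <- function(...) {
  defaults <- list(lsn_hidden = 16L, head_hidden = 8L, emb_dim = 8L,
                   conv_channels = c(2L, 3L, 4L), proj_d = 8L, proj_s = 8L,
                   epochs = 10L, batch_size = 64L, dropout = 0.1)
  do.call(dganet_config, utils::modifyList(defaults, list(...)))
}
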