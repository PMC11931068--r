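# Class-balanced k-fold cross-validation, ranking/classification metrics and
# long-tail statistics.

#' Sample balanced negative pairs
#'
#' Draws `n` distinct (drug, adr) pairs uniformly without replacement from the
#' universe, excluding every known positive pair. Used to match the negative
#' class size to the positive class size in training and test sets.
#'
#' @param positives data.frame with columns `drug_id`, `adr_id` (known
#'   positives to exclude).
#' @param drugs,adrs character vectors spanning the pair universe.
#' @param n number of negatives to draw.
#' @param seed integer seed.
#' @param exclude optional extra data.frame of pairs to exclude (e.g.
#'   negatives already drawn for another split).
#' @return data.frame with columns `drug_id`, `adr_id`, `label` (all 0).
#' @export
balanced_negative_sample <- function(positives, drugs, adrs, n, seed,
                                     exclude = NULL) {
  pair_key <- function(d, a) paste(d, a, sep = "\r")
  banned <- pair_key(positives$drug_id, positives$adr_id)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    banned <- c(banned, pair_key(exclude$drug_id, exclude$adr_id))
  }
  total <- length(drugs) * length(adrs)
  if (total - length(unique(banned)) < n) {
    dga_stop("pair universe too small for balanced negative sampling",
             "dga_data_error")
  }
  if (n == 0L) {
    return(data.frame(drug_id = character(), adr_id = character(),
                      label = integer()))
  }
  with_local_seed(seed, {
    chosen <- character(0)
    banned_set <- unique(banned)
    while (length(chosen) < n) {
      need <- n - length(chosen)
      cand <- pair_key(sample(drugs, 2L * need + 10L, replace = TRUE),
                       sample(adrs, 2L * need + 10L, replace = TRUE))
      cand <- setdiff(unique(cand), c(banned_set, chosen))
      chosen <- c(chosen, utils::head(cand, need))
    }
    parts <- strsplit(chosen, "\r", fixed = TRUE)
    data.frame(drug_id = vapply(parts, `[`, "", 1L),
               adr_id = vapply(parts, `[`, "", 2L),
               label = 0L, stringsAsFactors = FALSE)
  })
}

#' Build a class-balanced k-fold cross-validation plan
#'
#' Known positive pairs are split into k folds; each fold holds out one part
#' for testing and trains on the rest. Train and test negatives are sampled to
#' match their positive counts, never collide with any known positive, and
#' train/test negatives are disjoint. The fold's `mask` lists the held-out
#' positive pairs, to be zeroed when building association-profile features.
#'
#' @param assoc data.frame with columns `drug_id`, `adr_id`, `label`; the
#'   `label == 1` rows are the known positives.
#' @param k number of folds (>= 2).
#' @param drugs,adrs pair universe (defaults: entities seen in `assoc`).
#' @param seed integer seed; the same seed reproduces the identical plan.
#' @return a `fold_plan`: list of k folds, each with `train` and `test`
#'   data.frames (`drug_id`, `adr_id`, `label`) and `mask` (held-out positive
#'   pairs).
#' @export
make_fold_plan <- function(assoc, k = 5L, drugs = NULL, adrs = NULL, seed = 1L) {
  if (k < 2L) dga_stop("need k >= 2 folds", "dga_config_error")
  drugs <- drugs %||% sort(unique(assoc$drug_id))
  adrs <- adrs %||% sort(unique(assoc$adr_id))
  pos <- assoc[assoc$label == 1L, c("drug_id", "adr_id"), drop = FALSE]
  pos <- pos[!duplicated(paste(pos$drug_id, pos$adr_id, sep = "\r")), ,
             drop = FALSE]
  npos <- nrow(pos)
  if (npos < k) dga_stop("fewer positives than folds", "dga_data_error")
  fold_of <- with_local_seed(derive_seed(seed, "folds"), {
    sample(rep_len(seq_len(k), npos))
  })
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_pos <- pos[fold_of == f, , drop = FALSE]
    train_pos <- pos[fold_of != f, , drop = FALSE]
    test_pos$label <- 1L
    train_pos$label <- 1L
    train_neg <- balanced_negative_sample(pos, drugs, adrs, nrow(train_pos),
                                          derive_seed(seed, paste0("trneg", f)))
    test_neg <- balanced_negative_sample(pos, drugs, adrs, nrow(test_pos),
                                         derive_seed(seed, paste0("teneg", f)),
                                         exclude = train_neg)
    folds[[f]] <- list(
      train = rbind(train_pos, train_neg),
      test = rbind(test_pos, test_neg),
      mask = test_pos[, c("drug_id", "adr_id"), drop = FALSE]
    )
  }
  structure(list(folds = folds, k = k, drugs = drugs, adrs = adrs, seed = seed),
            class = "fold_plan")
}

#' Ranking and classification metrics for scored pairs
#'
#' AUROC via the rank statistic with average ranks on ties (equivalent to the
#' Wilcoxon/Mann-Whitney estimator); AUPRC via non-interpolated step
#' integration of the precision-recall curve; accuracy and Matthews
#' correlation coefficient at `score > threshold`, with any zero MCC
#' denominator defined as 0. With a single-class label vector, AUROC/AUPRC
#' are undefined and reported as `NaN` with a warning.
#'
#' @param scores numeric vector of model scores.
#' @param labels 0/1 vector of true labels.
#' @param threshold classification threshold on the score.
#' @return one-row data.frame: `auroc`, `auprc`, `acc`, `mcc`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  if (length(scores) != length(labels)) {
    dga_stop("scores and labels differ in length", "dga_contract_error")
  }
  if (!all(labels %in% c(0, 1))) dga_stop("labels must be 0/1",
                                          "dga_contract_error")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    warning("single-class labels: AUROC/AUPRC undefined")
    auroc <- auprc <- NaN
  } else {
    r <- rank(scores, ties.method = "average")
    auroc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]
    sc <- scores[ord]
    tp <- cumsum(lab)
    fp <- cumsum(1 - lab)
    # evaluate the PR curve only at the last index of each tied score block
    last <- c(sc[-1] != sc[-length(sc)], TRUE)
    tp <- tp[last]; fp <- fp[last]
    prec <- tp / (tp + fp)
    rec <- tp / npos
    drec <- diff(c(0, rec))
    auprc <- sum(prec * drec)
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / length(labels)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  data.frame(auroc = auroc, auprc = auprc, acc = acc, mcc = mcc)
}

#' Frequency-rank statistics of a pair table
#'
#' Counts pairs per left-column entity and sorts descending (ties broken by
#' entity id), the standard view of the long-tail shape of association data:
#' few drugs carry most associations, most drugs carry few.
#'
#' @param pairs a two-or-more-column data.frame; the first column is the
#'   entity, each row one association.
#' @return data.frame with columns `entity`, `count`, sorted by decreasing
#'   count.
#' @export
frequency_rank <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(entity = character(), count = integer()))
  }
  tab <- table(pairs[[1L]])
  out <- data.frame(entity = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Assert the leakage guard: the fold's masked association matrix must be zero
# at every held-out pair position.
assert_mask_zero <- function(dsa_sim, mask) {
  A <- attr(dsa_sim, "assoc_matrix")
  if (nrow(mask) == 0L) return(invisible(TRUE))
  keep <- mask$drug_id %in% rownames(A) & mask$adr_id %in% colnames(A)
  vals <- A[cbind(match(mask$drug_id[keep], rownames(A)),
                  match(mask$adr_id[keep], colnames(A)))]
  if (any(vals != 0)) {
    dga_stop("leakage guard violated: held-out pair present in DSA feature matrix",
             "dga_leakage_error")
  }
  invisible(TRUE)
}

#' Run class-balanced cross-validation of the full pipeline
#'
#' For each fold: association-profile (DSA) feature blocks, if requested, are
#' rebuilt with the fold's held-out pairs masked to zero (and the guard that
#' they are zero is asserted, not assumed); the model is trained on the fold's
#' balanced training pairs only; metrics are computed on the balanced test
#' pairs using raw (pre-threshold) scores.
#'
#' @param features named list with elements `drug` and `adr`, each a named
#'   list of [sim_matrix()] blocks (`cs`, `ge`, `cgi` / `mesh`, `gda`).
#' @param assoc association table (`drug_id`, `adr_id`, `label`).
#' @param drug_blocks,adr_blocks character vectors naming the blocks to use;
#'   `"dsa"` adds the masked association-profile block.
#' @param cfg a [dganet_config()].
#' @param k number of folds.
#' @param seed root seed; fold splitting, negative sampling and per-fold model
#'   seeds all derive from it.
#' @param drugs,adrs pair universe (defaults: ids of the feature blocks).
#' @param verbose print per-fold progress.
#' @return a data.frame with one row per fold plus a `summary` row holding
#'   mean and (in `*_sd` columns) standard deviation across folds.
#' @export
run_cross_validation <- function(features, assoc,
                                 drug_blocks = c("cgi"),
                                 adr_blocks = c("mesh", "gda"),
                                 cfg = dganet_config(), k = 5L, seed = 1L,
                                 drugs = NULL, adrs = NULL, verbose = FALSE) {
  known_d <- c("cs", "ge", "cgi", "dsa")
  known_a <- c("mesh", "gda", "dsa")
  if (!all(drug_blocks %in% known_d)) {
    dga_stop(sprintf("unknown drug block(s): %s",
                     paste(setdiff(drug_blocks, known_d), collapse = ", ")),
             "dga_config_error")
  }
  if (!all(adr_blocks %in% known_a)) {
    dga_stop(sprintf("unknown ADR block(s): %s",
                     paste(setdiff(adr_blocks, known_a), collapse = ", ")),
             "dga_config_error")
  }
  for (b in setdiff(drug_blocks, "dsa")) {
    if (is.null(features$drug[[b]])) {
      dga_stop(sprintf("requested drug block '%s' not supplied", b),
               "dga_config_error")
    }
  }
  for (b in setdiff(adr_blocks, "dsa")) {
    if (is.null(features$adr[[b]])) {
      dga_stop(sprintf("requested ADR block '%s' not supplied", b),
               "dga_config_error")
    }
  }
  pick_ids <- function(blocks, wanted, supplied, what) {
    if (!is.null(supplied)) return(supplied)
    nm <- setdiff(wanted, "dsa")
    ref <- if (length(nm) > 0L) blocks[[nm[1L]]] else blocks[[1L]]
    if (is.null(ref)) {
      dga_stop(sprintf("cannot infer %s universe: pass %s= explicitly", what, what),
               "dga_config_error")
    }
    rownames(ref)
  }
  drugs <- pick_ids(features$drug, drug_blocks, drugs, "drugs")
  adrs <- pick_ids(features$adr, adr_blocks, adrs, "adrs")

  plan <- make_fold_plan(assoc, k = k, drugs = drugs, adrs = adrs,
                         seed = derive_seed(seed, "plan"))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- plan$folds[[f]]
    dblocks <- features$drug[setdiff(drug_blocks, "dsa")]
    ablocks <- features$adr[setdiff(adr_blocks, "dsa")]
    if ("dsa" %in% drug_blocks) {
      dsa_d <- dsa_profile_similarity(assoc, mask = fold$mask, axis = "drug",
                                      drugs = drugs, adrs = adrs)
      assert_mask_zero(dsa_d, fold$mask)
      dblocks$dsa <- dsa_d
    }
    if ("dsa" %in% adr_blocks) {
      dsa_a <- dsa_profile_similarity(assoc, mask = fold$mask, axis = "adr",
                                      drugs = drugs, adrs = adrs)
      assert_mask_zero(dsa_a, fold$mask)
      ablocks$dsa <- dsa_a
    }
    drug_feats <- assemble_features(dblocks, order = drugs)
    adr_feats <- assemble_features(ablocks, order = adrs)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(seed, paste0("model", f))
    model <- train_dganet(drug_feats, adr_feats, fold$train, fold_cfg)
    pred <- predict_dganet(model, drug_feats, adr_feats, fold$test)
    m <- compute_metrics(pred$score, fold$test$label, threshold = cfg$s0)
    rows[[f]] <- cbind(data.frame(fold = as.character(f)), m)
    if (verbose) {
      message(sprintf("fold %d: AUROC %.3f  AUPRC %.3f  Acc %.3f  MCC %.3f",
                      f, m$auroc, m$auprc, m$acc, m$mcc))
    }
  }
  per_fold <- do.call(rbind, rows)
  mets <- c("auroc", "auprc", "acc", "mcc")
  summary_row <- data.frame(fold = "summary")
  for (m in mets) {
    summary_row[[m]] <- mean(per_fold[[m]])
    summary_row[[paste0(m, "_sd")]] <- stats::sd(per_fold[[m]])
  }
  for (m in paste0(mets, "_sd")) per_fold[[m]] <- NA_real_
  out <- rbind(per_fold, summary_row)
  rownames(out) <- NULL
  attr(out, "plan") <- plan
  out
}
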