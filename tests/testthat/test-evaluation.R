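# Fold construction, metrics and the leakage guard.

toy_assoc <- function(npos = 10L) {
  data.frame(drug_id = sprintf("d%02d", rep(1:5, 2))[seq_len(npos)],
             adr_id = sprintf("a%02d", seq_len(npos)), label = 1L,
             stringsAsFactors = FALSE)
}

test_that("fold plan arithmetic: balanced train and test sets", {
  assoc <- toy_assoc(10L)
  drugs <- sprintf("d%02d", 1:8)
  adrs <- sprintf("a%02d", 1:12)
  plan <- make_fold_plan(assoc, k = 5L, drugs = drugs, adrs = adrs, seed = 3L)
  for (fold in plan$folds) {
    expect_equal(sum(fold$train$label == 1), 8L)
    expect_equal(sum(fold$train$label == 0), 8L)
    expect_equal(sum(fold$test$label == 1), 2L)
    expect_equal(sum(fold$test$label == 0), 2L)
    # train and test pair sets are disjoint
    key <- function(df) paste(df$drug_id, df$adr_id)
    expect_length(intersect(key(fold$train), key(fold$test)), 0L)
  }
})

test_that("test positives partition the positives across folds", {
  assoc <- toy_assoc(10L)
  plan <- make_fold_plan(assoc, k = 5L, drugs = sprintf("d%02d", 1:8),
                         adrs = sprintf("a%02d", 1:12), seed = 3L)
  key <- function(df) paste(df$drug_id, df$adr_id)
  test_keys <- lapply(plan$folds, function(f) key(f$test[f$test$label == 1, ]))
  expect_setequal(unlist(test_keys), key(assoc))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(test_keys[[i]], test_keys[[j]]), 0L)
  }
})

test_that("fold plans are seed-reproducible and never reuse positives as negatives", {
  assoc <- toy_assoc(10L)
  drugs <- sprintf("d%02d", 1:8); adrs <- sprintf("a%02d", 1:12)
  p1 <- make_fold_plan(assoc, 5L, drugs, adrs, seed = 7L)
  p2 <- make_fold_plan(assoc, 5L, drugs, adrs, seed = 7L)
  expect_identical(p1, p2)
  p3 <- make_fold_plan(assoc, 5L, drugs, adrs, seed = 8L)
  expect_false(identical(p1, p3))
  key <- function(df) paste(df$drug_id, df$adr_id)
  pos_keys <- key(assoc)
  for (f in p1$folds) {
    negs <- rbind(f$train[f$train$label == 0, ], f$test[f$test$label == 0, ])
    expect_length(intersect(key(negs), pos_keys), 0L)
    expect_false(anyDuplicated(key(negs)) > 0)
  }
})

test_that("balanced negative sampling excludes positives and respects n", {
  pos <- toy_assoc(6L)
  drugs <- sprintf("d%02d", 1:5); adrs <- sprintf("a%02d", 1:6)
  neg <- balanced_negative_sample(pos, drugs, adrs, 6L, seed = 1L)
  expect_equal(nrow(neg), 6L)
  expect_true(all(neg$label == 0L))
  expect_length(intersect(paste(neg$drug_id, neg$adr_id),
                          paste(pos$drug_id, pos$adr_id)), 0L)
  expect_equal(nrow(balanced_negative_sample(pos, drugs, adrs, 0L, 1L)), 0L)
  expect_error(balanced_negative_sample(pos, drugs[1:2], adrs[1:2], 10L, 1L),
               class = "dga_data_error")
})

test_that("metrics match closed-form confusion arithmetic", {
  # TP=4, TN=3, FP=2, FN=1 at threshold 0
  scores <- c(rep(1, 4), rep(-1, 3), rep(1, 2), rep(-1, 1))
  labels <- c(rep(1, 4), rep(0, 3), rep(0, 2), rep(1, 1))
  m <- compute_metrics(scores, labels)
  expect_equal(m$acc, 0.7)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-12)
})

test_that("AUROC equals brute-force pairwise comparison, ties included", {
  expect_equal(compute_metrics(c(0.9, 0.8, 0.3), c(1, 0, 1))$auroc, 0.5)
  set.seed(21)
  for (i in 1:30) {
    n <- sample(4:200, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    m <- compute_metrics(scores, labels)
    expect_equal(m$auroc, brute_auroc(scores, labels), tolerance = 1e-12)
    expect_equal(m$auprc, brute_auprc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  ours <- compute_metrics(scores, labels)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("degenerate predictions give MCC 0 and single-class labels give NaN", {
  expect_equal(compute_metrics(c(1, 1, 1), c(1, 0, 1))$mcc, 0)
  expect_warning(m <- compute_metrics(c(1, 2), c(1, 1)), "single-class")
  expect_true(is.nan(m$auroc))
  expect_true(is.nan(m$auprc))
})

test_that("frequency_rank counts and orders entities", {
  pairs <- data.frame(drug = c("d1", "d1", "d2"), adr = c("a1", "a2", "a1"))
  fr <- frequency_rank(pairs)
  expect_equal(fr$entity, c("d1", "d2"))
  expect_equal(fr$count, c(2L, 1L))
  expect_equal(nrow(frequency_rank(pairs[0, ])), 0L)
  # ties break by id
  pairs2 <- data.frame(x = c("b", "a"), y = c("u", "v"))
  expect_equal(frequency_rank(pairs2)$entity, c("a", "b"))
})

test_that("the leakage guard holds in every fold and catches violations", {
  ds <- worked_example()
  assoc <- ds$assoc
  plan <- make_fold_plan(assoc, k = 3L, drugs = ds$drugs, adrs = ds$adrs,
                         seed = 2L)
  for (fold in plan$folds) {
    s <- dsa_profile_similarity(assoc, mask = fold$mask, axis = "drug",
                                drugs = ds$drugs, adrs = ds$adrs)
    A <- attr(s, "assoc_matrix")
    vals <- A[cbind(fold$mask$drug_id, fold$mask$adr_id)]
    expect_true(all(vals == 0))
    expect_silent(dganet:::assert_mask_zero(s, fold$mask))
    # an injected violation is caught
    A[cbind(fold$mask$drug_id[1], fold$mask$adr_id[1])] <- 1
    attr(s, "assoc_matrix") <- A
    expect_error(dganet:::assert_mask_zero(s, fold$mask),
                 class = "dga_leakage_error")
  }
})

test_that("cross-validation runs end to end with DSA blocks and reports k+1 rows", {
  set.seed(14)
  ds <- generate_dataset(synthetic_config(n_drugs = 12L, n_adrs = 14L,
                                          n_genes = 60L, n_ontology_nodes = 40L,
                                          genes_per_drug = 8L, genes_per_adr = 10L,
                                          n_modules = 3L, pi0 = 0.08, seed = 5L))
  feats <- build_feature_blocks(ds)
  rep <- suppressMessages(run_cross_validation(
    feats, ds$assoc, drug_blocks = c("cgi", "dsa"),
    adr_blocks = c("gda", "dsa"), cfg = tiny_cfg(epochs = 3L), k = 3L,
    seed = 4L))
  expect_equal(nrow(rep), 4L)
  expect_equal(rep$fold, c("1", "2", "3", "summary"))
  expect_true(all(is.finite(rep$auroc[1:3])))
  expect_error(run_cross_validation(feats, ds$assoc, drug_blocks = "bogus"),
               "bogus", class = "dga_config_error")
})
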