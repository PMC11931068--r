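# The synthetic generator: structure, determinism, the planted probability
# model and round-trips through the table writers.

test_that("generated ontologies are rooted, acyclic and deterministic", {
  one <- generate_ontology(1L, seed = 1L)
  expect_equal(length(one$nodes), 1L)
  expect_equal(n_edges(one), 0L)

  dag <- generate_ontology(20L, max_children = 3L, seed = 2L)
  expect_equal(length(dag$nodes), 20L)
  root <- dag$nodes[1L]
  for (n in setdiff(dag$nodes, root)) {
    expect_true(root %in% ancestors(dag, n))  # every node reaches the root
  }
  dag2 <- generate_ontology(20L, max_children = 3L, seed = 2L)
  expect_identical(dag, dag2)
  expect_false(identical(dag, generate_ontology(20L, max_children = 3L,
                                                seed = 3L)))
})

test_that("datasets are identical under one config, byte-for-byte through writers", {
  cfg <- synthetic_config(n_drugs = 10L, n_adrs = 12L, n_genes = 50L,
                          n_ontology_nodes = 30L, genes_per_drug = 6L,
                          genes_per_adr = 8L, seed = 9L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("emitted tables survive the reader round-trip unchanged", {
  ds <- generate_dataset(synthetic_config(n_drugs = 8L, n_adrs = 10L,
                                          n_genes = 40L, n_ontology_nodes = 25L,
                                          genes_per_drug = 5L, genes_per_adr = 6L,
                                          n_modules = 2L, seed = 4L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  suppressMessages({
    cgi <- read_cgi(file.path(dir, "cgi.tsv"))
    gda <- read_gda(file.path(dir, "gda.tsv"))
  })
  expect_equal(nrow(cgi), nrow(ds$cgi))
  expect_setequal(paste(cgi$chemical_id, cgi$gene_symbol),
                  paste(ds$cgi$chemical_id, ds$cgi$gene_symbol))
  expect_equal(nrow(gda), nrow(ds$gda))
  dag <- read_mesh_tree(file.path(dir, "mesh_tree.tsv"))
  expect_setequal(dag$nodes, ds$ontology$nodes)
  expect_equal(lapply(dag$parents[sort(dag$nodes)], sort),
               lapply(ds$ontology$parents[sort(ds$ontology$nodes)], sort))
  ge <- read_ge_signatures(file.path(dir, "ge_signatures.tsv"))
  expect_equal(ge, ds$ge, tolerance = 1e-12)
  fps <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  expect_equal(unname(fps), unname(ds$fps))
  assoc <- read_associations(file.path(dir, "associations.tsv"))
  expect_equal(assoc, ds$assoc)
})

test_that("the planted probability model follows pi0 + beta * Jaccard", {
  # beta = 1, tiny pi0: identical gene sets are certain, disjoint nearly never
  cfg <- synthetic_config(n_drugs = 6L, n_adrs = 6L, n_genes = 30L,
                          n_ontology_nodes = 20L, genes_per_drug = 5L,
                          genes_per_adr = 5L, beta = 1, pi0 = 1e-3, seed = 3L)
  ds <- generate_dataset(cfg)
  J <- outer(seq_along(ds$drugs), seq_along(ds$adrs), Vectorize(function(i, j) {
    naive_jaccard_sets(ds$latent$drug_genes[[i]], ds$latent$adr_genes[[j]])
  }))
  expect_equal(unname(ds$latent$prob), pmin(1, 1e-3 + J), tolerance = 1e-12)

  # observed positive rate within binomial error of the analytic expectation
  cfg2 <- synthetic_config(n_drugs = 30L, n_adrs = 40L, n_genes = 200L,
                           genes_per_drug = 20L, genes_per_adr = 25L,
                           beta = 0.9, pi0 = 0.05, seed = 1L)
  ds2 <- generate_dataset(cfg2)
  expected <- sum(ds2$latent$prob)
  sd_bin <- sqrt(sum(ds2$latent$prob * (1 - ds2$latent$prob)))
  observed <- nrow(ds2$assoc)
  expect_lt(abs(observed - expected), 4 * sd_bin)

  # beta = 0: labels independent of overlap (positive rate ~ pi0)
  cfg0 <- synthetic_config(n_drugs = 30L, n_adrs = 40L, beta = 0, pi0 = 0.05,
                           seed = 2L)
  ds0 <- generate_dataset(cfg0)
  expect_true(all(ds0$latent$prob == 0.05))
})

test_that("gene sharing lifts fingerprint and signature similarity", {
  ds <- generate_dataset(synthetic_config(seed = 6L))
  J <- outer(seq_along(ds$drugs), seq_along(ds$drugs), Vectorize(function(i, j) {
    naive_jaccard_sets(ds$latent$drug_genes[[i]], ds$latent$drug_genes[[j]])
  }))
  cs <- unclass(tanimoto_similarity(ds$fps))
  ge <- unclass(cosine_similarity_ge(ds$ge))
  up <- upper.tri(J)
  linked <- J[up] > 0.2
  expect_gt(mean(cs[up][linked]), mean(cs[up][!linked]))
  expect_gt(mean(ge[up][linked]), mean(ge[up][!linked]))
})

test_that("ADR ids are ontology nodes and similar ADRs sit near each other", {
  ds <- generate_dataset(synthetic_config(seed = 8L))
  expect_true(all(ds$adrs %in% ds$ontology$nodes))
  expect_equal(anyDuplicated(ds$adrs), 0L)
  mesh <- unclass(mesh_semantic_similarity(ds$ontology, ds$adrs))
  same <- outer(ds$latent$adr_module, ds$latent$adr_module, "==")
  up <- upper.tri(mesh)
  expect_gt(mean(mesh[up][same[up]]), mean(mesh[up][!same[up]]))
})

test_that("long-tail mode skews the drug association counts", {
  base <- synthetic_config(seed = 10L)
  lt <- synthetic_config(seed = 10L, long_tail = TRUE)
  fr <- frequency_rank(generate_dataset(lt)$assoc)
  fr0 <- frequency_rank(generate_dataset(base)$assoc)
  # the top drug takes a larger share of all pairs under the long tail
  expect_gt(fr$count[1] / sum(fr$count), fr0$count[1] / sum(fr0$count))
})

test_that("cross-validated AUROC is non-decreasing in the signal strength", {
  cfg <- dganet_config(lsn_hidden = 64L, head_hidden = 32L, emb_dim = 16L,
                       conv_channels = c(4L, 8L, 16L), proj_d = 12L,
                       proj_s = 12L, epochs = 30L, dropout = 0.2)
  for (sd in 1:3) {
    stats_by_beta <- sapply(c(0, 0.5, 0.9), function(b) {
      ds <- generate_dataset(synthetic_config(seed = sd, beta = b, pi0 = 0.05))
      feats <- build_feature_blocks(ds)
      rep <- run_cross_validation(feats, ds$assoc, drug_blocks = "cgi",
                                  adr_blocks = c("mesh", "gda"), cfg = cfg,
                                  k = 3L, seed = sd)
      c(mean = rep$auroc[rep$fold == "summary"],
        sd = rep$auroc_sd[rep$fold == "summary"])
    })
    pooled <- sqrt(mean(stats_by_beta["sd", ]^2))
    expect_gte(stats_by_beta["mean", 2], stats_by_beta["mean", 1] - pooled)
    expect_gte(stats_by_beta["mean", 3], stats_by_beta["mean", 2] - pooled)
    # and the planted end clearly beats the null end
    expect_gt(stats_by_beta["mean", 3], stats_by_beta["mean", 1])
  }
})

test_that("the worked example is stable and hand-checkable", {
  we1 <- worked_example()
  we2 <- worked_example()
  expect_identical(we1, we2)
  fb <- build_feature_blocks(we1)
  expect_equal(fb$drug$cgi["d1", "d2"], 0.5)
  expect_equal(fb$adr$mesh["a1", "a2"], 1 / 3)
  expect_equal(fb$adr$gda["a1", "a2"], 0.25)
  expect_equal(fb$drug$cs["d1", "d3"], 1)
})
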