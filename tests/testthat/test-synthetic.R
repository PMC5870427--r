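# a small config that keeps unit tests fast
small_config <- function(seed = 1, ...) {
  synthetic_config(
    n_genes = 600L, n_compounds = 16L,
    categories = data.frame(code = c("C10", "N02"),
                            n_members = c(5L, 5L),
                            alpha = c(0.8, 0)),
    planted_pathways = data.frame(pathway_id = "PW_PLANT",
                                  n_genes = 250L, effect = 2,
                                  affected = "C10"),
    n_decoys = 2L, seed = seed, ...)
}

test_that("identical configs give bit-identical bundles", {
  b1 <- generate_bundle(small_config(seed = 5))
  b2 <- generate_bundle(small_config(seed = 5))
  for (s in names(b1$matrices))
    expect_identical(b1$matrices[[s]]$values, b2$matrices[[s]]$values)
  expect_identical(b1$gene_sets$sets, b2$gene_sets$sets)
  expect_identical(unclass(b1$annotations), unclass(b2$annotations))

  b3 <- generate_bundle(small_config(seed = 6))
  expect_false(identical(b1$matrices[[1]]$values, b3$matrices[[1]]$values))
})

test_that("bundles share namespaces and carry usable ground truth", {
  b <- generate_bundle(small_config())
  g <- b$matrices[[1]]$gene_ids
  cpds <- b$matrices[[1]]$compound_ids
  for (m in b$matrices) {
    expect_identical(m$gene_ids, g)
    expect_identical(m$compound_ids, cpds)
    expect_true(all(is.finite(m$values)))
  }
  expect_true(all(unlist(b$gene_sets$sets) %in% g))
  expect_true(all(vapply(b$gene_sets$sets, length, 1L) > 200))
  expect_setequal(names(b$annotations), cpds)
  # 10 annotated members, the rest category-less
  expect_equal(sum(lengths(unclass(b$annotations)) > 0), 10)
  expect_equal(b$ground_truth$planted_pathways, "PW_PLANT")
})

test_that("perfectly correlated noiseless systems are identical", {
  rho <- matrix(1, 2, 2)
  cfg <- synthetic_config(n_genes = 400L, n_compounds = 10L,
                          systems = c("A", "B"), rho = rho,
                          categories = NULL, planted_pathways = NULL,
                          signal_sparsity = 0.5, noise_sd = 0, seed = 3)
  b <- generate_bundle(cfg)
  expect_equal(b$matrices$A$values, b$matrices$B$values, tolerance = 1e-12)

  sims <- lapply(names(b$matrices), function(s)
    pairwise_similarity(system_signatures(b$matrices[[s]], k = 20), s))
  res <- prank_score(sims[[1]], sims[[2]], quantile = 0.9)
  expect_equal(res$prank_score, 1.0)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(systems = c("A", "B"),
                                rho = matrix(c(1, .5, .4, 1), 2, 2)),
               "symmetric")
  expect_error(synthetic_config(systems = c("A", "B"),
                                rho = matrix(c(1, -.2, -.2, 1), 2, 2)),
               "\\[0, 1\\]")
  expect_error(synthetic_config(systems = c("A", "B"),
                                rho = matrix(c(2, .5, .5, 2), 2, 2)),
               "unit diagonal")
  bad <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  expect_error(synthetic_config(systems = c("A", "B", "C"), rho = bad),
               "semidefinite")
  expect_error(synthetic_config(n_compounds = 10L), "exceed n_compounds")
  expect_error(synthetic_config(n_genes = 100L), "larger than the gene universe")
})

test_that("expected_ordering sorts pairs by configured rho", {
  b <- generate_bundle(synthetic_config(n_genes = 500L, n_compounds = 6L,
                                        categories = NULL,
                                        planted_pathways = NULL, seed = 2))
  ord <- expected_ordering(b)
  expect_equal(ord$rho, c(0.9, 0.7, 0.55))
  expect_equal(ord$system_a[1], "InVivo_S")
  expect_equal(ord$system_b[1], "InVivo_R")
  expect_false(attr(ord, "partial"))

  rho_tied <- matrix(0.5, 3, 3); diag(rho_tied) <- 1
  b2 <- generate_bundle(synthetic_config(n_genes = 500L, n_compounds = 6L,
                                         systems = c("A", "B", "C"),
                                         rho = rho_tied, categories = NULL,
                                         planted_pathways = NULL, seed = 2))
  expect_true(attr(expected_ordering(b2), "partial"))
})

test_that("bundles written to disk re-read into the same objects", {
  b <- generate_bundle(small_config(seed = 9))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  m <- read_fold_change_matrix(file.path(dir, "fc_InVitro.tsv"), "InVitro")
  expect_identical(m$values, b$matrices$InVitro$values)
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_identical(ann$CPD001, b$annotations$CPD001)
  gsc <- read_gene_sets(file.path(dir, "gene_sets.gmt"), min_size = 200)
  expect_setequal(names(gsc$sets), names(b$gene_sets$sets))
  expect_setequal(gsc$sets$PW_PLANT, b$gene_sets$sets$PW_PLANT)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
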