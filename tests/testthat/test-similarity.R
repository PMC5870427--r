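test_that("dice matches the direction-aware overlap formula", {
  u <- paste0("g", 1:1000)
  a <- tgx_signature("a", up = u[1:200], down = u[201:400], mode = "topk", k = 200)
  expect_equal(dice(a, a), 1.0)

  b_disjoint <- tgx_signature("b", up = u[401:600], down = u[601:800],
                              mode = "topk", k = 200)
  expect_equal(dice(a, b_disjoint), 0.0)

  # 50 shared up, 30 shared down at k = 200 -> (50 + 30) / 400
  b <- tgx_signature("b", up = c(u[1:50], u[401:550]),
                     down = c(u[201:230], u[551:720]), mode = "topk", k = 200)
  expect_equal(dice(a, b), 0.2)

  # direction flip kills the similarity entirely
  flip <- tgx_signature("f", up = a$down, down = a$up, mode = "topk", k = 200)
  expect_equal(dice(a, flip), 0.0)

  small <- tgx_signature("s", up = u[1:5], down = u[6:10], mode = "topk", k = 5)
  expect_error(dice(a, small), "different k")
  thr <- tgx_signature("t", up = u[1:3], down = u[4:5], mode = "threshold")
  expect_error(dice(a, thr), "mix signature modes")
})

test_that("threshold-mode dice uses the generalized denominator", {
  a <- tgx_signature("a", up = c("g1", "g2"), down = "g3", mode = "threshold")
  b <- tgx_signature("b", up = "g1", down = c("g3", "g4", "g5"),
                     mode = "threshold")
  # overlap: 1 up + 1 down, sizes 3 + 4
  expect_equal(dice(a, b), 2 * 2 / 7)
  # fixed-denominator variant reproduces the 400+400 convention
  expect_equal(dice(a, b, denominator = "fixed", fixed_denom = 800), 4 / 800)
  # both empty: defined as 0
  e1 <- tgx_signature("e1", character(0), character(0), mode = "threshold")
  e2 <- tgx_signature("e2", character(0), character(0), mode = "threshold")
  expect_equal(dice(e1, e2), 0)
})

test_that("dice is symmetric for random signature pairs", {
  set.seed(21)
  u <- paste0("g", 1:300)
  for (i in 1:20) {
    a <- rand_signature("a", u, k = 30)
    b <- rand_signature("b", u, k = 30)
    expect_identical(dice(a, b), dice(b, a))
  }
  for (i in 1:20) {
    a <- rand_threshold_signature("a", u)
    b <- rand_threshold_signature("b", u)
    expect_identical(dice(a, b), dice(b, a))
  }
})

test_that("pairwise similarity agrees exactly with the brute-force oracle", {
  set.seed(31)
  u <- paste0("g", 1:500)
  sigs <- lapply(1:20, function(i) rand_signature(paste0("c", i), u, k = 25))
  sim <- pairwise_similarity(sigs, "sys")
  for (i in 1:19) for (j in (i + 1):20) {
    expect_identical(sim$values[i, j], dice_oracle(sigs[[i]], sigs[[j]]))
  }
  expect_identical(sim$values, t(sim$values))
  expect_equal(unname(diag(sim$values)), rep(1, 20))

  # threshold-mode matrices agree with the oracle too
  tsigs <- lapply(1:10, function(i) rand_threshold_signature(paste0("c", i), u))
  tsim <- pairwise_similarity(tsigs, "sys")
  for (i in 1:9) for (j in (i + 1):10) {
    expect_identical(tsim$values[i, j], dice_oracle(tsigs[[i]], tsigs[[j]]))
  }
})

test_that("pairwise similarity validates its inputs", {
  u <- paste0("g", 1:100)
  a <- rand_signature("a", u, 5)
  expect_error(pairwise_similarity(list(a), "sys"), "at least 2")
  expect_error(pairwise_similarity(list(a, a), "sys"), "duplicate compound")
})

test_that("mean similarity averages the strict upper triangle", {
  v <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  sm <- similarity_matrix(v, "sys")
  expect_equal(mean_similarity(sm), 0.2)

  # constant off-diagonal value c gives c
  vc <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(vc) <- 1
  expect_equal(mean_similarity(similarity_matrix(vc, "sys")), 0.4)

  # random matrix equals the direct enumeration oracle
  set.seed(41)
  n <- 8
  r <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  r[upper.tri(r)] <- runif(n * (n - 1) / 2)
  r <- r + t(r); diag(r) <- 1
  sm2 <- similarity_matrix(r, "sys")
  vals <- r[upper.tri(r)]
  expect_equal(mean_similarity(sm2), sum(vals) / length(vals))

  one <- similarity_matrix(matrix(1, 1, 1, dimnames = list("a", "a")), "sys")
  expect_error(mean_similarity(one), "at least one")
})

test_that("chemical-space correlation filters pairs and computes Pearson r", {
  ids <- letters[1:5]
  v <- matrix(0, 5, 5, dimnames = list(ids, ids))
  tgx_vals <- c(0.30, 0.10, 0.25, 0.15, 0.40, 0.05, 0.20, 0.35, 0.12, 0.28)
  v[upper.tri(v)] <- tgx_vals
  v <- v + t(v); diag(v) <- 1
  tgx <- similarity_matrix(v, "sys")
  pairs <- which(upper.tri(v), arr.ind = TRUE)

  # chem equal to tgx on every pair -> r = 1 (all pass cutoff 0)
  chem_eq <- chemical_similarity(ids[pairs[, 1]], ids[pairs[, 2]],
                                 v[upper.tri(v)])
  expect_equal(chem_tgx_correlation(tgx, chem_eq, chem_cutoff = 0)$r, 1.0)

  # chem = 1 - tgx -> r = -1
  chem_inv <- chemical_similarity(ids[pairs[, 1]], ids[pairs[, 2]],
                                  1 - v[upper.tri(v)])
  expect_equal(chem_tgx_correlation(tgx, chem_inv, chem_cutoff = 0)$r, -1.0)

  # strict cutoff keeps only chem > 0.2: of {0.1, 0.15, 0.3, 0.4, 0.5} keep 3
  chem5 <- chemical_similarity(c("a", "a", "a", "a", "b"),
                               c("b", "c", "d", "e", "c"),
                               c(0.1, 0.15, 0.3, 0.4, 0.5))
  res <- chem_tgx_correlation(tgx, chem5, chem_cutoff = 0.2)
  expect_equal(res$n_pairs, 3L)

  # fewer than 3 surviving pairs is an error
  chem2 <- chemical_similarity(c("a", "a"), c("b", "c"), c(0.5, 0.6))
  expect_error(chem_tgx_correlation(tgx, chem2), "need at least 3")
})
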