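# small helper: similarity matrix from an upper-triangle value vector
sim_from_values <- function(vals, system_id = "sys") {
  n <- (1 + sqrt(1 + 8 * length(vals))) / 2
  ids <- sprintf("c%02d", seq_len(n))
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  v[upper.tri(v)] <- vals
  v <- v + t(v); diag(v) <- 1
  similarity_matrix(v, system_id)
}

test_that("binarization is strict at the cutoff and supports quantile mode", {
  sm <- sim_from_values(c(0.41, 0.40, 0.39))
  labs <- binarize(sm, cutoff = 0.4)
  expect_equal(sum(labs), 1L)
  expect_equal(unname(labs[order(names(labs))]),
               as.integer(c(0.41, 0.40, 0.39) > 0.4)[order(names(labs))])

  expect_equal(sum(binarize(sim_from_values(rep(0, 6)))), 0L)

  sm2 <- sim_from_values(seq(0.01, 0.45, length.out = 45))
  q <- binarize(sm2, quantile = 0.95)
  expect_equal(attr(q, "cutoff"),
               unname(quantile(seq(0.01, 0.45, length.out = 45), 0.95)))
  expect_equal(sum(q), sum(seq(0.01, 0.45, length.out = 45) > attr(q, "cutoff")))
})

test_that("roc_auc reproduces closed-form cases", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0), c(0.2, 0.8)), 0.0)
  # 3 concordant of 4 positive-negative comparisons
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.3, 0.2, 0.25, 0.1)), 0.75)
  # all scores equal: every comparison is a tie
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)

  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "no negative")
  expect_error(roc_auc(c(0, 0), c(0.1, 0.2)), "no positive")
  expect_error(roc_auc(setNames(c(1, 0), c("a", "b")),
                       setNames(c(1, 0), c("a", "c"))), "same pairs")
})

test_that("roc_auc equals brute-force enumeration, including ties", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- integer(n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- 1L
    if (all(labels == labels[1])) labels[1] <- 1L - labels[1]
    # coarse grid of scores to force plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(labels, scores), auc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant under strictly increasing score transforms", {
  set.seed(52)
  labels <- rbinom(40, 1, 0.3)
  labels[1:2] <- c(0L, 1L)
  scores <- runif(40)
  base <- roc_auc(labels, scores)
  expect_equal(roc_auc(labels, exp(3 * scores)), base)
  expect_equal(roc_auc(labels, rank(scores)), base)
})

test_that("prank_score is 1 against itself and symmetric in its arguments", {
  set.seed(61)
  sm_a <- sim_from_values(round(runif(45, 0, 0.6), 2), "A")
  sm_b <- sim_from_values(round(runif(45, 0, 0.6), 2), "B")

  self <- prank_score(sm_a, sim_from_values(sm_a$values[upper.tri(sm_a$values)], "A2"),
                      cutoff = 0.4)
  expect_equal(self$prank_score, 1.0)
  expect_false(self$partial)

  ab <- prank_score(sm_a, sm_b, cutoff = 0.4)
  ba <- prank_score(sm_b, sm_a, cutoff = 0.4)
  expect_identical(ab$prank_score, ba$prank_score)
  expect_identical(ab$auc_a_labels, ba$auc_b_labels)
  expect_true(ab$prank_score >= 0 && ab$prank_score <= 1)
})

test_that("prank_score flags single-class directions as partial", {
  sm_a <- sim_from_values(c(0.9, 0.1, 0.1))          # one positive at 0.4
  sm_b <- sim_from_values(c(0.2, 0.1, 0.15))         # no positives
  res <- prank_score(sm_a, sm_b, cutoff = 0.4)
  expect_true(res$partial)
  expect_true(is.na(res$auc_b_labels))
  expect_equal(res$prank_score, res$auc_a_labels)
})

test_that("prank_score intersects compound sets and needs overlap", {
  sm_a <- sim_from_values(c(0.5, 0.1, 0.3))
  ids_b <- c("c01", "c02", "c03", "zz")
  v <- matrix(0.2, 4, 4, dimnames = list(ids_b, ids_b))
  v[1, 2] <- v[2, 1] <- 0.5
  diag(v) <- 1
  sm_b <- similarity_matrix(v, "B")
  expect_message(res <- prank_score(sm_a, sm_b), "intersecting to 3")
  expect_equal(res$n_pairs, 3L)

  ids_c <- c("x1", "x2")
  sm_c <- similarity_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                                   dimnames = list(ids_c, ids_c)), "C")
  expect_error(prank_score(sm_a, sm_c), "fewer than 2")
})

test_that("permuted scores give chance-level prank on average", {
  set.seed(71)
  vals <- runif(190, 0, 0.5)  # 20 compounds
  sm <- sim_from_values(vals, "A")
  labs <- binarize(sm, quantile = 0.9)
  keys <- names(labs)
  aucs <- replicate(300, {
    roc_auc(labs, setNames(sample(vals), keys))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("gene-set-restricted prank recovers constructed structure", {
  # pathway genes: compounds A and B share up-regulation, C is disjoint
  genes <- paste0("g", 1:12)
  vals <- cbind(A = c(2, 2, 2, rep(0, 9)),
                B = c(2, 2, 2, rep(0, 9)),
                C = c(0, 0, 0, -2, -2, -2, rep(0, 6)),
                D = c(rep(0, 6), 2, 2, 2, rep(0, 3)))
  m <- matrix(vals, nrow = 12, dimnames = list(genes, colnames(vals)))
  fc1 <- fold_change_matrix(m, "sys1")
  fc2 <- fold_change_matrix(m, "sys2")   # identical systems
  gsc <- gene_set_collection(list(pw_live = genes[1:9],
                                  pw_dead = genes[10:12]), min_size = 1)
  tbl <- prank_by_geneset(list(sys1 = fc1, sys2 = fc2), gsc)
  expect_equal(nrow(tbl), 2)
  live <- tbl[tbl$pathway_id == "pw_live", ]
  expect_equal(live$prank_score, 1.0)    # identical systems separate perfectly
  dead <- tbl[tbl$pathway_id == "pw_dead", ]
  expect_true(dead$partial)              # nothing passes the threshold

  ov <- top_pathway_overlap(tbl, l = 1)
  expect_equal(ov$common, "pw_live")
})

test_that("condition sweep emits one row per condition and system pair", {
  genes <- paste0("g", 1:10)
  set.seed(81)
  mk <- function(sys, cond) {
    m <- matrix(rnorm(40), 10, 4,
                dimnames = list(genes, paste0("c", 1:4)))
    fold_change_matrix(m, sys, condition = cond)
  }
  grids <- list(
    high_24h = list(A = mk("A", c("high", "24h")), B = mk("B", c("high", "24h")),
                    C = mk("C", c("high", "24h"))),
    low_24h = list(A = mk("A", c("low", "24h")), B = mk("B", c("low", "24h")),
                   C = mk("C", c("low", "24h")))
  )
  tbl <- condition_sweep(grids, cutoff = 0.2, k = 3)
  expect_equal(nrow(tbl), 6)   # 2 conditions x 3 pairs
  expect_setequal(unique(tbl$condition), c("high_24h", "low_24h"))

  # identical matrices at one condition give that condition score 1
  same <- mk("A", c("high", "24h"))
  same_b <- fold_change_matrix(same$values, "B", same$condition)
  tbl2 <- condition_sweep(list(only = list(A = same, B = same_b)),
                          cutoff = 0.2, k = 3)
  expect_equal(tbl2$prank_score, 1.0)
})
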