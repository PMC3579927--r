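# Enrichment curves, truncated AUC, ensemble aggregation, duplicate-state
# averaging, and rank consensus.

test_that("ensemble aggregation takes the per-ligand best score", {
  one <- matrix(c(-5, -6.5), ncol = 1, dimnames = list(c("L1", "L2"), "m"))
  expect_equal(aggregate_ensemble(one), c(L1 = -5, L2 = -6.5))

  two <- matrix(c(-5, -7.2), nrow = 1, dimnames = list("L1", c("a", "b")))
  expect_equal(aggregate_ensemble(two), c(L1 = -7.2))

  set.seed(30)
  m <- matrix(rnorm(350, -7, 2), 50, 7,
              dimnames = list(sprintf("L%02d", 1:50), sprintf("m%d", 1:7)))
  expect_equal(aggregate_ensemble(m), oracle_best_aggregate(m))
  expect_equal(aggregate_ensemble(m, models = c("m2", "m5")),
               oracle_best_aggregate(m[, c(2, 5)]))

  m[3, ] <- NA
  expect_error(aggregate_ensemble(m), "L03")
})

test_that("recovery curves have forced geometry at the extremes", {
  n <- 40; n_act <- 5
  labels <- c(rep(TRUE, n_act), rep(FALSE, n - n_act))
  first <- seq_len(n)          # actives ranked first
  cv <- recovery_curve(first, labels)
  expect_equal(cv$fraction_recovered[1 + n_act], 1)
  expect_equal(cv$fraction_screened[1], 0)
  expect_equal(cv$fraction_recovered[1], 0)
  expect_equal(cv$fraction_recovered[1 + n], 1)
  expect_false(is.unsorted(cv$fraction_recovered))

  last <- c(seq(100, length.out = n_act), seq_len(n - n_act))  # actives last
  cvl <- recovery_curve(last, labels)
  expect_true(all(cvl$fraction_recovered[cvl$fraction_screened <= (n - n_act) / n] == 0))
  expect_equal(auc_at_fraction(cvl, 0.1), 0)
})

test_that("recovery is invariant under strictly monotone score transforms", {
  set.seed(31)
  scores <- rnorm(60)
  labels <- seq_along(scores) %in% sample(60, 8)
  base <- recovery_curve(scores, labels)
  for (f in list(function(x) 3 * x + 2, function(x) exp(x), function(x) x^3))
    expect_equal(recovery_curve(f(scores), labels), base)
})

test_that("truncated AUC matches a fine-grid integration oracle", {
  # perfect ranking with the benchmark's shape: 11 actives in 231 ligands
  n <- 231; n_act <- 11
  labels <- c(rep(TRUE, n_act), rep(FALSE, n - n_act))
  cv <- recovery_curve(seq_len(n), labels)
  expect_equal(auc_at_fraction(cv, 0.1), oracle_auc_grid(cv, 0.1),
               tolerance = 1e-6)
  expect_equal(auc_at_fraction(cv, 0.1, normalize = "ideal"), 1)

  set.seed(32)
  for (i in 1:10) {
    sc <- rnorm(n)
    cvr <- recovery_curve(sc, labels)
    for (x in c(0.05, 0.1, 0.5, 1)) {
      expect_equal(auc_at_fraction(cvr, x), oracle_auc_grid(cvr, x),
                   tolerance = 1e-6)
      expect_gte(auc_at_fraction(cvr, x), 0)
      expect_lte(auc_at_fraction(cvr, x), x)
      expect_lte(auc_at_fraction(cvr, x, "ideal"), 1)
    }
    # monotone in x
    aucs <- vapply(c(0.05, 0.1, 0.5, 1), function(x) auc_at_fraction(cvr, x),
                   numeric(1))
    expect_false(is.unsorted(aucs))
  }
})

test_that("retrieved_at_fraction counts actives by average-tie rank", {
  n <- 231; n_act <- 7
  labels <- c(rep(TRUE, n_act), rep(FALSE, n - n_act))
  expect_equal(retrieved_at_fraction(seq_len(n), labels, 0.1), 7)
  expect_equal(retrieved_at_fraction(rev(seq_len(n)), labels, 0.1), 0)
  set.seed(33)
  for (i in 1:10) {
    sc <- sample(50, n, replace = TRUE)  # heavy ties
    r <- rank(sc, ties.method = "average")
    expect_equal(retrieved_at_fraction(sc, labels, 0.1),
                 sum(r[labels] <= ceiling(0.1 * n)))
  }
})

test_that("duplicate-state averaging collapses to one mean score per parent", {
  rows <- data.frame(parent_id = c("A", "A"), variant_id = c("a1", "a2"),
                     score = c(-8, -6))
  expect_equal(average_duplicate_scores(rows)$score, -7)

  solo <- data.frame(parent_id = c("B", "C"), variant_id = c("b", "c"),
                     score = c(-5, -4))
  expect_equal(average_duplicate_scores(solo)$score, c(-5, -4))

  v <- gen_variant_scores(n_parents = 115, n_rows = 500, seed = 9)
  out <- average_duplicate_scores(v)
  expect_equal(nrow(out), 115)
  expect_equal(sum(out$n_variants), 500)
  # spot-check the mean against a direct computation
  expect_equal(out$score[out$parent_id == "MB0001"],
               mean(v$score[v$parent_id == "MB0001"]))
})

test_that("mean-rank consensus reproduces identity, forced ties, and Borda oracle", {
  ids <- sprintf("L%02d", 1:9)
  r <- data.frame(ligand_id = ids, rank = sample(9))
  same <- consensus_rank(r, r)
  expect_identical(same$ligand_id, r$ligand_id[order(r$rank)])
  expect_equal(same$mean_rank, sort(r$rank))

  # exactly reversed rankings: every mean rank (n+1)/2, lexicographic output
  rev_r <- data.frame(ligand_id = ids, rank = 10 - r$rank)
  tied <- consensus_rank(r, rev_r)
  expect_true(all(tied$mean_rank == 5))
  expect_identical(tied$ligand_id, sort(ids))

  set.seed(34)
  for (i in 1:20) {
    pa <- sample(9); pb <- sample(9)
    a <- data.frame(ligand_id = ids, rank = pa)
    b <- data.frame(ligand_id = ids, rank = pb)
    expect_identical(consensus_rank(a, b)$ligand_id, oracle_borda(ids, pa, pb))
  }

  b_short <- data.frame(ligand_id = ids[-1], rank = 1:8)
  expect_error(consensus_rank(r, b_short), "L01")
})
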