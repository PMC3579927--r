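# Kabsch superposition, RMSD matrices, and gromos clustering.

test_that("Kabsch recovers rigid motions exactly and returns proper rotations", {
  set.seed(40)
  p <- matrix(rnorm(45, 0, 3), ncol = 3)
  fit0 <- kabsch_superpose(p, p)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  # 90 degrees about z plus a translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  q <- p %*% Rz + matrix(rep(c(4, -2, 7), each = nrow(p)), ncol = 3)
  fit <- kabsch_superpose(p, q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(p, fit), q, tolerance = 1e-9)

  expect_error(kabsch_superpose(p, p[1:10, ]), "differ in size")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
})

test_that("Kabsch RMSD matches a quaternion optimization oracle and lower-bounds plain RMSD", {
  set.seed(41)
  for (i in 1:5) {
    a <- matrix(rnorm(12, 0, 2), ncol = 3)  # 4-point toy sets
    b <- matrix(rnorm(12, 0, 2), ncol = 3)
    fit <- kabsch_superpose(a, b)
    expect_equal(fit$rmsd, oracle_min_rmsd(a, b), tolerance = 1e-6)
    expect_lte(fit$rmsd, rmsd_between(a, b) + 1e-12)
  }
})

test_that("rmsd_matrix is symmetric, zero-diagonal, and mask/superposition aware", {
  set.seed(42)
  base <- matrix(rnorm(60, 0, 3), ncol = 3)
  same <- conformer_ensemble(list(base, base, base))
  expect_equal(rmsd_matrix(same), matrix(0, 3, 3))

  R <- random_rotation()
  moved <- apply_rigid(base, R, c(3, -1, 2))
  pair <- conformer_ensemble(list(base, moved))
  expect_lt(rmsd_matrix(pair)[1, 2], 1e-9)
  expect_gt(rmsd_matrix(pair, superpose_first = FALSE)[1, 2], 1)

  ens <- gen_conformers(n_frames = 5, n_atoms = 15, seed = 2)
  m <- rmsd_matrix(ens)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  # direct pairwise recomputation after the same global superposition
  frames <- lapply(ens$frames, function(f)
    apply_superposition(f, kabsch_superpose(f, ens$frames[[1]])))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m[i, j], rmsd_between(frames[[i]], frames[[j]]))

  expect_error(rmsd_matrix(ens, mask = integer(0)), "0 atoms")
})

test_that("pocket_mask selects the shell around pocket atoms", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(11, 0, 0), c(0, 9, 0))
  expect_identical(pocket_mask(ref, pocket = 1L, distance = 10), c(1L, 2L, 4L))
  expect_identical(pocket_mask(ref, pocket = 1L, distance = 10,
                               elements = c("C", "H", "C", "N")), c(1L, 4L))
})

test_that("gromos clustering handles trivial cutoffs and matches the oracle", {
  set.seed(43)
  ens <- gen_conformers(n_frames = 12, n_atoms = 10, seed = 6)
  m <- rmsd_matrix(ens)
  all_in <- gromos_cluster(m, max(m) + 1)
  expect_equal(length(all_in$clusters), 1L)
  expect_identical(all_in$clusters[[1]]$members, 1:12)

  singletons <- gromos_cluster(m, min(m[m > 0]) / 2)
  expect_equal(length(singletons$clusters), 12L)

  for (trial in 1:20) {
    set.seed(500 + trial)
    n <- sample(6:12, 1)
    d <- matrix(runif(n * n, 0, 3), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    cutoff <- runif(1, 0.5, 2.5)
    res <- gromos_cluster(d, cutoff)
    oracle <- oracle_gromos(d, cutoff)
    expect_equal(length(res$clusters), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(res$clusters[[k]]$centroid, oracle[[k]]$centroid)
      expect_equal(res$clusters[[k]]$members, oracle[[k]]$members)
    }
    # partition property
    all_members <- unlist(lapply(res$clusters, `[[`, "members"))
    expect_identical(sort(all_members), seq_len(n))
  }

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(gromos_cluster(asym, 1), "symmetric")
})

test_that("planted three-blob ensembles are recovered exactly at an intermediate cutoff", {
  ens <- gen_conformers(n_frames = 30, n_atoms = 40, n_blobs = 3,
                        separation = 2, jitter_sd = 0.1, seed = 8)
  res <- gromos_cluster(rmsd_matrix(ens), cutoff = 0.75)
  expect_equal(length(res$clusters), 3L)
  blob <- attr(ens, "blob")
  for (cl in res$clusters)
    expect_equal(length(unique(blob[cl$members])), 1L)
  expect_identical(sort(unlist(lapply(res$clusters, `[[`, "members"))), 1:30)

  # zero jitter -> within-blob RMSD identically 0
  ens0 <- gen_conformers(n_frames = 9, n_atoms = 20, n_blobs = 3,
                         separation = 2, jitter_sd = 0, seed = 9)
  m0 <- rmsd_matrix(ens0)
  b0 <- attr(ens0, "blob")
  expect_true(all(m0[b0 == 1, b0 == 1] < 1e-9))
})

test_that("select_centroids takes the most populated clusters with deterministic ties", {
  m <- matrix(5, 7, 7); diag(m) <- 0
  m[1:3, 1:3] <- 0.1; m[4:5, 4:5] <- 0.1; m[6:7, 6:7] <- 0.1; diag(m) <- 0
  res <- gromos_cluster(m, 0.5)
  expect_equal(vapply(res$clusters, function(cl) length(cl$members), integer(1)),
               c(3L, 2L, 2L))
  # equal-size clusters -> earliest centroid first
  expect_equal(res$clusters[[2]]$centroid, 4)
  expect_warning(cent <- select_centroids(res, top_k = 5), "3 cluster")
  expect_identical(cent, c(1L, 4L, 6L))
  expect_identical(select_centroids(res, top_k = 2, extra_frames = 6L),
                   c(1L, 4L, 6L))
})
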