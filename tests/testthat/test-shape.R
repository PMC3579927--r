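# USR shape moments and the shape/color comboscore surrogate.

test_that("shape moments of degenerate and symmetric clouds", {
  expect_equal(as.numeric(shape_moments(matrix(c(1, 2, 3), 1))), rep(0, 12))

  # regular tetrahedron, edge 2*sqrt(2): all four reference points see the
  # distance multisets {sqrt(3) x4} (centroid) or {0, 2sqrt(2) x3} (vertex
  # references); moments below computed by hand from those sets
  tet <- tetrahedron_coords()
  m <- as.numeric(shape_moments(tet))
  expect_equal(m[1:3], c(sqrt(3), 0, 0))
  d <- c(0, rep(2 * sqrt(2), 3))
  mu <- mean(d)
  mu2 <- mean((d - mu)^2)
  mu3 <- mean((d - mu)^3)
  vertex_block <- c(mu, sqrt(mu2), sign(mu3) * abs(mu3)^(1 / 3))
  expect_equal(m[4:6], vertex_block)
  expect_equal(m[7:9], vertex_block)
  expect_equal(m[10:12], vertex_block)
})

test_that("shape moments are invariant to rigid motion", {
  set.seed(7)
  for (i in 1:10) {
    coords <- matrix(rnorm(36, 0, 4), ncol = 3)
    R <- random_rotation(); t <- rnorm(3, 0, 10)
    moved <- apply_rigid(coords, R, t)
    expect_equal(as.numeric(shape_moments(moved)),
                 as.numeric(shape_moments(coords)), tolerance = 1e-9)
  }
})

test_that("shape_sim follows the bounded inverse-L1 formula", {
  set.seed(8)
  a <- shape_moments(matrix(rnorm(30), ncol = 3))
  expect_identical(shape_sim(a, a), 1)
  b <- as.numeric(a); b[1] <- b[1] + 12  # total L1 of 12 -> 1/(1+1)
  expect_equal(shape_sim(a, b), 0.5)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(shape_sim(x, y), 1 / (1 + mean(abs(x - y))))
    expect_equal(shape_sim(x, y), shape_sim(y, x))
    expect_gt(shape_sim(x, y), 0)
    expect_lte(shape_sim(x, y), 1)
  }
})

test_that("color similarity averages per-feature-type shape similarities", {
  coords <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0, 1, 1, 1), ncol = 3, byrow = TRUE)
  a <- molecule_record("a", atoms = atom_table(rep("C", 4), coords[, 1],
                                               coords[, 2], coords[, 3],
                                               tags = c("donor", "donor", "acceptor", "")))
  # b shares only the donor type, with a different donor geometry
  bc <- coords + 0.5
  b <- molecule_record("b", atoms = atom_table(rep("C", 4), bc[, 1], bc[, 2], bc[, 3],
                                               tags = c("donor", "", "cation", "donor")))
  # hand evaluation of the stated rule: mean over {donor, acceptor, cation}
  # of (donor-cloud similarity, 0, 0)
  s_donor <- shape_sim(shape_moments(coords[c(1, 2), ]), shape_moments(bc[c(1, 4), ]))
  expect_equal(color_sim(a, b), mean(c(s_donor, 0, 0)))
  expect_equal(color_sim(a, b), color_sim(b, a))
  expect_equal(color_sim(a, a), 1)

  # disjoint feature types -> 0
  c1 <- molecule_record("c1", atoms = atom_table("C", 0, 0, 0, tags = "anion"))
  c2 <- molecule_record("c2", atoms = atom_table("C", 1, 0, 0, tags = "aromatic"))
  expect_equal(color_sim(c1, c2), 0)

  # untagged clouds are rejected with advice
  u <- molecule_record("u", atoms = atom_table(rep("C", 2), 0:1, 0, 0, tags = ""))
  expect_error(color_sim(u, a), "feature typing")
})

test_that("comboscore is bounded, symmetric, rigid-motion invariant, 2 for self", {
  set.seed(9)
  self <- random_tagged_molecule("x")
  expect_equal(comboscore(self, self)$total, 2)
  for (i in 1:15) {
    a <- random_tagged_molecule(sprintf("a%d", i))
    b <- random_tagged_molecule(sprintf("b%d", i))
    ab <- comboscore(a, b)
    expect_equal(ab$total, ab$shape + ab$color)
    expect_gte(ab$total, 0); expect_lte(ab$total, 2)
    ba <- comboscore(b, a)
    expect_equal(ab$total, ba$total)
    # rigid motion of one molecule leaves the score unchanged
    R <- random_rotation(); t <- rnorm(3, 0, 5)
    moved <- a
    xyz <- apply_rigid(as.matrix(a$atoms[, c("x", "y", "z")]), R, t)
    moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
    expect_equal(comboscore(moved, b)$total, ab$total, tolerance = 1e-9)
  }
})

test_that("cached provider agrees with direct comboscore and table provider round-trips", {
  set.seed(10)
  prov <- usr_combo_provider()
  mols <- lapply(sprintf("m%d", 1:6), random_tagged_molecule)
  rows <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    direct <- comboscore(mols[[i]], mols[[j]])$total
    expect_equal(prov(mols[[i]], mols[[j]]), direct, tolerance = 1e-12)
    rows[[length(rows) + 1]] <- data.frame(active_id = mols[[i]]$id,
                                           candidate_id = mols[[j]]$id,
                                           comboscore = direct)
  }
  tab <- combo_table_provider(do.call(rbind, rows))
  expect_equal(tab(mols[[1]], mols[[2]]), prov(mols[[1]], mols[[2]]))
  expect_error(tab(mols[[2]], mols[[1]]), "no comboscore")
})
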