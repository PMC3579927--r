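# Independent brute-force re-implementations used as oracles. These are
# written as literal step-by-step transcriptions of each procedure and stay
# independent of the package's code paths.

# Iterative decoy selection, spelled out step by step. Returns a named list
# (per active, in order) of candidate-id vectors.
oracle_select_decoys <- function(pool, quota, provider) {
  remaining <- pool_ids(pool, "candidate")
  picks <- list()
  for (aid in pool_ids(pool, "active")) {
    act <- pool$records[[aid]]
    dp <- vapply(remaining, function(cid)
      sum(abs(as.numeric(act$descriptors) -
              as.numeric(pool$records[[cid]]$descriptors))), numeric(1))
    combo <- vapply(remaining, function(cid)
      provider(act, pool$records[[cid]]), numeric(1))
    score <- dp + abs(combo - 2)
    ord <- remaining[order(score, remaining)]
    take <- ord[seq_len(min(quota, length(ord)))]
    picks[[aid]] <- take
    remaining <- remaining[!remaining %in% take]
  }
  picks
}

# gromos neighbor-counting iteration, literal transcription.
oracle_gromos <- function(m, cutoff) {
  left <- seq_len(nrow(m))
  clusters <- list()
  while (length(left)) {
    counts <- vapply(left, function(i)
      sum(m[i, setdiff(left, i)] <= cutoff), numeric(1))
    centroid <- left[which(counts == max(counts))[1]]
    members <- sort(c(centroid,
                      setdiff(left, centroid)[m[centroid, setdiff(left, centroid)] <= cutoff]))
    clusters[[length(clusters) + 1L]] <- list(centroid = centroid, members = members)
    left <- setdiff(left, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), numeric(1))
  cents <- vapply(clusters, function(cl) cl$centroid, numeric(1))
  clusters[order(-sizes, cents)]
}

# Elementwise row minimum over finite entries.
oracle_best_aggregate <- function(m) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) out[i] <- min(m[i, ][is.finite(m[i, ])])
  names(out) <- rownames(m)
  out
}

# Borda (mean-rank) consensus: average the two positions, order by the
# average then by id.
oracle_borda <- function(ids, pos_a, pos_b) {
  key <- (pos_a + pos_b) / 2
  ids[order(key, ids)]
}

# Fine-grid trapezoid integration of the piecewise-linear recovery curve.
oracle_auc_grid <- function(curve, x, n_grid = 2e5) {
  f <- stats::approxfun(curve$fraction_screened, curve$fraction_recovered,
                        rule = 2)
  g <- seq(0, x, length.out = n_grid)
  y <- f(g)
  sum(diff(g) * (head(y, -1) + tail(y, -1)) / 2)
}

# Minimum RMSD over rotations parameterized by quaternions, found
# numerically with multi-start BFGS.
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

oracle_min_rmsd <- function(P, Q, n_starts = 25) {
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    r <- stats::optim(stats::rnorm(4), obj, method = "BFGS",
                      control = list(maxit = 500))
    best <- min(best, r$value)
  }
  best
}

# Random rigid motion helpers for invariance checks.
random_rotation <- function() quat_to_rot(stats::rnorm(4))

apply_rigid <- function(coords, R, t) {
  sweep(as.matrix(coords) %*% t(R), 2L, -t)
}
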