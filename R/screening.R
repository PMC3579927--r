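# Enrichment evaluation of a docking screen: ensemble aggregation, active
# recovery curves, truncated (early-recognition) AUC, duplicate-state
# averaging, and two-program rank consensus.
#
# Docking scores follow the kcal/mol convention: lower (more negative) is
# better. Tied scores everywhere receive the average of the tied rank
# positions, so results do not depend on input file order.

#' Read a long-format docking score table
#'
#' CSV with columns `ligand_id,model_id,score` and optionally `label`
#' (1/TRUE for actives). Returns a ligand x model matrix with a logical
#' `labels` attribute when labels are present.
#'
#' @param path CSV path.
#' @return Numeric matrix (ligands x models), attribute `labels`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "model_id", "score")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ","))
  ligs <- unique(df$ligand_id); mods <- unique(df$model_id)
  m <- matrix(NA_real_, length(ligs), length(mods), dimnames = list(ligs, mods))
  m[cbind(match(df$ligand_id, ligs), match(df$model_id, mods))] <- df$score
  if (any(rowSums(is.finite(m)) == 0L))
    stop("every ligand needs at least one finite score")
  if ("label" %in% names(df)) {
    lab <- tapply(df$label, df$ligand_id, function(v) as.logical(v[1]))
    attr(m, "labels") <- as.logical(lab[ligs])
  }
  m
}

#' Aggregate an ensemble score table to one score per ligand
#'
#' Ensemble docking retains, for each ligand, its best (lowest) score over
#' the selected receptor models; a `mean` rule is provided as a configuration
#' hook.
#'
#' @param table Numeric ligand x model matrix (lower = better); `NA` marks a
#'   missing ligand/model combination.
#' @param models Model (column) names or indices to aggregate over; default
#'   all.
#' @param method `"best"` (minimum, the default) or `"mean"`.
#' @return Named numeric vector of per-ligand scores.
#' @examples
#' m <- matrix(c(-5, -7.2), 1, dimnames = list("L1", c("a", "b")))
#' aggregate_ensemble(m)  # -7.2
#' @export
aggregate_ensemble <- function(table, models = NULL, method = c("best", "mean")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (ncol(table) < 1L) stop("score table needs at least one model column")
  if (!is.null(models)) table <- table[, models, drop = FALSE]
  agg <- apply(table, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NA_real_)
    if (method == "best") min(v) else mean(v)
  })
  if (anyNA(agg))
    stop("ligand(s) with no finite score in the selected models: ",
         paste(names(agg)[is.na(agg)], collapse = ", "))
  agg
}

#' Active recovery curve of a ranked screen
#'
#' Ligands are ranked ascending by score (best first, average ranks for
#' ties); after each ranked ligand the fraction of actives recovered so far
#' is recorded, giving points (fraction screened, fraction of actives
#' recovered) from (0, 0) to (1, 1). The curve depends on the scores only
#' through their ranks, so it is invariant under strictly monotone score
#' transforms.
#'
#' @param scores Named or plain numeric vector of per-ligand scores.
#' @param labels Logical vector, `TRUE` for actives.
#' @return Data frame (`fraction_screened`, `fraction_recovered`) of class
#'   `recovery_curve`, with attributes `n_actives` and `n_total`.
#' @export
recovery_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  n_act <- sum(labels)
  if (n_act == 0L) stop("no actives in the screen")
  if (n_act == n) stop("no decoys in the screen")
  r <- rank(scores, ties.method = "average")
  act_ranks <- r[labels]
  rec <- vapply(seq_len(n), function(i) sum(act_ranks <= i) / n_act, numeric(1))
  out <- data.frame(fraction_screened = c(0, seq_len(n) / n),
                    fraction_recovered = c(0, rec))
  structure(out, n_actives = n_act, n_total = n,
            class = c("recovery_curve", "data.frame"))
}

.curve_area <- function(xs, ys, x) {
  keep <- xs <= x + 1e-12
  px <- xs[keep]; py <- ys[keep]
  if (px[length(px)] < x) {
    yx <- stats::approx(xs, ys, xout = x, rule = 2)$y
    px <- c(px, x); py <- c(py, yx)
  }
  sum(diff(px) * (utils::head(py, -1) + utils::tail(py, -1)) / 2)
}

#' Truncated area under a recovery curve
#'
#' Trapezoidal area of the piecewise-linear recovery curve over `[0, x]`
#' (e.g. x = 0.1 for the top 10% of the ranked database). With
#' `normalize = "none"` the raw area (at most `x`) is returned; with
#' `normalize = "ideal"` it is divided by the area an ideal ranking (all
#' actives first) achieves for the same number of actives, total ligands and
#' cutoff, giving a value in \[0, 1\].
#'
#' @param curve A [recovery_curve()].
#' @param x Fraction of the database screened, in (0, 1].
#' @param normalize `"none"` (default) or `"ideal"`.
#' @return A single number.
#' @export
auc_at_fraction <- function(curve, x, normalize = c("none", "ideal")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(curve, "recovery_curve"))
  stopifnot_scalar_number(x, "x")
  if (x <= 0 || x > 1) stop("'x' must be in (0, 1]")
  if (nrow(curve) == 0L) stop("empty curve")
  a <- .curve_area(curve$fraction_screened, curve$fraction_recovered, x)
  if (normalize == "none") return(a)
  n <- attr(curve, "n_total"); n_act <- attr(curve, "n_actives")
  ideal_rec <- pmin(seq_len(n), n_act) / n_act
  ideal <- .curve_area(c(0, seq_len(n) / n), c(0, ideal_rec), x)
  a / ideal
}

#' Number of actives retrieved in the top fraction of a ranking
#'
#' Counts actives whose (average-tie) rank is at most `ceiling(x * N)`.
#'
#' @inheritParams recovery_curve
#' @param x Fraction of the database screened, in (0, 1].
#' @return Integer count.
#' @export
retrieved_at_fraction <- function(scores, labels, x) {
  scores <- as.numeric(scores); labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  stopifnot_scalar_number(x, "x")
  r <- rank(scores, ties.method = "average")
  sum(r[labels] <= ceiling(x * length(scores)))
}

#' Average docking scores over duplicate ionization/tautomer states
#'
#' Ligand preparation can expand one parent compound into several ionization
#' states or tautomers that are docked independently; their scores are
#' collapsed to the arithmetic mean per parent.
#'
#' @param rows Data frame with columns `parent_id`, `variant_id`, `score`.
#' @return Data frame (`parent_id`, `score`, `n_variants`), one row per
#'   distinct parent, in order of first appearance.
#' @export
average_duplicate_scores <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("parent_id", "variant_id", "score") %in% names(rows)))
  if (nrow(rows) < 1L) stop("need at least one row")
  if (!all(is.finite(rows$score))) stop("scores must be finite")
  parents <- unique(rows$parent_id)
  idx <- match(rows$parent_id, parents)
  data.frame(parent_id = parents,
             score = as.numeric(tapply(rows$score, idx, mean)[as.character(seq_along(parents))]),
             n_variants = as.integer(table(idx)[as.character(seq_along(parents))]),
             stringsAsFactors = FALSE)
}

#' Ranking of ligands from a score vector
#'
#' @param scores Named numeric vector (lower = better).
#' @return Data frame (`ligand_id`, `rank`) with average ranks for ties.
#' @export
ranks_from_scores <- function(scores) {
  if (is.null(names(scores))) stop("'scores' must be named by ligand id")
  data.frame(ligand_id = names(scores),
             rank = rank(as.numeric(scores), ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Consensus of two ligand rankings
#'
#' Mean-rank (Borda) consensus of two rankings of the same ligand set, as
#' used to combine the hit lists of two docking programs: the consensus key
#' is the arithmetic mean of the two rank positions, with remaining ties
#' broken lexicographically by ligand id.
#'
#' @param rank_a,rank_b Data frames (`ligand_id`, `rank`) over the same
#'   ligand set, e.g. from [ranks_from_scores()].
#' @param method Only `"mean_rank"` currently.
#' @return Data frame (`ligand_id`, `mean_rank`, `rank`) sorted by consensus.
#' @export
consensus_rank <- function(rank_a, rank_b, method = c("mean_rank")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(rank_a), is.data.frame(rank_b),
            all(c("ligand_id", "rank") %in% names(rank_a)),
            all(c("ligand_id", "rank") %in% names(rank_b)))
  if (!setequal(rank_a$ligand_id, rank_b$ligand_id)) {
    only_a <- setdiff(rank_a$ligand_id, rank_b$ligand_id)
    only_b <- setdiff(rank_b$ligand_id, rank_a$ligand_id)
    stop("rankings cover different ligand sets; only in A: {",
         paste(only_a, collapse = ", "), "}; only in B: {",
         paste(only_b, collapse = ", "), "}")
  }
  b <- rank_b$rank[match(rank_a$ligand_id, rank_b$ligand_id)]
  mean_rank <- (rank_a$rank + b) / 2
  ord <- order(mean_rank, rank_a$ligand_id)
  data.frame(ligand_id = rank_a$ligand_id[ord],
             mean_rank = mean_rank[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
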