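# Alignment-free shape and pharmacophore ("color") similarity.
#
# The reference comboscore provider is USR-style: a conformer is summarized
# by 12 statistical moments of its atomic distance distributions from four
# reference points, and two conformers are compared through a bounded inverse
# L1 similarity. The "color" term repeats the construction per pharmacophore
# feature type. A comboscore (shape + color) lies in [0, 2], with 2 attained
# only by identically shaped, identically feature-typed clouds — the scalar
# contract any external overlay program can also fulfil through the provider
# interface.

#' USR shape moments of an atom cloud
#'
#' For each of four reference points — the centroid (ctd), the atom closest
#' to the centroid (cst), the atom farthest from the centroid (fct), and the
#' atom farthest from fct (ftf) — the distribution of distances to all atoms
#' is summarized by its mean, its standard deviation, and the signed cube
#' root of its third central moment (all in Angstrom). Population moments are
#' used, so a single atom yields the zero vector. The 12-vector is invariant
#' to rigid rotation and translation of the input.
#'
#' @param coords Numeric matrix (n x 3) of coordinates in Angstrom.
#' @return Named numeric vector of length 12 with class `shape_moments`.
#' @examples
#' shape_moments(matrix(rnorm(30), ncol = 3))
#' @export
shape_moments <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L || ncol(coords) != 3L)
    stop("'coords' must be an n x 3 matrix with n >= 1")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  ctd <- colMeans(coords)
  d_ctd <- .dists_to(coords, ctd)
  cst <- coords[which.min(d_ctd), ]
  fct <- coords[which.max(d_ctd), ]
  ftf <- coords[which.max(.dists_to(coords, fct)), ]
  refs <- list(ctd = ctd, cst = cst, fct = fct, ftf = ftf)
  out <- unlist(lapply(refs, function(p) .dist_moments(.dists_to(coords, p))))
  names(out) <- as.vector(outer(c("mean", "sd", "skew3"), names(refs),
                                function(m, r) paste(r, m, sep = ".")))
  structure(out, class = "shape_moments")
}

.dists_to <- function(coords, p) {
  sqrt(colSums((t(coords) - p)^2))
}

.dist_moments <- function(d) {
  m <- mean(d)
  mu2 <- mean((d - m)^2)
  mu3 <- mean((d - m)^3)
  c(m, sqrt(mu2), sign(mu3) * abs(mu3)^(1 / 3))
}

#' Similarity between two sets of shape moments
#'
#' `1 / (1 + L1/12)` where L1 is the sum of absolute differences of the 12
#' moments: symmetric, in (0, 1], and 1 iff the moment vectors are identical.
#'
#' @param a,b Length-12 moment vectors from [shape_moments()].
#' @return A number in (0, 1].
#' @export
shape_sim <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 12L || length(b) != 12L)
    stop("shape moment vectors must have length 12")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("moments must be finite")
  1 / (1 + mean(abs(a - b)))
}

.atoms_of_type <- function(mol, type) {
  tags <- atom_tags(mol$atoms)
  has <- vapply(tags, function(t) type %in% t, logical(1))
  which(has)
}

.require_tagged <- function(mol) {
  if (is.null(mol$atoms))
    stop("record ", mol$id, " has no 3D atoms")
  if (!any(nzchar(mol$atoms$tags)))
    stop("record ", mol$id, " has an untagged atom cloud; ",
         "run pharmacophore feature typing first")
  invisible(mol)
}

#' Pharmacophore ("color") similarity between two tagged atom clouds
#'
#' For every feature type present in either molecule, the USR shape
#' similarity of the two sub-clouds of that type is computed ([shape_sim()]
#' of per-type [shape_moments()]); a type present in only one molecule
#' contributes 0. The color similarity is the mean over the types present in
#' either molecule: symmetric, 1 for identical tagged clouds, 0 when no
#' feature type is shared.
#'
#' @param a,b [molecule_record()]s carrying feature-tagged 3D atoms.
#' @return A number in \[0, 1\].
#' @export
color_sim <- function(a, b) {
  .require_tagged(a); .require_tagged(b)
  coords_a <- as.matrix(a$atoms[, c("x", "y", "z")])
  coords_b <- as.matrix(b$atoms[, c("x", "y", "z")])
  sims <- numeric(0)
  for (type in FEATURE_TYPES) {
    ia <- .atoms_of_type(a, type); ib <- .atoms_of_type(b, type)
    if (length(ia) == 0L && length(ib) == 0L) next
    sims <- c(sims, if (length(ia) > 0L && length(ib) > 0L)
      shape_sim(shape_moments(coords_a[ia, , drop = FALSE]),
                shape_moments(coords_b[ib, , drop = FALSE])) else 0)
  }
  if (length(sims) == 0L)
    stop("neither molecule carries any pharmacophore feature tags")
  mean(sims)
}

#' Shape + color comboscore of two molecules
#'
#' Total similarity in \[0, 2\]: the USR shape similarity of the full atom
#' clouds plus the pharmacophore color similarity. A molecule compared with
#' itself scores exactly 2.
#'
#' @param a,b [molecule_record()]s with feature-tagged 3D atoms.
#' @return List with elements `shape`, `color`, `total`; class `comboscore`.
#' @export
comboscore <- function(a, b) {
  .require_tagged(a); .require_tagged(b)
  sh <- shape_sim(shape_moments(as.matrix(a$atoms[, c("x", "y", "z")])),
                  shape_moments(as.matrix(b$atoms[, c("x", "y", "z")])))
  co <- color_sim(a, b)
  structure(list(shape = sh, color = co, total = sh + co), class = "comboscore")
}

#' @export
print.comboscore <- function(x, ...) {
  cat(sprintf("<comboscore> total %.4f (shape %.4f + color %.4f)\n",
              x$total, x$shape, x$color))
  invisible(x)
}

# ---- combo providers --------------------------------------------------------
# A combo provider is a function(active, cand) -> number in [0, 2]; decoy
# selection consumes only this scalar, so an external overlay program can be
# substituted through `combo_table_provider` without touching the pipeline.

#' Reference USR comboscore provider
#'
#' Returns a provider function computing [comboscore()] totals, caching the
#' full and per-feature-type shape moments per molecule id so that scoring a
#' pool of candidates against many actives stays linear in pool size. The
#' reference provider works on the single conformer stored in each record.
#'
#' @return A function `(active, cand) -> total in [0, 2]` with class
#'   `combo_provider`.
#' @export
usr_combo_provider <- function() {
  cache <- new.env(parent = emptyenv())
  moments_of <- function(mol) {
    key <- mol$id
    if (!is.null(cache[[key]])) return(cache[[key]])
    .require_tagged(mol)
    coords <- as.matrix(mol$atoms[, c("x", "y", "z")])
    per_type <- lapply(stats::setNames(FEATURE_TYPES, FEATURE_TYPES), function(type) {
      idx <- .atoms_of_type(mol, type)
      if (length(idx)) shape_moments(coords[idx, , drop = FALSE]) else NULL
    })
    val <- list(full = shape_moments(coords), per_type = per_type)
    cache[[key]] <- val
    val
  }
  f <- function(active, cand) {
    ma <- moments_of(active); mb <- moments_of(cand)
    sh <- shape_sim(ma$full, mb$full)
    sims <- numeric(0)
    for (type in FEATURE_TYPES) {
      ta <- ma$per_type[[type]]; tb <- mb$per_type[[type]]
      if (is.null(ta) && is.null(tb)) next
      sims <- c(sims, if (!is.null(ta) && !is.null(tb)) shape_sim(ta, tb) else 0)
    }
    if (length(sims) == 0L)
      stop("neither molecule carries any pharmacophore feature tags")
    sh + mean(sims)
  }
  structure(f, class = c("combo_provider", "function"),
            info = list(provider = "usr_reference", conformers = "single"))
}

#' Comboscore provider backed by a precomputed pairwise table
#'
#' For scores produced by an external overlay program: a data frame with
#' columns `active_id`, `candidate_id`, `comboscore` (values in \[0, 2\]).
#'
#' @param table Data frame of precomputed pair scores.
#' @return A provider function `(active, cand) -> total`.
#' @export
combo_table_provider <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("active_id", "candidate_id", "comboscore") %in% names(table)))
  if (any(!is.finite(table$comboscore)) ||
      any(table$comboscore < 0 | table$comboscore > 2))
    stop("comboscore values must be finite and in [0, 2]")
  key <- paste(table$active_id, table$candidate_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (active_id, candidate_id) pairs")
  f <- function(active, cand) {
    i <- match(paste(active$id, cand$id, sep = "\r"), key)
    if (is.na(i)) stop("no comboscore for pair (", active$id, ", ", cand$id, ")")
    table$comboscore[i]
  }
  structure(f, class = c("combo_provider", "function"),
            info = list(provider = "table"))
}
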