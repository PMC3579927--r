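# Receptor conformer handling: Kabsch superposition, pairwise RMSD, and
# gromos clustering for picking representative receptor models from a
# trajectory.

#' Construct a conformer ensemble
#'
#' @param frames List of n x 3 coordinate matrices (Angstrom), all with the
#'   same atom count.
#' @param atom_names Optional character vector of atom names/ids (length n).
#' @param elements Optional element symbols (length n), used by
#'   [pocket_mask()]'s heavy-atom filter.
#' @return Object of class `conformer_ensemble` with fields `frames`,
#'   `atom_names`, `elements`.
#' @export
conformer_ensemble <- function(frames, atom_names = NULL, elements = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("each frame must be an n x 3 matrix")
    if (!all(is.finite(f))) stop("coordinates must be finite")
    f
  })
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("all frames must have the same atom count")
  if (!is.null(atom_names) && length(atom_names) != n)
    stop("'atom_names' length must match the atom count")
  if (!is.null(elements) && length(elements) != n)
    stop("'elements' length must match the atom count")
  structure(list(frames = frames, atom_names = atom_names, elements = elements),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frames x %d atoms\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' Read a conformer ensemble from disk
#'
#' `pdb` reads a multi-MODEL PDB through bio3d; `xyz` reads a whitespace
#' table with header columns `frame,name,x,y,z` (one row per atom per frame,
#' equal atom counts).
#'
#' @param path File path.
#' @param format `"pdb"` or `"xyz"`.
#' @return A [conformer_ensemble()].
#' @export
read_conformers <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading PDB requires the bio3d package")
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
    conformer_ensemble(frames, atom_names = pdb$atom$elety,
                       elements = pdb$atom$elesy)
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("frame", "name", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("xyz table must have columns: ", paste(need, collapse = ","))
    fr <- split(df, df$frame)
    frames <- lapply(fr, function(d) as.matrix(d[, c("x", "y", "z")]))
    conformer_ensemble(unname(frames), atom_names = fr[[1]]$name)
  }
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `mobile %*% R + t` onto `reference`, via SVD of the cross-covariance of
#' the centered point sets with a reflection correction so `det(R) = +1`.
#'
#' @param mobile,reference n x 3 coordinate matrices with the same n >= 3.
#' @return List of class `kabsch_fit`: `rotation` (3 x 3, applied on the
#'   right), `translation` (length 3), `rmsd` (Angstrom).
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(p, p)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  if (nrow(P) < 3L) stop("need at least 3 points")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("coordinates must be finite")
  cm <- colMeans(P); cr <- colMeans(Q)
  Pc <- sweep(P, 2L, cm); Qc <- sweep(Q, 2L, cr)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-9 * max(sv_p[1], 1))
    stop("degenerate (collinear) geometry: superposition rotation is not unique")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd),
            class = "kabsch_fit")
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param fit A `kabsch_fit` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(as.matrix(coords) %*% fit$rotation, 2L, -fit$translation)
}

#' Plain (un-fitted) RMSD between two coordinate sets
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("point sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Pairwise RMSD matrix of a conformer ensemble
#'
#' When `superpose_first` is set every frame is first rigidly superposed
#' onto frame 1 (using `superpose_mask` atoms, e.g. the backbone, or all
#' atoms), removing global rotation/translation; pairwise RMSDs are then
#' computed directly on the `mask` atoms (e.g. the binding-pocket shell)
#' without per-pair refitting, matching the trajectory-analysis convention.
#'
#' @param ens A [conformer_ensemble()].
#' @param mask Optional atom indices the RMSD is computed on (default all).
#' @param superpose_first Superpose all frames onto frame 1 first (default
#'   TRUE).
#' @param superpose_mask Optional atom indices used for the global
#'   superposition (default all atoms).
#' @return Symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
rmsd_matrix <- function(ens, mask = NULL, superpose_first = TRUE,
                        superpose_mask = NULL) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  frames <- ens$frames
  nf <- length(frames)
  if (nf < 2L) stop("need at least 2 frames")
  n_atoms <- nrow(frames[[1]])
  mask <- if (is.null(mask)) seq_len(n_atoms) else sort(unique(as.integer(mask)))
  if (length(mask) == 0L) stop("mask selects 0 atoms")
  if (any(mask < 1L | mask > n_atoms)) stop("mask indices out of range")
  if (superpose_first) {
    smask <- if (is.null(superpose_mask)) seq_len(n_atoms) else as.integer(superpose_mask)
    ref <- frames[[1]][smask, , drop = FALSE]
    frames <- lapply(frames, function(f) {
      fit <- kabsch_superpose(f[smask, , drop = FALSE], ref)
      apply_superposition(f, fit)
    })
  }
  sub <- lapply(frames, function(f) f[mask, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    m[i, j] <- m[j, i] <- rmsd_between(sub[[i]], sub[[j]])
  }
  m
}

#' Atom mask of a shell around a binding pocket
#'
#' Implements the "residues/atoms within a distance of the binding pocket"
#' recipe: returns the indices of atoms of a reference frame whose minimum
#' distance to any pocket atom is at most `distance`, optionally restricted
#' to heavy atoms.
#'
#' @param reference n x 3 coordinate matrix of the reference frame.
#' @param pocket Atom indices (into `reference`) or an m x 3 coordinate
#'   matrix defining the pocket.
#' @param distance Shell radius in Angstrom (default 10).
#' @param elements Optional element symbols for the heavy-atom filter.
#' @param heavy_only Drop hydrogens when `elements` are given (default TRUE).
#' @return Integer vector of atom indices.
#' @export
pocket_mask <- function(reference, pocket, distance = 10, elements = NULL,
                        heavy_only = TRUE) {
  reference <- as.matrix(reference)
  stopifnot_scalar_number(distance, "distance", positive = TRUE)
  pk <- if (is.matrix(pocket) || is.data.frame(pocket)) as.matrix(pocket)
        else reference[as.integer(pocket), , drop = FALSE]
  keep <- vapply(seq_len(nrow(reference)), function(i) {
    min(sqrt(colSums((t(pk) - reference[i, ])^2))) <= distance
  }, logical(1))
  idx <- which(keep)
  if (heavy_only && !is.null(elements))
    idx <- idx[toupper(elements[idx]) != "H"]
  idx
}

#' gromos clustering of an RMSD matrix
#'
#' The iterative neighbor-counting algorithm of the g_cluster "gromos"
#' method: among unassigned frames, each frame's neighbors are the other
#' unassigned frames within `cutoff`; the frame with the most neighbors
#' (lowest index on ties) becomes a centroid, it and its neighbors form a
#' cluster and are removed, and the step repeats until every frame is
#' assigned. The result is a partition of all frames.
#'
#' @param m Square symmetric RMSD matrix (Angstrom).
#' @param cutoff Neighbor cutoff in Angstrom (> 0); distances `<= cutoff`
#'   count as neighbors.
#' @return Object of class `gromos_clusters`: list with `clusters` (list of
#'   `list(centroid, members)`, ordered by decreasing size, ties by earliest
#'   centroid) and `cutoff`.
#' @export
gromos_cluster <- function(m, cutoff) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RMSD matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("RMSD matrix must be symmetric")
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  n <- nrow(m)
  unassigned <- seq_len(n)
  clusters <- list()
  while (length(unassigned) > 0L) {
    sub <- m[unassigned, unassigned, drop = FALSE]
    counts <- rowSums(sub <= cutoff) - 1L  # exclude self
    pick <- which.max(counts)              # lowest index on ties
    centroid <- unassigned[pick]
    members <- unassigned[sub[pick, ] <= cutoff]
    clusters[[length(clusters) + 1L]] <- list(centroid = centroid,
                                              members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  cents <- vapply(clusters, function(cl) cl$centroid, integer(1))
  ord <- order(-sizes, cents)
  structure(list(clusters = clusters[ord], cutoff = cutoff),
            class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  cat(sprintf("<gromos_clusters> %d clusters at cutoff %.3g A\n",
              length(x$clusters), x$cutoff))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d centroid %d, size %d\n", i, cl$centroid,
                length(cl$members)))
  }
  invisible(x)
}

#' Cluster report as a data frame
#' @param res A `gromos_clusters` object.
#' @return Data frame with columns cluster_rank, centroid_frame, size,
#'   member_frames (space-separated).
#' @export
cluster_report <- function(res) {
  stopifnot(inherits(res, "gromos_clusters"))
  data.frame(
    cluster_rank = seq_along(res$clusters),
    centroid_frame = vapply(res$clusters, function(cl) cl$centroid, integer(1)),
    size = vapply(res$clusters, function(cl) length(cl$members), integer(1)),
    member_frames = vapply(res$clusters, function(cl)
      paste(cl$members, collapse = " "), character(1)),
    stringsAsFactors = FALSE)
}

#' Centroid frames of the most populated clusters
#'
#' Returns the centroid frame indices of the `top_k` largest clusters
#' (clusters are already ordered by size, ties by earliest centroid). If the
#' clustering produced fewer clusters a warning is issued and all centroids
#' are returned. `extra_frames` appends explicitly chosen frames (e.g. a
#' conformation selected on solvent-exposure grounds) without duplication.
#'
#' @param res A `gromos_clusters` object.
#' @param top_k Number of clusters to take centroids from (default 5).
#' @param extra_frames Optional extra frame indices to append.
#' @return Integer vector of frame indices.
#' @export
select_centroids <- function(res, top_k = 5, extra_frames = NULL) {
  stopifnot(inherits(res, "gromos_clusters"))
  if (!is.numeric(top_k) || top_k < 1 || top_k != round(top_k))
    stop("'top_k' must be a positive integer")
  k <- length(res$clusters)
  if (k < top_k)
    warning(sprintf("only %d cluster(s) available; returning %d centroid(s)", k, k))
  cents <- vapply(res$clusters[seq_len(min(k, top_k))],
                  function(cl) cl$centroid, integer(1))
  unique(c(cents, as.integer(extra_frames)))
}
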