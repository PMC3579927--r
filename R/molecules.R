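# Molecule records, descriptor vectors, and pool I/O.
#
# A molecule carries an id, optionally a SMILES string, optionally a 3D atom
# cloud with pharmacophore feature tags, and a 7-descriptor physicochemical
# vector (the "PK properties" used for decoy matching).

#' Names of the seven physicochemical descriptors
#'
#' Hydrogen-bond acceptors and donors (counts), logS (log10 mol/L aqueous
#' solubility), SlogP (atom-contribution logP), molecular weight (Da),
#' rotatable bond count, and topological polar surface area (A^2).
#' @export
DESCRIPTOR_NAMES <- c("hba", "hbd", "logS", "slogp", "mw", "rotbonds", "tpsa")

#' Pharmacophore feature types recognized on atom clouds
#' @export
FEATURE_TYPES <- c("donor", "acceptor", "anion", "cation", "aromatic", "hydrophobe")

.integer_descriptors <- c("hba", "hbd", "rotbonds")

#' Construct a descriptor vector
#'
#' @param hba,hbd Hydrogen-bond acceptor / donor counts (non-negative integers).
#' @param logS log10 aqueous solubility (mol/L).
#' @param slogp Atom-contribution logP.
#' @param mw Molecular weight in Da (> 0).
#' @param rotbonds Rotatable bond count (non-negative integer).
#' @param tpsa Topological polar surface area in A^2 (>= 0).
#' @return A named numeric vector of length 7 with class `descriptor_vector`.
#' @examples
#' descriptor_vector(hba = 1, hbd = 1, logS = -0.1, slogp = -0.0014,
#'                   mw = 46.07, rotbonds = 0, tpsa = 20.23)
#' @export
descriptor_vector <- function(hba, hbd, logS, slogp, mw, rotbonds, tpsa) {
  x <- c(hba = hba, hbd = hbd, logS = logS, slogp = slogp, mw = mw,
         rotbonds = rotbonds, tpsa = tpsa)
  validate_descriptor_vector(x)
}

#' @rdname descriptor_vector
#' @param x A named numeric vector with the seven descriptor names.
#' @export
validate_descriptor_vector <- function(x) {
  x <- x[DESCRIPTOR_NAMES]
  if (anyNA(names(x)) || !identical(names(x), DESCRIPTOR_NAMES))
    stop("descriptor vector must carry names: ", paste(DESCRIPTOR_NAMES, collapse = ", "))
  if (!all(is.finite(x))) stop("descriptors must all be finite")
  ints <- x[.integer_descriptors]
  if (any(ints < 0) || any(abs(ints - round(ints)) > 1e-8))
    stop("hba, hbd and rotbonds must be non-negative integers")
  if (x[["mw"]] <= 0) stop("mw must be > 0")
  if (x[["tpsa"]] < 0) stop("tpsa must be >= 0")
  x[.integer_descriptors] <- round(ints)
  class(x) <- "descriptor_vector"
  x
}

#' Construct a molecule atom table
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param tags Character vector of `|`-separated pharmacophore feature tags
#'   per atom (subset of [FEATURE_TYPES]); `""` means untagged.
#' @return A `data.frame` with columns element, x, y, z, tags.
#' @export
atom_table <- function(element, x, y, z, tags = "") {
  n <- length(element)
  df <- data.frame(element = as.character(element),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   tags = rep_len(as.character(tags), n),
                   stringsAsFactors = FALSE)
  if (n < 1L) stop("atom table must contain at least one atom")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  bad <- setdiff(unlist(strsplit(df$tags[nzchar(df$tags)], "|", fixed = TRUE)),
                 FEATURE_TYPES)
  if (length(bad))
    stop("unknown feature tags: ", paste(unique(bad), collapse = ", "))
  df
}

#' Feature tags of each atom as a list of character vectors
#' @param atoms An atom table (see [atom_table()]).
#' @return List of character vectors, one per atom.
#' @export
atom_tags <- function(atoms) {
  lapply(atoms$tags, function(t) if (nzchar(t)) strsplit(t, "|", fixed = TRUE)[[1]] else character(0))
}

#' Construct a molecule record
#'
#' The unit of decoy selection: an id, an optional SMILES, an optional tagged
#' 3D atom cloud, and (optionally deferred) physicochemical descriptors.
#'
#' @param id Non-empty unique identifier.
#' @param smiles Optional SMILES string.
#' @param atoms Optional atom table (see [atom_table()]).
#' @param descriptors Optional [descriptor_vector()].
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(id, smiles = NULL, atoms = NULL, descriptors = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.null(atoms)) {
    stopifnot(is.data.frame(atoms))
    atoms <- atom_table(atoms$element, atoms$x, atoms$y, atoms$z,
                        atoms$tags %||% "")
  }
  if (!is.null(descriptors)) descriptors <- validate_descriptor_vector(descriptors)
  structure(list(id = id, smiles = smiles, atoms = atoms,
                 descriptors = descriptors),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record>", x$id,
      if (!is.null(x$smiles)) paste0(" smiles=", x$smiles) else "",
      if (!is.null(x$atoms)) sprintf(" (%d atoms)", nrow(x$atoms)) else " (no 3D)",
      "\n", sep = "")
  if (!is.null(x$descriptors)) print(unclass(x$descriptors))
  invisible(x)
}

#' Construct a molecule pool
#'
#' An ordered collection of molecule records, each tagged as `active` or
#' `candidate`. Actives are the known ligands a decoy set is matched to;
#' candidates are the library the decoys are drawn from.
#'
#' @param records List of [molecule_record()] objects.
#' @param roles Character vector (`"active"` / `"candidate"`), recycled.
#' @return An object of class `molecule_pool`.
#' @export
molecule_pool <- function(records, roles = "candidate") {
  stopifnot(is.list(records), length(records) >= 1L)
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate molecule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  roles <- rep_len(as.character(roles), length(records))
  if (!all(roles %in% c("active", "candidate")))
    stop("roles must be 'active' or 'candidate'")
  names(records) <- ids
  structure(list(records = records, roles = stats::setNames(roles, ids)),
            class = "molecule_pool")
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat(sprintf("<molecule_pool> %d records (%d active, %d candidate)\n",
              length(x$records), sum(x$roles == "active"),
              sum(x$roles == "candidate")))
  invisible(x)
}

#' Ids of the records in a pool
#' @param pool A [molecule_pool()].
#' @param role Optional filter, `"active"` or `"candidate"`.
#' @return Character vector of ids in pool order.
#' @export
pool_ids <- function(pool, role = NULL) {
  stopifnot(inherits(pool, "molecule_pool"))
  ids <- names(pool$records)
  if (is.null(role)) ids else ids[pool$roles == match.arg(role, c("active", "candidate"))]
}

#' Read a molecule pool from disk
#'
#' Three formats are supported. `descriptor_csv` is the self-contained
#' interchange format: header `id,hba,hbd,logS,slogp,mw,rotbonds,tpsa` with an
#' optional `role` column. `smiles_csv` has columns `id,smiles` (descriptors
#' are computed through `provider`). `sdf` reads a V2000 SD file through the
#' ChemmineR toolkit adapter; entries without 3D coordinates yield records with
#' `atoms = NULL`. Malformed entries are skipped with a warning that reports
#' the count.
#'
#' @param path File path.
#' @param format One of `"descriptor_csv"`, `"smiles_csv"`, `"sdf"`.
#' @param provider Descriptor provider (see [openbabel_descriptor_provider()]),
#'   required for `smiles_csv` and `sdf`.
#' @param roles Default role for records without an explicit role column.
#' @return A [molecule_pool()].
#' @export
read_pool <- function(path, format = c("descriptor_csv", "smiles_csv", "sdf"),
                      provider = NULL, roles = "candidate") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    descriptor_csv = .read_pool_descriptor_csv(path, roles),
    smiles_csv = .read_pool_smiles_csv(path, provider, roles),
    sdf = .read_pool_sdf(path, provider, roles))
}

.read_pool_descriptor_csv <- function(path, roles) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", DESCRIPTOR_NAMES)
  if (!all(need %in% names(df)))
    stop("descriptor_csv must have columns: ", paste(need, collapse = ","))
  if (anyDuplicated(df$id))
    stop("duplicate molecule ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  role_col <- if ("role" %in% names(df)) df$role else rep(roles, nrow(df))
  records <- vector("list", nrow(df)); keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      molecule_record(as.character(df$id[i]),
                      descriptors = descriptor_vector(
                        df$hba[i], df$hbd[i], df$logS[i], df$slogp[i],
                        df$mw[i], df$rotbonds[i], df$tpsa[i])),
      error = function(e) NULL)
    if (!is.null(rec)) { records[[i]] <- rec; keep[i] <- TRUE }
  }
  n_bad <- sum(!keep)
  if (n_bad > 0L) warning(sprintf("skipped %d malformed record(s) in %s", n_bad, path))
  if (!any(keep)) stop("no parseable records in ", path)
  molecule_pool(records[keep], role_col[keep])
}

.read_pool_smiles_csv <- function(path, provider, roles) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df)))
    stop("smiles_csv must have columns: id,smiles")
  if (anyDuplicated(df$id))
    stop("duplicate molecule ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (is.null(provider)) stop("smiles_csv requires a descriptor provider")
  records <- vector("list", nrow(df)); keep <- logical(nrow(df))
  role_col <- if ("role" %in% names(df)) df$role else rep(roles, nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      r <- molecule_record(as.character(df$id[i]), smiles = df$smiles[i])
      r$descriptors <- compute_descriptors(provider, r)
      r
    }, error = function(e) NULL)
    if (!is.null(rec)) { records[[i]] <- rec; keep[i] <- TRUE }
  }
  n_bad <- sum(!keep)
  if (n_bad > 0L) warning(sprintf("skipped %d malformed record(s) in %s", n_bad, path))
  if (!any(keep)) stop("no parseable records in ", path)
  molecule_pool(records[keep], role_col[keep])
}

.read_pool_sdf <- function(path, provider, roles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdf)
  n_bad <- sum(!ok)
  sdf <- sdf[ok]
  if (length(sdf) == 0L) stop("no parseable records in ", path)
  ids <- ChemmineR::sdfid(sdf)
  if (anyDuplicated(ids))
    stop("duplicate molecule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- vector("list", length(sdf))
  for (i in seq_along(sdf)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    elem <- gsub("_.*$", "", rownames(ab))
    atoms <- NULL
    # V2000 2D files carry all-zero z; treat those as "no 3D coordinates"
    if (any(abs(ab[, 3]) > 1e-6))
      atoms <- atom_table(elem, ab[, 1], ab[, 2], ab[, 3])
    smi <- tryCatch(as.character(ChemmineR::sdf2smiles(sdf[i])),
                    error = function(e) NULL)
    rec <- molecule_record(ids[i], smiles = smi, atoms = atoms)
    if (!is.null(provider)) rec$descriptors <- compute_descriptors(provider, rec)
    records[[i]] <- rec
  }
  if (n_bad > 0L) warning(sprintf("skipped %d malformed record(s) in %s", n_bad, path))
  molecule_pool(records, roles)
}

#' Write a molecule pool as a descriptor CSV
#'
#' Inverse of `read_pool(format = "descriptor_csv")`; atom clouds and SMILES
#' are not serialized by this format.
#'
#' @param pool A [molecule_pool()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "molecule_pool"))
  desc <- t(vapply(pool$records, function(r) {
    if (is.null(r$descriptors)) stop("record ", r$id, " has no descriptors")
    as.numeric(r$descriptors)
  }, numeric(7)))
  colnames(desc) <- DESCRIPTOR_NAMES
  df <- data.frame(id = names(pool$records), desc,
                   role = unname(pool$roles), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weighted L1 distance between two descriptor vectors
#'
#' The physicochemical half of the decoy score: the sum over the seven
#' descriptors of absolute differences, optionally dividing each term by a
#' positive per-descriptor scale to make the incommensurate units comparable.
#'
#' @param active,cand Descriptor vectors (named, 7 descriptors).
#' @param mode `"raw"` (plain absolute differences, the default) or
#'   `"scaled"`.
#' @param scales In scaled mode, 7 positive numbers (named or in
#'   [DESCRIPTOR_NAMES] order), e.g. from [pool_descriptor_scales()].
#' @return A single non-negative number; 0 iff the vectors are equal.
#' @examples
#' a <- descriptor_vector(2, 1, -3, 2.5, 300, 4, 80)
#' delta_pk(a, a)  # 0
#' @export
delta_pk <- function(active, cand, mode = c("raw", "scaled"), scales = NULL) {
  mode <- match.arg(mode)
  a <- validate_descriptor_vector(active)
  b <- validate_descriptor_vector(cand)
  d <- abs(unclass(a) - unclass(b))
  if (mode == "scaled") {
    if (is.null(scales)) stop("scaled mode requires 'scales'")
    if (!is.null(names(scales))) scales <- scales[DESCRIPTOR_NAMES]
    scales <- as.numeric(scales)
    if (length(scales) != 7L || !all(is.finite(scales)) || any(scales <= 0))
      stop("'scales' must be 7 positive finite numbers")
    d <- d / scales
  }
  sum(d)
}

#' Per-descriptor MAD scales for a pool
#'
#' Median absolute deviation of each descriptor across all pool records, for
#' use as `scales` in [delta_pk()]'s scaled mode. Descriptors with zero MAD
#' fall back to 1 so they contribute raw differences.
#'
#' @param pool A [molecule_pool()].
#' @return Named numeric vector of 7 positive scales.
#' @export
pool_descriptor_scales <- function(pool) {
  stopifnot(inherits(pool, "molecule_pool"))
  m <- t(vapply(pool$records, function(r) as.numeric(r$descriptors), numeric(7)))
  s <- apply(m, 2, stats::mad)
  s[!is.finite(s) | s <= 0] <- 1
  stats::setNames(s, DESCRIPTOR_NAMES)
}
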