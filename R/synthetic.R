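# Seeded synthetic-data generators.
#
# Every generator is a pure function of its spec and seed, producing inputs
# with the statistical structure the analysis stages assume: candidate pools
# with planted active mimics, active/decoy score matrices with plantable
# separation, and conformer ensembles with planted cluster structure.

#' Specification of a synthetic molecule pool
#'
#' Descriptor sampling windows default to drug-like ranges (mw 150-550 Da,
#' TPSA 20-140 A^2, counts 0-10, logS -6..0, SlogP -1..5). A
#' `mimic_fraction` of candidates are generated as perturbed copies of
#' actives (small descriptor differences, jittered atom cloud with the same
#' feature tags), so they carry low decoy scores against their source active
#' by construction.
#'
#' @param n_actives,n_candidates Record counts (>= 1).
#' @param seed RNG seed (required; the generator is deterministic per seed).
#' @param mimic_fraction Fraction of candidates that are active mimics
#'   (default 0.3).
#' @param n_atoms_range Atoms per molecule, inclusive integer range.
#' @param ranges Named list of per-descriptor c(min, max) sampling windows.
#' @param feature_probs Per-atom tagging probability for each feature type.
#' @param mimic_jitter List with `desc` (SD of continuous-descriptor
#'   perturbation, in MAD-like units), `count` (probability a count
#'   descriptor shifts by 1) and `coord` (atom-coordinate jitter SD, A).
#' @return Object of class `pool_spec`.
#' @export
pool_spec <- function(n_actives = 11, n_candidates = 500, seed,
                      mimic_fraction = 0.3, n_atoms_range = c(8, 30),
                      ranges = list(logS = c(-6, 0), slogp = c(-1, 5),
                                    mw = c(150, 550), tpsa = c(20, 140),
                                    counts = c(0, 10)),
                      feature_probs = c(donor = 0.15, acceptor = 0.2,
                                        anion = 0.05, cation = 0.05,
                                        aromatic = 0.3, hydrophobe = 0.4),
                      mimic_jitter = list(desc = 0.05, count = 0.1, coord = 0.1)) {
  stopifnot(n_actives >= 1, n_candidates >= 1,
            mimic_fraction >= 0, mimic_fraction <= 1,
            length(n_atoms_range) == 2L, n_atoms_range[1] >= 1,
            all(names(feature_probs) %in% FEATURE_TYPES),
            all(feature_probs >= 0 & feature_probs <= 1))
  if (missing(seed)) stop("'seed' is required")
  for (r in ranges) if (r[2] < r[1]) stop("invalid descriptor range")
  structure(list(n_actives = as.integer(n_actives),
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed), mimic_fraction = mimic_fraction,
                 n_atoms_range = as.integer(n_atoms_range), ranges = ranges,
                 feature_probs = feature_probs, mimic_jitter = mimic_jitter),
            class = "pool_spec")
}

.gen_descriptors <- function(rg) {
  descriptor_vector(
    hba = sample(rg$counts[1]:rg$counts[2], 1L),
    hbd = sample(rg$counts[1]:rg$counts[2], 1L),
    logS = stats::runif(1, rg$logS[1], rg$logS[2]),
    slogp = stats::runif(1, rg$slogp[1], rg$slogp[2]),
    mw = stats::runif(1, rg$mw[1], rg$mw[2]),
    rotbonds = sample(rg$counts[1]:rg$counts[2], 1L),
    tpsa = stats::runif(1, rg$tpsa[1], rg$tpsa[2]))
}

.gen_atoms <- function(n_atoms, feature_probs) {
  tags <- character(n_atoms)
  for (i in seq_len(n_atoms)) {
    t <- names(feature_probs)[stats::runif(length(feature_probs)) < feature_probs]
    tags[i] <- paste(t, collapse = "|")
  }
  if (!any(nzchar(tags)))  # guarantee a typed cloud
    tags[sample.int(n_atoms, 1L)] <- sample(names(feature_probs), 1L)
  atom_table(element = rep("C", n_atoms),
             x = stats::rnorm(n_atoms, 0, 3),
             y = stats::rnorm(n_atoms, 0, 3),
             z = stats::rnorm(n_atoms, 0, 3),
             tags = tags)
}

.perturb_descriptors <- function(d, rg, jit) {
  d <- unclass(d)
  for (k in c("logS", "slogp", "mw", "tpsa")) {
    width <- diff(range(rg[[k]]))
    d[[k]] <- d[[k]] + stats::rnorm(1, 0, jit$desc * width / 10)
  }
  for (k in c("hba", "hbd", "rotbonds")) {
    if (stats::runif(1) < jit$count)
      d[[k]] <- max(0, d[[k]] + sample(c(-1L, 1L), 1L))
  }
  d[["mw"]] <- max(d[["mw"]], 1)
  d[["tpsa"]] <- max(d[["tpsa"]], 0)
  validate_descriptor_vector(d)
}

#' Generate a synthetic molecule pool
#'
#' Actives and independent candidates draw descriptors uniformly from the
#' spec's drug-like windows and atom clouds from an isotropic Gaussian with
#' Bernoulli feature tags; mimic candidates copy a source active's
#' descriptors and atom cloud with small perturbations, so their decoy
#' scores against that active are low by construction. Candidate order is
#' shuffled (deterministically per seed) so mimics carry no positional
#' signal. The mimic-to-source mapping is recorded in attribute
#' `mimic_map`.
#'
#' @param spec A [pool_spec()].
#' @return A [molecule_pool()] with the spec in attribute `spec`.
#' @examples
#' pool <- gen_pool(pool_spec(n_actives = 2, n_candidates = 20, seed = 1))
#' @export
gen_pool <- function(spec) {
  stopifnot(inherits(spec, "pool_spec"))
  with_seed(spec$seed, {
    rg <- spec$ranges
    act_ids <- sprintf("ACT%02d", seq_len(spec$n_actives))
    actives <- lapply(act_ids, function(id)
      molecule_record(id,
                      atoms = .gen_atoms(sample(spec$n_atoms_range[1]:spec$n_atoms_range[2], 1L),
                                         spec$feature_probs),
                      descriptors = .gen_descriptors(rg)))
    names(actives) <- act_ids
    n_mimic <- round(spec$mimic_fraction * spec$n_candidates)
    cand_ids <- sprintf("CAND%04d", seq_len(spec$n_candidates))
    is_mimic <- c(rep(TRUE, n_mimic), rep(FALSE, spec$n_candidates - n_mimic))
    source_of <- rep(NA_character_, spec$n_candidates)
    source_of[is_mimic] <- rep_len(act_ids, n_mimic)
    shuffle <- sample.int(spec$n_candidates)
    is_mimic <- is_mimic[shuffle]; source_of <- source_of[shuffle]
    cands <- vector("list", spec$n_candidates)
    for (i in seq_len(spec$n_candidates)) {
      if (is_mimic[i]) {
        src <- actives[[source_of[i]]]
        atoms <- src$atoms
        n <- nrow(atoms)
        atoms$x <- atoms$x + stats::rnorm(n, 0, spec$mimic_jitter$coord)
        atoms$y <- atoms$y + stats::rnorm(n, 0, spec$mimic_jitter$coord)
        atoms$z <- atoms$z + stats::rnorm(n, 0, spec$mimic_jitter$coord)
        cands[[i]] <- molecule_record(cand_ids[i], atoms = atoms,
                                      descriptors = .perturb_descriptors(
                                        src$descriptors, rg, spec$mimic_jitter))
      } else {
        cands[[i]] <- molecule_record(
          cand_ids[i],
          atoms = .gen_atoms(sample(spec$n_atoms_range[1]:spec$n_atoms_range[2], 1L),
                             spec$feature_probs),
          descriptors = .gen_descriptors(rg))
      }
    }
    pool <- molecule_pool(c(actives, cands),
                          c(rep("active", spec$n_actives),
                            rep("candidate", spec$n_candidates)))
    attr(pool, "spec") <- spec
    attr(pool, "mimic_map") <- data.frame(candidate_id = cand_ids[is_mimic],
                                          source_active = source_of[is_mimic],
                                          stringsAsFactors = FALSE)
    pool
  })
}

#' Specification of a synthetic docking screen
#'
#' Each ligand draws a latent "true" score from its role's Normal
#' distribution (actives lower = better when `mu_active < mu_decoy`); each
#' receptor model observes the latent score plus independent Normal jitter.
#' Setting `mu_active = mu_decoy` gives a null screen with no enrichment.
#'
#' @param n_actives,n_decoys,n_models Dimensions of the screen (defaults:
#'   the 11 + 220 ligand validation set docked to 7 receptor models).
#' @param mu_active,mu_decoy Latent score means, kcal/mol-like.
#' @param sd_active,sd_decoy Latent score SDs (> 0).
#' @param model_jitter_sd Per-model observation noise SD (> 0).
#' @param seed RNG seed (required).
#' @return Object of class `screen_spec`.
#' @export
screen_spec <- function(n_actives = 11, n_decoys = 220, n_models = 7,
                        mu_active = -9, mu_decoy = -6.5,
                        sd_active = 1, sd_decoy = 1,
                        model_jitter_sd = 0.5, seed) {
  stopifnot(n_actives >= 1, n_decoys >= 1, n_models >= 1,
            sd_active > 0, sd_decoy > 0, model_jitter_sd > 0)
  if (missing(seed)) stop("'seed' is required")
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 n_models = as.integer(n_models),
                 mu_active = mu_active, mu_decoy = mu_decoy,
                 sd_active = sd_active, sd_decoy = sd_decoy,
                 model_jitter_sd = model_jitter_sd, seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a synthetic docking score table
#'
#' @param spec A [screen_spec()].
#' @return Ligand x model numeric matrix with attributes `labels` (logical,
#'   `TRUE` = active) and `spec`; ligands named `ACTxx`/`DECxxxx`, models
#'   `model1..k`.
#' @examples
#' tab <- gen_screen(screen_spec(seed = 1))
#' dim(tab)  # 231 x 7
#' @export
gen_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  with_seed(spec$seed, {
    n <- spec$n_actives + spec$n_decoys
    labels <- c(rep(TRUE, spec$n_actives), rep(FALSE, spec$n_decoys))
    ids <- c(sprintf("ACT%02d", seq_len(spec$n_actives)),
             sprintf("DEC%04d", seq_len(spec$n_decoys)))
    latent <- ifelse(labels,
                     stats::rnorm(n, spec$mu_active, spec$sd_active),
                     stats::rnorm(n, spec$mu_decoy, spec$sd_decoy))
    m <- latent + matrix(stats::rnorm(n * spec$n_models, 0, spec$model_jitter_sd),
                         n, spec$n_models)
    dimnames(m) <- list(ids, paste0("model", seq_len(spec$n_models)))
    attr(m, "labels") <- labels
    attr(m, "spec") <- spec
    m
  })
}

#' Generate ionization/tautomer variant scores for parent compounds
#'
#' Emulates a ligand-preparation expansion: `n_rows` docked states spread
#' over `n_parents` parent compounds (every parent receives at least one
#' state), each scoring its parent's latent score plus Normal jitter.
#'
#' @param n_parents Number of parent compounds.
#' @param n_rows Total variant rows (>= n_parents).
#' @param mu,sd Latent parent score distribution.
#' @param variant_jitter_sd Per-variant score jitter SD.
#' @param seed RNG seed.
#' @return Data frame (`parent_id`, `variant_id`, `score`).
#' @export
gen_variant_scores <- function(n_parents = 115, n_rows = 500, mu = -8, sd = 1,
                               variant_jitter_sd = 0.3, seed) {
  stopifnot(n_parents >= 1, n_rows >= n_parents)
  if (missing(seed)) stop("'seed' is required")
  with_seed(seed, {
    parent <- c(seq_len(n_parents),
                sample.int(n_parents, n_rows - n_parents, replace = TRUE))
    parent <- sort(parent)
    latent <- stats::rnorm(n_parents, mu, sd)
    variant_no <- stats::ave(parent, parent, FUN = seq_along)
    data.frame(parent_id = sprintf("MB%04d", parent),
               variant_id = sprintf("MB%04d_s%d", parent, variant_no),
               score = latent[parent] + stats::rnorm(n_rows, 0, variant_jitter_sd),
               stringsAsFactors = FALSE)
  })
}

#' Generate a conformer ensemble with planted cluster structure
#'
#' A base geometry is drawn once; each of `n_blobs` reference conformations
#' displaces every atom of the base independently (Normal, SD `separation`),
#' so the blobs differ in internal geometry, not merely by a rigid motion.
#' Frames cycle through the blobs and add Normal jitter of SD `jitter_sd` to
#' every coordinate. With `separation >> jitter_sd`, gromos clustering at an
#' intermediate cutoff recovers the blobs exactly. The true assignment is
#' kept in attribute `blob`.
#'
#' @param n_frames,n_atoms Ensemble dimensions.
#' @param n_blobs Number of planted conformational clusters.
#' @param separation Per-atom per-coordinate SD of blob displacements (A, > 0).
#' @param jitter_sd Within-blob coordinate jitter SD (A, >= 0).
#' @param seed RNG seed.
#' @return A [conformer_ensemble()] with attribute `blob` (integer vector of
#'   planted blob labels per frame).
#' @export
gen_conformers <- function(n_frames = 60, n_atoms = 40, n_blobs = 3,
                           separation = 2, jitter_sd = 0.1, seed) {
  stopifnot(n_frames >= 1, n_atoms >= 1, n_blobs >= 1,
            separation > 0, jitter_sd >= 0, n_frames >= n_blobs)
  if (missing(seed)) stop("'seed' is required")
  with_seed(seed, {
    base <- matrix(stats::rnorm(n_atoms * 3, 0, 5), n_atoms, 3)
    refs <- lapply(seq_len(n_blobs), function(b)
      base + matrix(stats::rnorm(n_atoms * 3, 0, separation), n_atoms, 3))
    blob <- rep_len(seq_len(n_blobs), n_frames)
    frames <- lapply(seq_len(n_frames), function(i)
      refs[[blob[i]]] + matrix(stats::rnorm(n_atoms * 3, 0, jitter_sd), n_atoms, 3))
    ens <- conformer_ensemble(frames,
                              atom_names = sprintf("A%03d", seq_len(n_atoms)))
    attr(ens, "blob") <- blob
    ens
  })
}
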