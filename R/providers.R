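# Pluggable descriptor providers.
#
# logS and SlogP are model-dependent quantities; the pipeline therefore never
# computes descriptors internally but obtains them through a provider object:
# either a toolkit-backed adapter or a lookup into a user-supplied table.
# Each provider records which models produced its values in `$info`, which is
# propagated into output metadata.

#' Compute the seven physicochemical descriptors for a molecule
#'
#' Dispatches to the provider's compute function and validates the result:
#' all seven descriptors present, finite, count descriptors integral.
#'
#' @param provider A descriptor provider, e.g.
#'   [openbabel_descriptor_provider()] or [table_descriptor_provider()].
#' @param mol A [molecule_record()].
#' @param ... Passed through to the provider (e.g. a pre-parsed SDF entry).
#' @return A [descriptor_vector()].
#' @export
compute_descriptors <- function(provider, mol, ...) {
  stopifnot(inherits(provider, "descriptor_provider"),
            inherits(mol, "molecule_record"))
  x <- provider$compute(mol, ...)
  if (!all(DESCRIPTOR_NAMES %in% names(x)))
    stop("provider '", provider$name, "' did not return all 7 descriptors (missing: ",
         paste(setdiff(DESCRIPTOR_NAMES, names(x)), collapse = ", "), ")")
  validate_descriptor_vector(x[DESCRIPTOR_NAMES])
}

new_descriptor_provider <- function(name, compute, info = list()) {
  structure(list(name = name, compute = compute, info = info),
            class = "descriptor_provider")
}

#' @export
print.descriptor_provider <- function(x, ...) {
  cat("<descriptor_provider>", x$name, "\n")
  if (length(x$info)) utils::str(x$info, give.attr = FALSE)
  invisible(x)
}

#' Descriptor provider backed by a precomputed table
#'
#' Looks descriptors up by molecule id in a data frame with columns
#' `id,hba,hbd,logS,slogp,mw,rotbonds,tpsa` (e.g. an export from MOE or any
#' other descriptor engine).
#'
#' @param table Data frame of precomputed descriptors.
#' @param source Free-text provenance note stored in `$info`.
#' @return A descriptor provider.
#' @export
table_descriptor_provider <- function(table, source = "precomputed table") {
  stopifnot(is.data.frame(table),
            all(c("id", DESCRIPTOR_NAMES) %in% names(table)))
  if (anyDuplicated(table$id)) stop("duplicate ids in descriptor table")
  idx <- stats::setNames(seq_len(nrow(table)), table$id)
  new_descriptor_provider(
    name = "table",
    compute = function(mol, ...) {
      i <- idx[[mol$id]]
      if (is.null(i)) stop("no descriptor row for id ", mol$id)
      unlist(table[i, DESCRIPTOR_NAMES])
    },
    info = list(source = source))
}

# Daylight-style rotatable bond SMARTS: acyclic single bond between two
# non-terminal atoms, excluding triple-bond-adjacent linkages.
.ROTBOND_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Toolkit descriptor provider (openbabel adapter)
#'
#' Computes the seven descriptors from a record's SMILES through the
#' openbabel toolkit (ChemmineOB): hydrogen-bond acceptors/donors, logP
#' (atom-contribution, reported as `slogp`), molecular weight, TPSA, and
#' rotatable bonds by SMARTS matching. Aqueous solubility `logS` is estimated
#' with the ESOL regression (Delaney 2004):
#' `logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`,
#' with AP the aromatic-heavy-atom proportion. The logS and logP model names
#' are recorded in `$info` so downstream outputs can state their provenance.
#'
#' @return A descriptor provider.
#' @export
openbabel_descriptor_provider <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("openbabel_descriptor_provider requires the ChemmineOB package")
  new_descriptor_provider(
    name = "openbabel",
    compute = function(mol, ...) {
      if (is.null(mol$smiles)) stop("record ", mol$id, " has no SMILES")
      obmol <- ChemmineOB::forEachMol("SMILES", mol$smiles, identity)
      props <- ChemmineOB::prop_OB(obmol)
      if (nrow(props) != 1L || !is.finite(props$MW))
        stop("unparseable structure for ", mol$id, ": ", mol$smiles)
      rb <- ChemmineOB::smartsSearch_OB(obmol, .ROTBOND_SMARTS, uniqueMatches = TRUE)
      n_arom <- ChemmineOB::smartsSearch_OB(obmol, "a", uniqueMatches = TRUE)
      n_heavy <- ChemmineOB::smartsSearch_OB(obmol, "[!#1]", uniqueMatches = TRUE)
      ap <- if (n_heavy > 0) n_arom / n_heavy else 0
      logS <- 0.16 - 0.63 * props$logP - 0.0062 * props$MW + 0.066 * rb - 0.74 * ap
      c(hba = props$HBA1, hbd = props$HBD, logS = logS, slogp = props$logP,
        mw = props$MW, rotbonds = rb, tpsa = props$TPSA)
    },
    info = list(toolkit = "openbabel (ChemmineOB)",
                logS_model = "ESOL (Delaney 2004)",
                logP_model = "openbabel atom-contribution logP",
                hba_model = "openbabel HBA1 SMARTS"))
}
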