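# Summary arithmetic over a Ramachandran (PROCHECK-style) region
# distribution of a structural model.

#' Summarize a Ramachandran region distribution
#'
#' Given the percentages of analyzed residues falling in the most favored,
#' additional allowed, generously allowed and disallowed regions of the
#' Ramachandran plot (as printed by PROCHECK for non-glycine, non-proline
#' residues), computes the cumulative non-disallowed percentage and converts
#' region percentages into residue counts, both rounded to the nearest
#' integer as such reports conventionally print them.
#'
#' @param favored,additional,generous,disallowed Region percentages (0-100);
#'   they must sum to 100 within `tol`.
#' @param n_residues Number of residues analyzed.
#' @param tol Allowed deviation of the percentage sum from 100 (default 0.5,
#'   absorbing per-region rounding in printed reports).
#' @return List of class `ramachandran_summary`: `allowed_percent` (rounded
#'   cumulative favored + additional + generous), `allowed_percent_exact`,
#'   `disallowed_residues` (rounded count), `region_residues` (rounded count
#'   per region), `n_residues`.
#' @examples
#' ramachandran_summary(83.7, 13.9, 1.5, 1.0, n_residues = 411)
#' @export
ramachandran_summary <- function(favored, additional, generous, disallowed,
                                 n_residues, tol = 0.5) {
  pct <- c(favored = favored, additional = additional,
           generous = generous, disallowed = disallowed)
  if (!all(is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("region percentages must lie in [0, 100]")
  if (abs(sum(pct) - 100) > tol)
    stop(sprintf("region percentages sum to %.2f, not 100", sum(pct)))
  stopifnot_scalar_number(n_residues, "n_residues", positive = TRUE)
  allowed <- favored + additional + generous
  structure(list(
    allowed_percent = round(allowed),
    allowed_percent_exact = allowed,
    disallowed_residues = round(disallowed / 100 * n_residues),
    region_residues = round(pct / 100 * n_residues),
    n_residues = n_residues), class = "ramachandran_summary")
}

#' @export
print.ramachandran_summary <- function(x, ...) {
  cat(sprintf("Ramachandran summary over %d residues\n", as.integer(x$n_residues)))
  cat(sprintf("  non-disallowed: %.1f%% (prints as %d%%)\n",
              x$allowed_percent_exact, x$allowed_percent))
  cat(sprintf("  disallowed residues: %d\n", as.integer(x$disallowed_residues)))
  invisible(x)
}
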