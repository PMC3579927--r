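# Property-matched decoy selection.
#
# Each candidate is scored against an active with
#   decoy score = delta-PK + |comboscore - 2|,
# so that 0 means a perfect physicochemical and shape/pharmacophore mimic.
# Candidates are ranked ascending per active; the top `quota` are taken and
# removed from the pool before the next active is processed, which guarantees
# disjoint decoy sets by construction.

#' Decoy score of a candidate against an active
#'
#' Sum of the descriptor-difference term ([delta_pk()]) and the comboscore
#' complement `2 - comboscore`; smaller is a better mimic, and a candidate
#' identical to the active scores 0.
#'
#' @param active,cand [molecule_record()]s with descriptors.
#' @param combo_provider Provider function `(active, cand) -> [0, 2]`,
#'   e.g. [usr_combo_provider()].
#' @param delta_mode,scales Passed to [delta_pk()].
#' @return One-row data frame: active_id, candidate_id, delta_pk, combo, score.
#' @export
decoy_score <- function(active, cand, combo_provider = usr_combo_provider(),
                        delta_mode = c("raw", "scaled"), scales = NULL) {
  delta_mode <- match.arg(delta_mode)
  combo <- combo_provider(active, cand)
  if (!is.numeric(combo) || length(combo) != 1L || !is.finite(combo) ||
      combo < 0 || combo > 2)
    stop("combo provider returned a value outside [0, 2] for pair (",
         active$id, ", ", cand$id, ")")
  dp <- delta_pk(active$descriptors, cand$descriptors, delta_mode, scales)
  data.frame(active_id = active$id, candidate_id = cand$id,
             delta_pk = dp, combo = combo, score = dp + (2 - combo),
             stringsAsFactors = FALSE)
}

#' Iterative per-active decoy selection
#'
#' For each active, in pool order (or the order given), every remaining
#' candidate is scored with [decoy_score()], candidates are ranked ascending
#' by score (ties broken by lexicographic candidate id), the top `quota` are
#' assigned to that active and removed from the candidate pool, and the
#' procedure repeats for the next active. Decoy sets across actives are
#' therefore pairwise disjoint. Note the selection is order-sensitive:
#' permuting the actives may change the assignment, which is why the
#' processing order is recorded in the result.
#'
#' @param pool A [molecule_pool()] with at least one active; candidates are
#'   all records tagged `"candidate"`.
#' @param quota Decoys to select per active (default 20).
#' @param combo_provider Comboscore provider, default [usr_combo_provider()].
#' @param delta_mode,scales Passed to [delta_pk()].
#' @param exhaustion_policy `"error"` stops if a processed active finds fewer
#'   than `quota` remaining candidates; `"partial"` assigns what is left with
#'   a warning.
#' @param active_order Optional permutation of the active ids.
#' @return A `decoy_assignment`: data frame with columns active_id, rank,
#'   candidate_id, delta_pk, combo, score; attributes `quota`, `delta_mode`,
#'   `active_order`, `combo_info`.
#' @examples
#' pool <- gen_pool(pool_spec(n_actives = 2, n_candidates = 12, seed = 1))
#' head(select_decoys(pool, quota = 3))
#' @export
select_decoys <- function(pool, quota = 20,
                          combo_provider = usr_combo_provider(),
                          delta_mode = c("raw", "scaled"), scales = NULL,
                          exhaustion_policy = c("error", "partial"),
                          active_order = NULL) {
  stopifnot(inherits(pool, "molecule_pool"))
  delta_mode <- match.arg(delta_mode)
  exhaustion_policy <- match.arg(exhaustion_policy)
  if (!is.numeric(quota) || length(quota) != 1L || quota < 1 ||
      quota != round(quota))
    stop("'quota' must be a positive integer")
  actives <- pool_ids(pool, "active")
  if (length(actives) == 0L) stop("pool contains no actives")
  if (!is.null(active_order)) {
    if (!setequal(active_order, actives))
      stop("'active_order' must be a permutation of the active ids")
    actives <- as.character(active_order)
  }
  if (delta_mode == "scaled" && is.null(scales))
    scales <- pool_descriptor_scales(pool)
  remaining <- pool_ids(pool, "candidate")
  rows <- vector("list", length(actives))
  for (k in seq_along(actives)) {
    act <- pool$records[[actives[k]]]
    if (length(remaining) < quota) {
      msg <- sprintf("candidate pool exhausted at active '%s': %d remaining, quota %d",
                     actives[k], length(remaining), quota)
      if (exhaustion_policy == "error") stop(msg)
      warning(msg)
    }
    if (length(remaining) == 0L) next
    scored <- do.call(rbind, lapply(remaining, function(cid)
      decoy_score(act, pool$records[[cid]], combo_provider, delta_mode, scales)))
    ord <- order(scored$score, scored$candidate_id)
    take <- utils::head(ord, quota)
    sel <- scored[take, , drop = FALSE]
    sel$rank <- seq_len(nrow(sel))
    rows[[k]] <- sel
    remaining <- setdiff(remaining, sel$candidate_id)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("active_id", "rank", "candidate_id", "delta_pk", "combo", "score")]
  structure(out,
            quota = quota, delta_mode = delta_mode, active_order = actives,
            combo_info = attr(combo_provider, "info"),
            class = c("decoy_assignment", "data.frame"))
}

#' Write a decoy assignment to CSV
#' @param assignment A `decoy_assignment` from [select_decoys()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "decoy_assignment"))
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
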