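# Transfer / fission-fusion impact: pre-post matrix correlation on shared
# members, per-individual centrality deltas, stability statistics.

#' Quantify one composition change
#'
#' For two adjacent compositions of the same group, restricts both
#' association matrices to the shared individuals, correlates them with a
#' Mantel test (the "stability" of dyadic relationships across the
#' change), counts the individuals transferred (added plus removed; an
#' enclosure-only change counts 0), and computes per-individual metric
#' deltas (after minus before) for the shared members.
#'
#' @param comp_before,comp_after one-row composition slices (or lists);
#'   `comp_after` must start no earlier than `comp_before` ends and both
#'   must belong to the same group.
#' @param assoc_before,assoc_after the compositions'
#'   [association_matrix()] objects.
#' @param metrics_before,metrics_after rows of the metric table for the
#'   two compositions (need `individual_id`, the delta columns, a
#'   `dominance` rank and `familiarity`).
#' @param sided sidedness of the stability Mantel test (required; the
#'   field convention is `"one_pos"`: stability means positive
#'   correlation).
#' @param n_perm,seed passed to [mantel_test()].
#' @param delta_cols metric columns to difference; default the corrected
#'   centralities.
#' @return A `transfer_record`: ids of the two compositions,
#'   `shared_members`, `n_transferred`, `enclosure_only`, `mantel`
#'   (a `mantel_result`), and `deltas` (individual_id, one `d_<col>` per
#'   metric, `d_rank`, `familiarity_new`).  An individual missing a rank
#'   in either composition gets `NA` for `d_rank`, never an imputed value.
#' @export
build_transfer_record <- function(comp_before, comp_after,
                                  assoc_before, assoc_after,
                                  metrics_before, metrics_after,
                                  sided, n_perm = 1000, seed = NULL,
                                  delta_cols = c("eigenvector_corrected",
                                                 "strength_corrected")) {
  cb <- .as_composition(comp_before)
  ca <- .as_composition(comp_after)
  if (!identical(cb$group, ca$group))
    .stop("compositions %s and %s belong to different groups",
          cb$composition_id, ca$composition_id)
  if (as.Date(ca$start_date) < as.Date(cb$end_date))
    .stop("compositions %s and %s are not adjacent in time",
          cb$composition_id, ca$composition_id)
  removed <- setdiff(cb$members, ca$members)
  added <- setdiff(ca$members, cb$members)
  n_transferred <- length(removed) + length(added)
  enclosure_only <- isTRUE(ca$enclosure_change_only)
  if (enclosure_only && n_transferred != 0L)
    .stop("enclosure-only change %s -> %s must keep the same members",
          cb$composition_id, ca$composition_id)

  restr <- restrict_to_shared(assoc_before, assoc_after)
  mantel <- mantel_test(restr$before$counts, restr$after$counts,
                        sided = sided, n_perm = n_perm, seed = seed)

  shared <- restr$shared
  mb <- metrics_before[match(shared, metrics_before$individual_id), ,
                       drop = FALSE]
  ma <- metrics_after[match(shared, metrics_after$individual_id), ,
                      drop = FALSE]
  if (anyNA(mb$individual_id) || anyNA(ma$individual_id))
    .stop("metric table lacks rows for some shared individuals")
  deltas <- data.frame(individual_id = shared, stringsAsFactors = FALSE)
  for (col in delta_cols)
    deltas[[paste0("d_", sub("_corrected$", "", col))]] <-
      ma[[col]] - mb[[col]]
  deltas$d_rank <- ma$dominance - mb$dominance
  deltas$familiarity_new <- ma$familiarity
  structure(list(before = cb$composition_id, after = ca$composition_id,
                 group = cb$group, shared_members = shared,
                 n_transferred = n_transferred,
                 added = added, removed = removed,
                 enclosure_only = enclosure_only,
                 mantel = mantel, deltas = deltas,
                 delta_cols = delta_cols),
            class = "transfer_record")
}

#' Does network stability depend on how many individuals moved?
#'
#' Correlates the pre/post Mantel correlation coefficients of a set of
#' transfer records with the number of individuals transferred, using a
#' Spearman correlation test with permutations.
#'
#' @param records list of `transfer_record` objects (at least 3).
#' @param sided sidedness of the permutation test (required).
#' @param n_perm,seed passed to [perm_correlation()].
#' @return The [perm_correlation()] result (`estimate`, `p`, ...).
#' @export
stability_vs_transfers <- function(records, sided, n_perm = 1000,
                                   seed = NULL) {
  if (length(records) < 3L) .stop("need at least 3 transfer records")
  r <- vapply(records, function(x) x$mantel$r, numeric(1))
  n_tr <- vapply(records, function(x) as.numeric(x$n_transferred),
                 numeric(1))
  if (sd(n_tr) == 0)
    .stop("number transferred is constant across records")
  perm_correlation(n_tr, r, sided = sided, n_perm = n_perm,
                   method = "spearman", seed = seed)
}

#' Mean and range of pre/post network stability
#'
#' @param records list of `transfer_record` objects (at least 1).
#' @return List with `mean`, `min`, `max` of the Mantel correlation
#'   coefficients and `n` records.
#' @export
mean_stability <- function(records) {
  if (!length(records)) .stop("no transfer records")
  r <- vapply(records, function(x) x$mantel$r, numeric(1))
  list(mean = mean(r), min = min(r), max = max(r), n = length(r))
}

#' @export
print.transfer_record <- function(x, ...) {
  cat(sprintf("transfer_record %s -> %s: %d shared, %d transferred%s, Mantel r = %.3f (p = %.3g)\n",
              x$before, x$after, length(x$shared_members), x$n_transferred,
              if (x$enclosure_only) " (enclosure change only)" else "",
              x$mantel$r, x$mantel$p))
  invisible(x)
}
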