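# Modified David's Score dominance ranking from win/loss matrices.

#' Directed win-count matrix from agonistic events
#'
#' `wins[i, j]` is the number of agonistic interactions (supplant,
#' avoidance or aggression, all weighted equally) that individual `i` won
#' against `j`.
#'
#' @param events agonistic event table (`composition_id`, `winner_id`,
#'   `loser_id`, ...).
#' @param composition composition id or slice; only its events are used.
#' @param herd optional `herd_data` for id lookup.
#' @return An `agonistic_matrix` object (list with `wins` and `members`).
#' @export
agonistic_matrix <- function(events, composition, herd = NULL) {
  comp <- .as_composition(composition, herd)
  members <- comp$members
  e <- events[events$composition_id == comp$composition_id, , drop = FALSE]
  unknown <- setdiff(unique(c(e$winner_id, e$loser_id)), members)
  if (length(unknown))
    .stop("agonistic log references non-members of %s: %s",
          comp$composition_id, paste(unknown, collapse = ", "))
  wins <- table(factor(e$winner_id, levels = members),
                factor(e$loser_id, levels = members))
  structure(list(wins = unclass(wins), members = members),
            class = "agonistic_matrix")
}

#' Modified David's Score and dominance ranks
#'
#' David's score combines an unweighted and a weighted sum of an
#' individual's dyadic win proportions with the analogous loss sums.  For
#' each dyad with `n_ij = wins_ij + wins_ji > 0` interactions the raw win
#' proportion is `P_ij = wins_ij / n_ij`; the modified (chance-corrected)
#' index shrinks it toward 0.5 by the amount of evidence:
#' `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`.  Dyads that never
#' interacted contribute 0 to every sum.  Then
#' `w_i = sum_j D_ij`, `w2_i = sum_j D_ij * w_j`,
#' `l_i = sum_j D_ji`, `l2_i = sum_j D_ji * l_j`, and
#' `DS_i = w_i + w2_i - l_i - l2_i`.  Individuals are ranked from the
#' highest score (rank 1) to the lowest; ties are broken by id, and tied
#' ids are reported in the result.
#'
#' @param agonistic an [agonistic_matrix()] or a plain square win matrix
#'   with dimnames.
#' @param correction `"corrected"` (default) uses the chance-corrected
#'   `D_ij`; `"raw"` uses plain `P_ij`.
#' @return An `mds_result`: data frame `scores` (id, w, w2, l, l2, ds,
#'   rank), matrices `P` and `D`, and `ties` (ids involved in tied
#'   scores).
#' @export
compute_mds <- function(agonistic, correction = c("corrected", "raw")) {
  correction <- match.arg(correction)
  if (inherits(agonistic, "agonistic_matrix")) {
    W <- agonistic$wins; members <- agonistic$members
  } else {
    W <- as.matrix(agonistic)
    members <- rownames(W) %||% as.character(seq_len(nrow(W)))
  }
  N <- nrow(W)
  if (N < 2L) .stop("David's score needs at least two individuals")
  if (any(W < 0)) .stop("win matrix must be non-negative")
  if (any(diag(W) != 0)) .stop("win matrix must have zero diagonal")
  storage.mode(W) <- "double"

  n <- W + t(W)
  P <- matrix(0, N, N, dimnames = list(members, members))
  has <- n > 0
  P[has] <- W[has] / n[has]
  if (correction == "corrected") {
    D <- matrix(0, N, N, dimnames = list(members, members))
    D[has] <- P[has] - (P[has] - 0.5) / (n[has] + 1)
  } else {
    D <- P
  }
  w <- rowSums(D)
  w2 <- as.vector(D %*% w)
  l <- colSums(D)
  l2 <- as.vector(t(D) %*% l)
  ds <- w + w2 - l - l2

  ord <- order(-ds, members)
  rank <- integer(N); rank[ord] <- seq_len(N)
  tied <- members[duplicated(ds) | duplicated(ds, fromLast = TRUE)]
  scores <- data.frame(id = members, w = w, w2 = w2, l = l, l2 = l2,
                       ds = ds, rank = rank, stringsAsFactors = FALSE,
                       row.names = NULL)
  structure(list(scores = scores, P = P, D = D, ties = tied,
                 correction = correction),
            class = "mds_result")
}

#' Spearman correlation of estimated ranks with a latent order
#'
#' Validation utility for synthetic herds: correlates the MDS dominance
#' ranks with a supplied ground-truth order.
#'
#' @param mds an `mds_result`.
#' @param latent_order character vector of the same ids ordered from the
#'   highest-ranking (first) to the lowest, or a named integer rank
#'   vector.
#' @return Spearman's rho between the two rankings.
#' @export
rank_correlation_with_latent <- function(mds, latent_order) {
  stopifnot(inherits(mds, "mds_result"))
  ids <- mds$scores$id
  if (is.character(latent_order)) {
    if (!setequal(ids, latent_order))
      .stop("latent order and MDS result cover different individuals")
    latent_rank <- match(ids, latent_order)
  } else {
    if (is.null(names(latent_order)) || !setequal(ids, names(latent_order)))
      .stop("latent ranks must be named by the same individual ids")
    latent_rank <- as.numeric(latent_order[ids])
  }
  cor(mds$scores$rank, latent_rank, method = "spearman")
}

#' Write per-individual dominance scores as CSV
#'
#' @param mds an `mds_result`.
#' @param path file path.
#' @export
write_mds_csv <- function(mds, path) {
  stopifnot(inherits(mds, "mds_result"))
  write.csv(mds$scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result (%s): %d individuals\n", x$correction,
              nrow(x$scores)))
  print(x$scores[order(x$scores$rank), c("id", "ds", "rank")],
        row.names = FALSE)
  invisible(x)
}
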