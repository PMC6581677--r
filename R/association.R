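# Dyadic nearest-neighbour association matrices.

#' Construct an association matrix object
#'
#' A symmetric non-negative integer matrix of nearest-neighbour
#' co-occurrence counts with zero diagonal; the edge weights of the social
#' network.
#'
#' @param counts N x N numeric matrix, symmetric, zero diagonal.
#' @param members ordered character vector of individual ids.
#' @param n_scans_used number of scans contributing to the counts.
#' @return An `association_matrix` object.
#' @export
association_matrix <- function(counts, members = rownames(counts),
                               n_scans_used = NA_integer_) {
  counts <- as.matrix(counts)
  if (is.null(members)) .stop("association matrix needs member ids")
  dimnames(counts) <- list(members, members)
  x <- structure(list(counts = counts, members = members,
                      n_scans_used = n_scans_used),
                 class = "association_matrix")
  validate_association_matrix(x)
  x
}

#' @rdname association_matrix
#' @param x an `association_matrix`.
#' @export
validate_association_matrix <- function(x) {
  stopifnot(inherits(x, "association_matrix"))
  m <- x$counts
  if (nrow(m) != ncol(m)) .stop("association matrix must be square")
  if (!isTRUE(all.equal(m, t(m)))) .stop("association matrix must be symmetric")
  if (any(m < 0)) .stop("association counts must be non-negative")
  if (any(diag(m) != 0)) .stop("association matrix must have zero diagonal")
  invisible(x)
}

#' Build the association matrix of one composition from the scan log
#'
#' Each scan records, for a focal individual, its single nearest
#' neighbour.  The directed designation focal -> neighbour adds 1 to the
#' dyad; directed counts are summed into one symmetric matrix, so a scan
#' in which A and B are each other's nearest neighbour contributes 2 to
#' the (A, B) dyad.  When the scan table carries a `day` column (day
#' offset from the composition start, 1-based), scans from the first
#' `exclusion_days` days are discarded: relationships are unstable
#' immediately after a change of composition or enclosure, so scoring
#' starts on day `exclusion_days + 1` (default: the eighth day).
#'
#' @param scans scan table (may contain scans of other compositions;
#'   they are ignored).
#' @param composition composition id or one-row slice of
#'   `herd$compositions` (or a list with `composition_id` and `members`).
#' @param exclusion_days days to discard at the start, default 7.
#' @param herd optional `herd_data`, needed when `composition` is an id.
#' @return An [association_matrix()].  All-zero with a warning when no
#'   scans survive.
#' @export
build_association_matrix <- function(scans, composition, exclusion_days = 7,
                                     herd = NULL) {
  comp <- .as_composition(composition, herd)
  members <- comp$members
  s <- scans[scans$composition_id == comp$composition_id, , drop = FALSE]
  unknown <- setdiff(unique(c(s$focal_id, s$neighbour_id)), members)
  if (length(unknown))
    .stop("scan log references non-members of %s: %s", comp$composition_id,
          paste(unknown, collapse = ", "))
  if ("day" %in% names(s) && nrow(s))
    s <- s[s$day > exclusion_days, , drop = FALSE]
  if (!nrow(s)) {
    .warn("no scans for composition %s after the exclusion window",
          comp$composition_id)
    return(association_matrix(matrix(0L, length(members), length(members)),
                              members, 0L))
  }
  directed <- table(factor(s$focal_id, levels = members),
                    factor(s$neighbour_id, levels = members))
  counts <- unclass(directed) + t(unclass(directed))
  association_matrix(counts, members, length(unique(s$scan_index)))
}

#' Sum association matrices over observation days
#'
#' Daily association matrices of the same composition are added
#' elementwise into the composition's total matrix.
#'
#' @param matrices list of [association_matrix()] objects with identical
#'   member lists.
#' @return The elementwise-sum `association_matrix`.
#' @export
aggregate_daily <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  members <- matrices[[1L]]$members
  for (m in matrices) {
    if (!identical(m$members, members))
      .stop("cannot aggregate association matrices with different members")
  }
  counts <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  n <- sum(vapply(matrices, function(m) as.integer(m$n_scans_used %||% 0L),
                  integer(1)), na.rm = TRUE)
  association_matrix(counts, members, n)
}

#' Read/write association matrices as square CSV
#'
#' The conventional exchange format for social-network tools: a square
#' table with the member ids as both header row and first column.
#'
#' @param x an `association_matrix`.
#' @param path file path.
#' @return `write_association_csv` returns `path` invisibly;
#'   `read_association_csv` returns an `association_matrix`.
#' @export
write_association_csv <- function(x, path) {
  validate_association_matrix(x)
  df <- data.frame(id = x$members, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_csv
#' @export
read_association_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  members <- as.character(df[[1L]])
  counts <- as.matrix(df[, -1L, drop = FALSE])
  association_matrix(counts, members)
}

#' Write an association matrix as an edge list
#'
#' One row per dyad with positive weight: `id1,id2,weight`, upper
#' triangle only.
#'
#' @inheritParams write_association_csv
#' @export
write_edge_list <- function(x, path) {
  validate_association_matrix(x)
  idx <- which(upper.tri(x$counts) & x$counts > 0, arr.ind = TRUE)
  df <- data.frame(id1 = x$members[idx[, 1L]], id2 = x$members[idx[, 2L]],
                   weight = x$counts[idx], stringsAsFactors = FALSE)
  df <- df[order(df$id1, df$id2), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("association_matrix:", length(x$members), "individuals,",
      sum(x$counts) / 2, "dyadic designations,", x$n_scans_used, "scans\n")
  invisible(x)
}
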