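# Strength, eigenvector centrality, group-size correction, MetricTable.

.assoc_counts <- function(assoc) {
  if (inherits(assoc, "association_matrix")) return(assoc$counts)
  m <- as.matrix(assoc)
  if (is.null(rownames(m))) dimnames(m) <- list(as.character(seq_len(nrow(m))),
                                                as.character(seq_len(ncol(m))))
  m
}

#' Strength of associations
#'
#' The sum of each node's edge values: how often an individual was
#' recorded as the nearest neighbour of (or had as nearest neighbour)
#' another group member.
#'
#' @param assoc an [association_matrix()] or symmetric numeric matrix.
#' @return Named numeric vector of row sums.
#' @export
strength <- function(assoc) {
  m <- .assoc_counts(assoc)
  if (!isTRUE(all.equal(m, t(m))))
    .stop("strength is defined on a symmetric association matrix")
  rowSums(m)
}

# connected components of the positive-weight graph (simple BFS)
.components <- function(m) {
  n <- nrow(m)
  comp <- integer(n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- k
      queue <- c(queue, which(m[v, ] > 0 & comp == 0L))
    }
  }
  comp
}

#' Eigenvector centrality of a weighted association network
#'
#' Entry of the dominant eigenvector of the symmetric non-negative
#' association matrix: high for individuals connected to well-connected
#' partners ("popularity").  Returned entrywise non-negative with unit
#' Euclidean norm (`sum(e^2) = 1`); a max-entry-equals-1 normalization is
#' available.  On a disconnected network the dominant eigenvector
#' concentrates on the strongest component; a structural warning lists
#' the components.
#'
#' @param assoc an [association_matrix()] or symmetric non-negative
#'   matrix with at least one positive entry.
#' @param normalization `"euclidean"` (default) or `"max"`.
#' @param method `"exact"` (default, full symmetric eigendecomposition)
#'   or `"power"` (power iteration).
#' @param tol convergence tolerance for the power method, default 1e-10.
#' @param max_iter iteration cap for the power method.
#' @return Named numeric vector of centralities, with the dominant
#'   eigenvalue as attribute `"eigenvalue"`.
#' @export
eigenvector_centrality <- function(assoc,
                                   normalization = c("euclidean", "max"),
                                   method = c("exact", "power"),
                                   tol = 1e-10, max_iter = 1000L) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  m <- .assoc_counts(assoc)
  if (!isTRUE(all.equal(m, t(m))))
    .stop("eigenvector centrality is defined on a symmetric matrix")
  if (any(m < 0)) .stop("association weights must be non-negative")
  if (all(m == 0))
    .stop("eigenvector centrality is undefined on an all-zero matrix")
  comp <- .components(m)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    .warn("association network has %d components (sizes %s); centrality concentrates on the strongest component",
          max(comp), paste(sizes, collapse = ", "))
  }
  if (method == "exact") {
    es <- eigen(m, symmetric = TRUE)
    lambda <- es$values[1L]
    v <- es$vectors[, 1L]
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
  } else {
    v <- rep(1 / sqrt(nrow(m)), nrow(m))
    lambda <- 0
    for (it in seq_len(max_iter)) {
      nv <- as.vector(m %*% v)
      lambda <- sqrt(sum(nv^2))
      if (lambda == 0) .stop("power iteration collapsed to zero")
      nv <- nv / lambda
      if (max(abs(nv - v)) < tol) { v <- nv; break }
      v <- nv
      if (it == max_iter)
        .stop("power iteration did not converge in %d iterations", max_iter)
    }
  }
  v <- v / sqrt(sum(v^2))
  if (normalization == "max") v <- v / max(v)
  names(v) <- rownames(m)
  attr(v, "eigenvalue") <- lambda
  v
}

#' Assemble the per-individual, per-composition metric table
#'
#' The unit of the regression analyses: one row per (individual,
#' composition) carrying the network metrics (strength, eigenvector
#' centrality), the dominance rank from the agonistic data, and the
#' socio-demographic attributes (age at composition start, sex,
#' familiarity count, group size).
#'
#' @param herd a `herd_data` object.
#' @param assoc_list named list of [association_matrix()] per composition
#'   id (built if `NULL`).
#' @param mds_list named list of `mds_result` per composition id (built
#'   if `NULL`).
#' @param exclusion_days passed to [build_association_matrix()] when
#'   matrices are built here.
#' @param familiarity_threshold passed to [compute_familiarity()].
#' @return Data frame with columns `individual_id`, `composition_id`,
#'   `group`, `group_size`, `strength`, `eigenvector`, `age`, `sex`,
#'   `dominance`, `familiarity`.  `dominance` is the MDS rank (1 =
#'   highest); individuals absent from the agonistic data keep their rank
#'   from the all-zero-score ordering.
#' @export
build_metric_table <- function(herd, assoc_list = NULL, mds_list = NULL,
                               exclusion_days = 7,
                               familiarity_threshold = 90) {
  comps <- herd$compositions
  rows <- vector("list", nrow(comps))
  for (k in seq_len(nrow(comps))) {
    cid <- comps$composition_id[k]
    comp <- .as_composition(comps[k, , drop = FALSE])
    assoc <- assoc_list[[cid]] %||%
      build_association_matrix(herd$scans, comp,
                               exclusion_days = exclusion_days)
    mds <- mds_list[[cid]] %||% compute_mds(agonistic_matrix(herd$events, comp))
    st <- strength(assoc)
    ev <- if (all(assoc$counts == 0)) setNames(rep(NA_real_,
                                                   length(comp$members)),
                                               comp$members)
          else eigenvector_centrality(assoc)
    fam <- compute_familiarity(comp, herd, familiarity_threshold)
    ind <- herd$individuals
    sexes <- ind$sex[match(comp$members, ind$id)]
    ages <- compute_age(ind$birth_date[match(comp$members, ind$id)],
                        comp$start_date)
    rank <- mds$scores$rank[match(comp$members, mds$scores$id)]
    rows[[k]] <- data.frame(
      individual_id = comp$members, composition_id = cid,
      group = comp$group, group_size = length(comp$members),
      strength = as.numeric(st[comp$members]),
      eigenvector = as.numeric(ev[comp$members]),
      age = ages, sex = factor(as.character(sexes), levels = SEX_LEVELS),
      dominance = rank, familiarity = as.numeric(fam[comp$members]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correct centralities for group size
#'
#' Larger groups mechanically inflate network metrics (more nodes, more
#' scans of partners), so metrics are adjusted for the number of
#' individuals before regression.  Mode `"residual"` (default) fits the
#' pooled regression `y = a*x + b` of the metric on group size and
#' returns `y - a*(x - mean(x))`, removing the size trend while
#' preserving the mean.  Mode `"literal"` returns `y * b` (the fitted
#' intercept), kept for reproduction of analyses that used that rule;
#' multiplying by a constant cannot remove a size effect, which is why it
#' is not the default.  Both record the fitted `(a, b)` per metric as the
#' `"correction"` attribute.
#'
#' @param metric_table data frame from [build_metric_table()] (needs a
#'   `group_size` column).
#' @param mode `"residual"` or `"literal"`.
#' @param metrics columns to correct, default strength and eigenvector.
#' @return The table with `<metric>_corrected` columns appended.  With
#'   fewer than two distinct group sizes the correction is the identity
#'   and a warning is raised.
#' @export
correct_for_group_size <- function(metric_table,
                                   mode = c("residual", "literal"),
                                   metrics = c("strength", "eigenvector")) {
  mode <- match.arg(mode)
  x <- metric_table$group_size
  fits <- list()
  single <- length(unique(x)) < 2L
  if (single)
    .warn("fewer than two distinct group sizes: group-size correction is the identity")
  for (m in metrics) {
    y <- metric_table[[m]]
    if (single) {
      metric_table[[paste0(m, "_corrected")]] <- y
      fits[[m]] <- c(a = 0, b = mean(y, na.rm = TRUE))
      next
    }
    ok <- complete.cases(y, x)
    fit <- lm(y[ok] ~ x[ok])
    a <- unname(coef(fit)[2L]); b <- unname(coef(fit)[1L])
    metric_table[[paste0(m, "_corrected")]] <-
      if (mode == "residual") y - a * (x - mean(x[ok])) else y * b
    fits[[m]] <- c(a = a, b = b)
  }
  attr(metric_table, "correction") <- list(mode = mode, fits = fits)
  metric_table
}
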