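# Attribute-difference matrices, Mantel tests, permutation correlation
# tests, matrix restriction, p-value combination.

#' Attribute-difference matrix for homophily tests
#'
#' For numeric attributes (age, dominance rank) the entry is the absolute
#' pairwise difference (0 = same age/rank, 1 = one year/rank apart, ...);
#' for sex it is the inequality indicator (0 = same sex, 1 = different
#' sex).
#'
#' @param values named attribute vector (names = individual ids).
#' @param kind `"age"`, `"rank"` or `"sex"`.
#' @return Symmetric matrix with zero diagonal and dimnames from `values`.
#' @export
difference_matrix <- function(values, kind = c("age", "rank", "sex")) {
  kind <- match.arg(kind)
  if (anyNA(values)) .stop("attribute has missing values")
  members <- names(values) %||% as.character(seq_along(values))
  m <- if (kind == "sex") {
    v <- as.character(values)
    1 * outer(v, v, `!=`)
  } else {
    v <- as.numeric(values)
    abs(outer(v, v, `-`))
  }
  dimnames(m) <- list(members, members)
  m
}

# all permutations of 1..n as an n! x n matrix (n small)
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(rep.int(k, nrow(p)),
                      matrix(rest[p], nrow(p), n - 1L))
  }
  do.call(rbind, out)
}

.perm_p <- function(stat_null, stat_obs, sided, exhaustive) {
  eps <- 1e-12 * (1 + abs(stat_obs))
  hit <- switch(sided,
    two = abs(stat_null) >= abs(stat_obs) - eps,
    one_pos = stat_null >= stat_obs - eps,
    one_neg = stat_null <= stat_obs + eps)
  if (exhaustive) mean(hit) else (sum(hit) + 1) / (length(stat_null) + 1)
}

#' Mantel test between two square matrices
#'
#' Correlates the vectorized upper triangles of two symmetric matrices
#' and assesses significance by simultaneously permuting the rows and
#' columns of one matrix, respecting the non-independence of dyads.
#' The sampled-permutation p-value uses the +1/+1 rule (the observed
#' statistic is part of the null set), so p > 0 always.  When `N!` is at
#' most 5000 the null is enumerated exhaustively and the p-value is
#' exact.
#'
#' @param X,Y symmetric matrices over the same members, N >= 3.
#' @param sided `"two"`, `"one_pos"` or `"one_neg"`; required, because the
#'   direction of a homophily hypothesis is part of the test.
#' @param n_perm permutations to sample (default 1000); ignored in
#'   exhaustive mode.
#' @param seed optional integer seed for the sampled mode.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) enumeration;
#'   default `NULL` = automatic (`N! <= 5000`).
#' @return A `mantel_result` list: `r`, `p`, `n_perm` (number of null
#'   statistics), `sided`, `exhaustive`, `seed`.
#' @export
mantel_test <- function(X, Y, sided, n_perm = 1000, seed = NULL,
                        exhaustive = NULL) {
  sided <- match.arg(sided, c("two", "one_pos", "one_neg"))
  X <- .assoc_counts(X); Y <- .assoc_counts(Y)
  if (!all(dim(X) == dim(Y)))
    .stop("Mantel test needs matrices of identical size")
  N <- nrow(X)
  if (N < 3L) .stop("Mantel test needs at least 3 individuals")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    .stop("Mantel test needs matrices over the same members in the same order")
  ut <- upper.tri(X)
  x <- X[ut]; y <- Y[ut]
  if (sd(x) == 0 || sd(y) == 0)
    .stop("matrix correlation undefined: constant matrix")
  r_obs <- cor(x, y)
  if (is.null(exhaustive)) exhaustive <- factorial(N) <= 5000
  if (exhaustive) {
    perms <- .all_permutations(N)
    r_null <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      cor(x, Y[p, p][ut])
    }, numeric(1))
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_null <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(N)
      cor(x, Y[p, p][ut])
    }, numeric(1))
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = .perm_p(r_null, r_obs, sided, exhaustive),
                 n_perm = n_used, sided = sided, exhaustive = exhaustive,
                 seed = seed),
            class = "mantel_result")
}

#' Restrict two association matrices to their shared members
#'
#' Before correlating the networks of two adjacent compositions, both
#' matrices are subset to the individuals present in both, in identical
#' order (the first matrix's member order).
#'
#' @param assoc_before,assoc_after [association_matrix()] objects.
#' @return List of the two restricted `association_matrix` objects and
#'   `shared` (the id vector).  Error when fewer than 3 members are
#'   shared (the Mantel test would be undefined).
#' @export
restrict_to_shared <- function(assoc_before, assoc_after) {
  mb <- assoc_before$members; ma <- assoc_after$members
  shared <- mb[mb %in% ma]
  if (length(shared) < 3L)
    .stop("fewer than 3 shared individuals between the two compositions")
  sub <- function(a) association_matrix(a$counts[shared, shared,
                                                 drop = FALSE],
                                        shared, a$n_scans_used)
  list(before = sub(assoc_before), after = sub(assoc_after),
       shared = shared)
}

#' Correlation test with permutations
#'
#' Spearman (default) or Pearson correlation of two vectors with a
#' permutation p-value obtained by shuffling one vector; exact
#' enumeration when `n! <= 5000`.
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-constant.
#' @param sided `"two"`, `"one_pos"` or `"one_neg"` (required).
#' @param n_perm sampled permutations, default 1000.
#' @param method `"spearman"` or `"pearson"`.
#' @param seed optional integer seed.
#' @param exhaustive `NULL` = automatic.
#' @return List with `estimate`, `p`, `method`, `n_perm`, `sided`,
#'   `exhaustive`, `seed`.
#' @export
perm_correlation <- function(x, y, sided, n_perm = 1000,
                             method = c("spearman", "pearson"),
                             seed = NULL, exhaustive = NULL) {
  sided <- match.arg(sided, c("two", "one_pos", "one_neg"))
  method <- match.arg(method)
  if (length(x) != length(y)) .stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) .stop("permutation correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) .stop("correlation undefined: constant vector")
  est <- cor(x, y, method = method)
  if (is.null(exhaustive)) exhaustive <- factorial(n) <= 5000
  if (exhaustive) {
    perms <- .all_permutations(n)
    null <- vapply(seq_len(nrow(perms)), function(k)
      cor(x, y[perms[k, ]], method = method), numeric(1))
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(k)
      cor(x, y[sample.int(n)], method = method), numeric(1))
    n_used <- n_perm
  }
  list(estimate = est, p = .perm_p(null, est, sided, exhaustive),
       method = method, n_perm = n_used, sided = sided,
       exhaustive = exhaustive, seed = seed)
}

#' Combine p-values across group compositions
#'
#' Fisher's method (default): `X2 = -2 * sum(log(p))` referred to the
#' chi-square upper tail with `2k` degrees of freedom.  Stouffer's
#' Z-score method is available as an option (p-values of exactly 1 are
#' nudged below 1 for the normal quantile).  Combining is monotone:
#' lowering any input p never raises the combined p.
#'
#' @param p_list numeric vector of p-values in (0, 1].  A p of exactly 0
#'   is an error — permutation p-values produced upstream respect the
#'   1/(n_perm + 1) floor.
#' @param method `"fisher"` or `"stouffer"`.
#' @return The combined p-value.
#' @export
combine_pvalues <- function(p_list, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  p <- as.numeric(p_list)
  if (!length(p)) .stop("no p-values to combine")
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    .stop("p-values must lie in (0, 1]")
  if (method == "fisher") {
    pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  } else {
    z <- sum(qnorm(1 - pmin(p, 1 - 1e-16))) / sqrt(length(p))
    pnorm(z, lower.tail = FALSE)
  }
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %s, %d permutations)\n",
              x$r, x$p, x$sided,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}
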