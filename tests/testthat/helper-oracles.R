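# Independent brute-force oracles used to pin expected values.  These are
# deliberately naive (per-dyad loops, explicit enumeration) and share no
# code with the package implementations they check.

# David's score by explicit per-dyad summation
oracle_mds <- function(W, corrected = TRUE) {
  N <- nrow(W)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      n_ij <- W[i, j] + W[j, i]
      if (n_ij == 0) next
      P <- W[i, j] / n_ij
      D[i, j] <- if (corrected) P - (P - 0.5) / (n_ij + 1) else P
    }
  }
  w <- w2 <- l <- l2 <- numeric(N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      w[i] <- w[i] + D[i, j]
      l[i] <- l[i] + D[j, i]
    }
  }
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      w2[i] <- w2[i] + D[i, j] * w[j]
      l2[i] <- l2[i] + D[j, i] * l[j]
    }
  }
  w + w2 - l - l2
}

# association counts by scanning the log row by row
oracle_association <- function(scans, members) {
  m <- matrix(0, length(members), length(members),
              dimnames = list(members, members))
  for (r in seq_len(nrow(scans))) {
    i <- scans$focal_id[r]; j <- scans$neighbour_id[r]
    m[i, j] <- m[i, j] + 1
    m[j, i] <- m[j, i] + 1
  }
  m
}

# exhaustive Mantel p by enumerating every relabelling (independent of the
# package's permutation generator)
oracle_mantel_exhaustive <- function(X, Y, sided = "two") {
  N <- nrow(X)
  ut <- upper.tri(X)
  x <- X[ut]
  r_obs <- cor(x, Y[ut])
  perms <- .perms_list(seq_len(N))
  r_all <- vapply(perms, function(p) cor(x, Y[p, p][ut]), numeric(1))
  eps <- 1e-12 * (1 + abs(r_obs))
  hits <- switch(sided,
                 two = abs(r_all) >= abs(r_obs) - eps,
                 one_pos = r_all >= r_obs - eps,
                 one_neg = r_all <= r_obs + eps)
  list(r = r_obs, p = mean(hits))
}

oracle_perm_cor_exhaustive <- function(x, y, method = "spearman",
                                       sided = "two") {
  est <- cor(x, y, method = method)
  perms <- .perms_list(seq_along(y))
  null <- vapply(perms, function(p) cor(x, y[p], method = method),
                 numeric(1))
  eps <- 1e-12 * (1 + abs(est))
  hits <- switch(sided,
                 two = abs(null) >= abs(est) - eps,
                 one_pos = null >= est - eps,
                 one_neg = null <= est + eps)
  list(estimate = est, p = mean(hits))
}

# recursive permutation list (distinct from the package's matrix builder)
.perms_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    out <- c(out, lapply(.perms_list(v[-k]), function(p) c(v[k], p)))
  out
}

# pairwise co-residence days by day-by-day simulation over a calendar grid
oracle_coresidence <- function(res1, res2, ref_date) {
  days <- seq(min(res1$start, res2$start), ref_date - 1, by = "day")
  loc_on <- function(res, d) {
    hit <- res$start <= d & (is.na(res$end) | res$end > d)
    if (any(hit)) res$location[which(hit)[1L]] else NA_character_
  }
  sum(vapply(days, function(d) {
    l1 <- loc_on(res1, d); l2 <- loc_on(res2, d)
    !is.na(l1) && !is.na(l2) && l1 == l2
  }, logical(1)))
}
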