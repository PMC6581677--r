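test_that("strength is the row sum, zero for isolates, closed-form on complete graphs", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[1, 2] <- m[2, 1] <- 3
  m[2, 3] <- m[3, 2] <- 5
  s <- strength(m)
  expect_equal(unname(s), c(3, 8, 5, 0))
  # complete graph with uniform weight w
  w <- 7; N <- 6
  cg <- matrix(w, N, N); diag(cg) <- 0
  dimnames(cg) <- list(letters[1:N], letters[1:N])
  expect_equal(unname(strength(cg)), rep((N - 1) * w, N))
  set.seed(41)
  r <- random_sym_matrix(7)
  expect_equal(strength(r), rowSums(r))
  asym <- r; asym[1, 2] <- asym[1, 2] + 1
  expect_error(strength(asym), "symmetric")
})

test_that("eigenvector centrality matches closed forms", {
  N <- 5
  cg <- matrix(1, N, N); diag(cg) <- 0
  dimnames(cg) <- list(letters[1:N], letters[1:N])
  expect_equal(as.numeric(eigenvector_centrality(cg)), rep(1 / sqrt(N), N),
               tolerance = 1e-10)
  # star: centre 1/sqrt(2), leaves 1/sqrt(2*(N-1))
  N <- 7
  star <- matrix(0, N, N); star[1, 2:N] <- star[2:N, 1] <- 1
  dimnames(star) <- list(letters[1:N], letters[1:N])
  e <- eigenvector_centrality(star)
  expect_equal(unname(e[1]), 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(unname(e[-1]), rep(1 / sqrt(2 * (N - 1)), N - 1),
               tolerance = 1e-10)
  expect_equal(unname(attr(e, "eigenvalue")), sqrt(N - 1),
               tolerance = 1e-10)
})

test_that("exact and power methods agree and satisfy A e = lambda e", {
  set.seed(42)
  for (rep in 1:5) {
    m <- random_sym_matrix(8)
    e1 <- eigenvector_centrality(m, method = "exact")
    e2 <- eigenvector_centrality(m, method = "power")
    expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-8)
    lambda <- attr(e1, "eigenvalue")
    expect_lt(max(abs(m %*% e1 - lambda * e1)), 1e-8)
    expect_equal(sum(e1^2), 1, tolerance = 1e-12)
    expect_true(all(e1 >= 0))
  }
})

test_that("eigenvector centrality agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(43)
  m <- random_sym_matrix(8)
  e <- eigenvector_centrality(m)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::eigen_centrality(g)$vector
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(as.numeric(e), unname(ref[rownames(m)]), tolerance = 1e-6)
})

test_that("scaling weights scales strength but not eigenvector", {
  set.seed(44)
  m <- random_sym_matrix(6)
  expect_equal(strength(3 * m), 3 * strength(m))
  expect_equal(as.numeric(eigenvector_centrality(3 * m)),
               as.numeric(eigenvector_centrality(m)), tolerance = 1e-10)
})

test_that("all-zero matrices error and disconnected graphs warn", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(eigenvector_centrality(z), "undefined")
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[1, 2] <- m[2, 1] <- 5
  m[3, 4] <- m[4, 3] <- 1
  expect_warning(eigenvector_centrality(m), "components")
})

test_that("max normalization rescales the top individual to one", {
  set.seed(45)
  m <- random_sym_matrix(5)
  e <- eigenvector_centrality(m, normalization = "max")
  expect_equal(max(e), 1)
})

test_that("residual group-size correction removes the size trend", {
  set.seed(46)
  n <- 200
  x <- sample(8:21, n, replace = TRUE)
  tab <- data.frame(group_size = x,
                    strength = 2 * x + rnorm(n),
                    eigenvector = 0.5 - 0.01 * x + rnorm(n, 0, 0.05))
  out <- correct_for_group_size(tab)
  expect_lt(abs(cor(out$strength_corrected, x)), 0.05)
  expect_lt(abs(cor(out$eigenvector_corrected, x)), 0.05)
  # means preserved
  expect_equal(mean(out$strength_corrected), mean(tab$strength))
  fits <- attr(out, "correction")$fits
  expect_equal(unname(fits$strength["a"]), 2, tolerance = 0.1)
})

test_that("no size trend leaves residual-mode values unchanged", {
  set.seed(47)
  x <- rep(c(10, 15), each = 30)
  y <- rnorm(60)
  y <- y - ave(y, x) + mean(y)      # force slope exactly 0 within groups
  tab <- data.frame(group_size = x, strength = y, eigenvector = y)
  out <- correct_for_group_size(tab)
  expect_equal(out$strength_corrected, y, tolerance = 1e-10)
})

test_that("literal mode multiplies by the fitted intercept", {
  tab <- data.frame(group_size = c(10, 10, 20, 20),
                    strength = c(1, 3, 2, 4),
                    eigenvector = c(1, 3, 2, 4))
  out <- correct_for_group_size(tab, mode = "literal")
  b <- attr(out, "correction")$fits$strength["b"]
  expect_equal(out$strength_corrected, tab$strength * unname(b))
  # with a fitted intercept of exactly 1 the output equals the input
  tab2 <- data.frame(group_size = c(0, 0, 1, 1),
                     strength = c(0.5, 1.5, 1.5, 2.5),
                     eigenvector = c(0.5, 1.5, 1.5, 2.5))
  out2 <- correct_for_group_size(tab2, mode = "literal")
  expect_equal(unname(attr(out2, "correction")$fits$strength["b"]), 1,
               tolerance = 1e-12)
  expect_equal(out2$strength_corrected, tab2$strength)
})

test_that("a single group size is an identity correction with a warning", {
  tab <- data.frame(group_size = rep(10, 5), strength = 1:5,
                    eigenvector = 1:5)
  expect_warning(out <- correct_for_group_size(tab), "identity")
  expect_equal(out$strength_corrected, tab$strength)
})
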