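# simulated metric-table-shaped data with known coefficients
sim_table <- function(n_id = 30, n_comp = 3, beta = c(age = 0.5),
                      sd_id = 0.5, sd_eps = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n_id))
  tab <- expand.grid(individual_id = ids,
                     composition_id = sprintf("C%d", seq_len(n_comp)),
                     stringsAsFactors = FALSE)
  tab$age <- round(runif(nrow(tab), 1, 10))
  tab$familiarity <- rpois(nrow(tab), 4)
  tab$dominance <- ave(tab$age, tab$composition_id,
                       FUN = function(a) rank(-a, ties.method = "first"))
  u <- rnorm(n_id, 0, sd_id)
  mu <- 0
  for (nm in names(beta)) mu <- mu + beta[[nm]] * tab[[nm]]
  tab$y <- mu + u[match(tab$individual_id, ids)] +
    rnorm(nrow(tab), 0, sd_eps)
  tab
}

test_that("with one observation per individual the fit reduces to OLS", {
  tab <- sim_table(n_id = 40, n_comp = 1, seed = 2)
  fit <- fit_mixed(model_spec("y", c("age", "familiarity")), tab)
  ols <- lm(y ~ age + familiarity, data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("an identically-zero response gives all-zero estimates", {
  tab <- sim_table(seed = 3)
  tab$y <- 0
  fit <- fit_mixed(model_spec("y", "age"), tab)
  expect_equal(fit$coefficients$estimate, c(0, 0), tolerance = 1e-10)
})

test_that("a singular design errors and names the aliased column", {
  tab <- sim_table(seed = 4)
  tab$age2 <- tab$age
  expect_error(fit_mixed(model_spec("y", c("age", "age2")), tab),
               "aliased.*age2")
})

test_that("AICc exceeds AIC and the correction vanishes with n", {
  corr <- vapply(c(20, 50, 200, 1000), function(n) {
    tab <- sim_table(n_id = n, n_comp = 1, seed = 5)
    fit <- fit_mixed(model_spec("y", "age"), tab)
    fit$aicc - fit$aic
  }, numeric(1))
  expect_true(all(corr > 0))
  expect_true(all(diff(corr) < 0))
})

test_that("VIF is 1 for orthogonal predictors, closed-form at r = 0.6, Inf at collinearity", {
  set.seed(6)
  n <- 64
  z1 <- rnorm(n); z2 <- rnorm(n)
  x1 <- z1 - mean(z1); x1 <- x1 / sqrt(sum(x1^2))
  z2 <- z2 - mean(z2)
  z2 <- z2 - sum(z2 * x1) * x1           # exactly orthogonal to x1
  z2 <- z2 / sqrt(sum(z2^2))
  tab <- data.frame(x1 = x1, x2 = z2)
  expect_equal(unname(compute_vif(tab, c("x1", "x2"))), c(1, 1),
               tolerance = 1e-10)
  # empirical correlation exactly 0.6 by construction
  tab$x2 <- 0.6 * x1 + 0.8 * z2
  v <- compute_vif(tab, c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 1e-6)
  tab$x3 <- tab$x1
  v3 <- compute_vif(tab, c("x1", "x3"))
  expect_true(all(!is.finite(v3)))
})

test_that("VIF agrees with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(7)
  tab <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  tab$b <- tab$b + 0.5 * tab$a
  tab$y <- rnorm(50)
  ours <- compute_vif(tab, c("a", "b", "c"))
  ref <- car::vif(lm(y ~ a + b + c, data = tab))
  expect_equal(unname(ours[c("a", "b", "c")]), unname(ref[c("a", "b", "c")]),
               tolerance = 1e-8)
})

test_that("single-candidate RVI equals the full model's Akaike weight", {
  tab <- sim_table(seed = 8)
  inf <- all_subsets_inference(model_spec("y", "age"), tab)
  expect_equal(nrow(inf$models), 2)
  expect_equal(sum(inf$models$weight), 1)
  w_full <- inf$models$weight[inf$models$terms == "age"]
  expect_equal(unname(inf$rvi["age"]), w_full)
})

test_that("model-averaged estimates equal the dominant model's when its weight is ~1", {
  # a strong effect and large n make the full model carry all the weight
  tab <- sim_table(n_id = 80, n_comp = 3, beta = c(age = 2), sd_eps = 0.5,
                   seed = 9)
  inf <- all_subsets_inference(model_spec("y", c("age", "familiarity")),
                               tab)
  top <- which.max(inf$models$weight)
  if (inf$models$weight[top] > 0.99) {
    fit_top <- inf$fits[[top]]$coefficients
    for (r in seq_len(nrow(fit_top))) {
      avg <- inf$averaged$estimate[inf$averaged$term == fit_top$term[r]]
      expect_equal(avg, fit_top$estimate[r], tolerance = 1e-6)
    }
  }
  expect_equal(sum(inf$models$weight), 1)
})

test_that("perfectly collinear candidates are rejected before fitting", {
  tab <- sim_table(seed = 10)
  tab$age_copy <- tab$age
  expect_error(all_subsets_inference(model_spec("y", c("age", "age_copy")),
                                     tab), "collinear")
})

test_that("a constant response yields permutation p of 1 on both sides", {
  tab <- sim_table(seed = 11)
  tab$y <- 3
  suppressWarnings(
    p <- node_label_permutation(model_spec("y", "age"), tab, n_perm = 50,
                                seed = 1))
  expect_equal(p$p_perm_left, c(1, 1))
  expect_equal(p$p_perm_right, c(1, 1))
  # +1 rule invariant
  expect_true(all(p$p_perm_left + p$p_perm_right >= 1))
})

test_that("permutation p-values are invariant to affine response rescaling", {
  tab <- sim_table(beta = c(age = 0.3), seed = 12)
  spec <- model_spec("y", c("age", "familiarity"))
  p1 <- node_label_permutation(spec, tab, n_perm = 200, seed = 5)
  tab2 <- tab
  tab2$y <- 3 * tab$y + 10
  p2 <- node_label_permutation(spec, tab2, n_perm = 200, seed = 5)
  slopes <- p1$term != "(Intercept)"
  expect_equal(p1$p_perm_left[slopes], p2$p_perm_left[slopes])
  expect_equal(p1$p_perm_right[slopes], p2$p_perm_right[slopes])
})

test_that("a strong simulated effect is detected by the right-side permutation p", {
  tab <- sim_table(n_id = 70, n_comp = 3, beta = c(age = 1), sd_eps = 1,
                   seed = 13)
  p <- node_label_permutation(model_spec("y", c("age", "familiarity")),
                              tab, n_perm = 200, seed = 6)
  expect_lte(p$p_perm_right[p$term == "age"], 0.01)
})
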