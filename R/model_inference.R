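# Mixed-effects regressions of centralities on socio-demographic
# predictors: ML fits via lme4, AICc all-subsets model averaging with
# relative variable importance, node-label permutation significance, VIF.

#' Specify a centrality regression model
#'
#' Gaussian linear mixed model of a (corrected) centrality, or a
#' between-composition centrality difference, on socio-demographic fixed
#' effects with a random intercept per individual.  Sex must not be used
#' in difference models (its levels are confounded with transfer choice
#' there); the specification enforces nothing, the pipeline does.
#'
#' @param response name of the response column.
#' @param fixed_effects character vector of predictor columns (at most 6).
#' @param random column holding the grouping id for the random intercept,
#'   default `"individual_id"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed_effects,
                       random = "individual_id") {
  stopifnot(is.character(response), length(response) == 1L)
  fixed_effects <- as.character(fixed_effects)
  if (length(fixed_effects) > 6L)
    .stop("at most 6 candidate fixed effects are supported (2^k model fits)")
  structure(list(response = response, fixed = fixed_effects,
                 random = random), class = "model_spec")
}

.aicc <- function(fm) {
  ll <- logLik(fm)
  k <- attr(ll, "df")
  n <- nobs(fm)
  if (n - k - 1 <= 0)
    .stop("AICc undefined: n (%d) too small for %d parameters", n, k)
  AIC(fm) + 2 * k * (k + 1) / (n - k - 1)
}

.check_spec_table <- function(spec, table) {
  miss <- setdiff(c(spec$response, spec$fixed, spec$random), names(table))
  if (length(miss))
    .stop("columns missing from the table: %s", paste(miss, collapse = ", "))
  invisible(TRUE)
}

.mixed_formula <- function(response, fixed, random) {
  rhs <- c(if (length(fixed)) fixed else "1",
           sprintf("(1 | %s)", random))
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a Gaussian mixed model of centrality
#'
#' Maximum-likelihood (not REML) fit so that AICc values are comparable
#' across fixed-effect subsets.  The random-intercept variance is allowed
#' to go to zero (e.g. one observation per individual), in which case the
#' fixed-effect estimates coincide with ordinary least squares.
#'
#' @param spec a [model_spec()].
#' @param table data frame with the response, predictors and grouping id.
#' @return A `fit_mixed` object: `model` (the lme4 fit), `coefficients`
#'   (term, estimate, std_error, z_value with `z = |estimate| / SE`),
#'   `logLik`, `aic`, `aicc`, `n`.
#' @export
fit_mixed <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  .check_spec_table(spec, table)
  if (nrow(table) < 2L) .stop("need at least 2 observations")
  if (length(spec$fixed)) {
    mm <- model.matrix(reformulate(spec$fixed), table)
    qr_ <- qr(mm)
    if (qr_$rank < ncol(mm)) {
      aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
      .stop("singular fixed-effect design; aliased column(s): %s",
            paste(aliased, collapse = ", "))
    }
  }
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fm <- suppressMessages(
    lme4::lmer(.mixed_formula(spec$response, spec$fixed, spec$random),
               data = table, REML = FALSE, control = ctrl))
  est <- lme4::fixef(fm)
  # a zero residual variance (e.g. constant response) breaks vcov; report
  # the standard errors as NA rather than failing
  V <- tryCatch(suppressWarnings(as.matrix(vcov(fm))),
                error = function(e) matrix(NA_real_, length(est),
                                           length(est)))
  se <- sqrt(diag(V))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      std_error = unname(se),
                      z_value = unname(abs(est) / se),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(model = fm, spec = spec, coefficients = coefs,
                 logLik = as.numeric(logLik(fm)), aic = AIC(fm),
                 aicc = .aicc(fm), n = nobs(fm)),
            class = "fit_mixed")
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing
#' predictor column k on all the others (factors are dummy-coded first).
#' Perfect collinearity is reported as `Inf`, never an error, so callers
#' can gate on it.
#'
#' @param table data frame.
#' @param terms predictor columns (at least 2).
#' @return Named numeric vector, one VIF per design-matrix column.
#' @export
compute_vif <- function(table, terms) {
  if (length(terms) < 2L) .stop("VIF needs at least 2 terms")
  mm <- model.matrix(reformulate(terms), table)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  vapply(seq_len(ncol(mm)), function(j) {
    fit <- lm.fit(cbind(1, mm[, -j, drop = FALSE]), mm[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((mm[, j] - mean(mm[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(mm))
}

#' All-subsets AICc multi-model inference
#'
#' Fits every subset of the candidate fixed effects (each model keeps the
#' intercept and the random intercept), ranks them by AICc, converts
#' AICc differences into Akaike weights `w_m = exp(-delta_m / 2) /
#' sum(...)`, and reports the relative variable importance of each term
#' (RVI: the summed weight of all models containing it).  "Best models"
#' are those within `delta_cut` AICc of the top model; term estimates are
#' model-averaged over the best models containing the term, with weights
#' renormalized (natural averaging).  Candidates are screened for
#' collinearity first: an infinite VIF aborts before any fitting.
#'
#' @param spec a [model_spec()] holding the full candidate set.
#' @param table data frame.
#' @param delta_cut AICc difference defining the best-model set, default 2.
#' @return An `inference_result`: `models` (terms, aicc, delta, weight,
#'   best), `rvi`, `averaged` (term, estimate, std_error, z_value), `vif`,
#'   and `fits` (the per-subset `fit_mixed` objects).
#' @export
all_subsets_inference <- function(spec, table, delta_cut = 2) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- spec$fixed
  if (length(terms) > 6L) .stop("at most 6 candidate terms")
  vif <- if (length(terms) >= 2L) compute_vif(table, terms) else NULL
  if (!is.null(vif) && any(!is.finite(vif)))
    .stop("perfectly collinear candidate predictors: %s",
          paste(names(vif)[!is.finite(vif)], collapse = ", "))

  subsets <- lapply(0:(2^length(terms) - 1L), function(mask)
    terms[bitwAnd(mask, bitwShiftL(1L, seq_along(terms) - 1L)) != 0L])
  fits <- lapply(subsets, function(sub)
    fit_mixed(model_spec(spec$response, sub, spec$random), table))
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- aicc - min(aicc)
  weight <- exp(-delta / 2); weight <- weight / sum(weight)
  models <- data.frame(
    model_id = seq_along(subsets) - 1L,
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)", ""),
    aicc = aicc, delta_aicc = delta, weight = weight,
    best = delta <= delta_cut, stringsAsFactors = FALSE)

  rvi <- vapply(terms, function(tm)
    sum(weight[vapply(subsets, function(s) tm %in% s, logical(1))]),
    numeric(1))

  # model-average coefficients over the best set (per design column)
  best_idx <- which(models$best)
  col_names <- unique(unlist(lapply(fits[best_idx], function(f)
    f$coefficients$term)))
  averaged <- do.call(rbind, lapply(col_names, function(cn) {
    has <- vapply(best_idx, function(i)
      cn %in% fits[[i]]$coefficients$term, logical(1))
    idx <- best_idx[has]
    w <- weight[idx] / sum(weight[idx])
    est <- vapply(seq_along(idx), function(k) {
      cf <- fits[[idx[k]]]$coefficients
      cf$estimate[cf$term == cn]
    }, numeric(1))
    se <- vapply(seq_along(idx), function(k) {
      cf <- fits[[idx[k]]]$coefficients
      cf$std_error[cf$term == cn]
    }, numeric(1))
    e <- sum(w * est)
    # unconditional SE across the averaged models
    s <- sqrt(sum(w * (se^2 + (est - e)^2)))
    data.frame(term = cn, estimate = e, std_error = s,
               z_value = abs(e) / s, stringsAsFactors = FALSE)
  }))
  rownames(averaged) <- NULL
  structure(list(models = models, rvi = rvi, averaged = averaged,
                 vif = vif, fits = fits, delta_cut = delta_cut,
                 spec = spec),
            class = "inference_result")
}

#' Node-label permutation significance for a mixed model
#'
#' Builds an empirical null for every coefficient by permuting the
#' response values across individuals (by default within each
#' composition, preserving composition-level structure) and refitting the
#' model.  For each term, `p_right = (#\{b* >= b\} + 1) / (n_perm + 1)` and
#' `p_left` analogously; under the +1 rule `p_left + p_right >= 1`.
#' Permutations whose refit fails are logged and redrawn, never silently
#' dropped.
#'
#' @param spec a [model_spec()].
#' @param table data frame; needs a `composition_id` column when
#'   `unit = "composition"`.
#' @param n_perm number of permutations (default 1000; below 100 a
#'   warning is raised).
#' @param seed optional integer seed.
#' @param unit `"composition"` (permute responses within composition) or
#'   `"table"` (permute the whole column).
#' @return Data frame (term, estimate, p_perm_left, p_perm_right) with
#'   attributes `n_perm`, `seed`, `n_refit_failures`.
#' @export
node_label_permutation <- function(spec, table, n_perm = 1000, seed = NULL,
                                   unit = c("composition", "table")) {
  unit <- match.arg(unit)
  if (n_perm < 100) .warn("n_perm < 100 gives a very coarse p-value resolution")
  fit0 <- fit_mixed(spec, table)
  b0 <- lme4::fixef(fit0$model)
  y <- table[[spec$response]]
  grp <- if (unit == "composition") {
    if (is.null(table$composition_id))
      .stop("unit = \"composition\" needs a composition_id column")
    table$composition_id
  } else rep(1L, nrow(table))
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(NA_real_, n_perm, length(b0),
              dimnames = list(NULL, names(b0)))
  failures <- 0L
  for (i in seq_len(n_perm)) {
    for (try in 1:10) {
      yp <- unsplit(lapply(split(y, grp), function(v)
        v[sample.int(length(v))]), grp)
      fm <- tryCatch(suppressMessages(lme4::refit(fit0$model, newresp = yp)),
                     error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fm)) break
      failures <- failures + 1L
    }
    if (is.null(fm)) .stop("permutation refit failed 10 times in a row")
    B[i, ] <- lme4::fixef(fm)
  }
  tol <- 1e-8 * (1 + abs(b0))
  p_right <- (colSums(sweep(B, 2, b0 - tol, `>=`)) + 1) / (n_perm + 1)
  p_left <- (colSums(sweep(B, 2, b0 + tol, `<=`)) + 1) / (n_perm + 1)
  out <- data.frame(term = names(b0), estimate = unname(b0),
                    p_perm_left = unname(p_left),
                    p_perm_right = unname(p_right),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n_refit_failures") <- failures
  out
}

#' @export
print.inference_result <- function(x, ...) {
  cat("AICc all-subsets inference:", nrow(x$models), "models;",
      sum(x$models$best), "within delta <=", x$delta_cut, "\n")
  cat("RVI:", paste(sprintf("%s=%.3f", names(x$rvi), x$rvi),
                    collapse = ", "), "\n")
  invisible(x)
}
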