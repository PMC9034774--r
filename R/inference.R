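#' Residualize one variable on another
#'
#' Ordinary least-squares residuals of `y_col` regressed on `x_col` with an
#' intercept, appended to the table as `<y_col>_resid`. Used to adjust
#' locus coeruleus CNR for the main effect of age before it enters the
#' moderated regressions, and optionally to adjust regional grey-matter
#' volumes for total grey matter.
#'
#' @param table data frame with at least 3 complete rows.
#' @param y_col,x_col column names (strings).
#' @return the input as a tibble with the residual column added (mean 0,
#'   orthogonal to `x_col`).
#' @examples
#' d <- tibble::tibble(age = 50:59, cnr = 5 - 0.02 * (50:59) + rnorm(10, 0, 0.1))
#' residualize(d, "cnr", "age")
#' @export
residualize <- function(table, y_col, x_col) {
  table <- tibble::as_tibble(table)
  y <- table[[y_col]]; x <- table[[x_col]]
  if (is.null(y) || is.null(x)) stop("column not found", call. = FALSE)
  ok <- stats::complete.cases(y, x)
  if (sum(ok) < 3) stop("need at least 3 complete rows", call. = FALSE)
  if (stats::sd(x[ok]) == 0) stop(x_col, " is constant; cannot residualize", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(y = y, x = x))
  res <- rep(NA_real_, nrow(table))
  res[ok] <- stats::residuals(fit)
  table[[paste0(y_col, "_resid")]] <- res
  table
}

vif_from_mm <- function(mm) {
  # drop the intercept; VIF_j = 1 / (1 - R^2 of column j on the others)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  if (ncol(mm) < 2) return(stats::setNames(rep(1, ncol(mm)), colnames(mm)))
  vapply(seq_len(ncol(mm)), function(j) {
    r2 <- summary(stats::lm(mm[, j] ~ mm[, -j]))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1)) |> stats::setNames(colnames(mm))
}

term_table <- function(coefs, df_resid) {
  tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, 1],
    std_error = coefs[, 2],
    statistic = coefs[, 3],
    df = df_resid,
    p_value = 2 * stats::pt(abs(coefs[, 3]), df_resid, lower.tail = FALSE),
    partial_eta2 = coefs[, 3]^2 / (coefs[, 3]^2 + df_resid)
  )
}

#' Moderated multiple regression with diagnostics
#'
#' Fits `outcome ~ focal * moderator + covariates` by ordinary least
#' squares, mean-centring the focal predictor and the moderator before
#' forming their product (to prevent collinearity between the interaction
#' and its constituents). Reports per-term coefficient, SE, t, residual df,
#' p and partial eta squared (`t^2 / (t^2 + df)`), plus variance inflation
#' factors, Cook's distances and the 4/n influence cutoff. A VIF above 10
#' triggers a multicollinearity warning; rank deficiency is an error naming
#' the collinear terms.
#'
#' @param table covariate data frame.
#' @param outcome,focal,moderator column names (strings).
#' @param covariates character vector of additional column names (binary
#'   covariates such as sex enter uncentred).
#' @return object of class `lc_regression`; see [tidy()]/[glance()]
#'   methods.
#' @export
fit_moderated_regression <- function(table, outcome, focal, moderator,
                                     covariates = character(0)) {
  table <- tibble::as_tibble(table)
  cols <- c(outcome, focal, moderator, covariates)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("column(s) not found: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- table[stats::complete.cases(table[cols]), cols]
  if (nrow(d) < length(cols) + 2) stop("too few complete rows", call. = FALSE)
  d$.focal_c <- d[[focal]] - mean(d[[focal]])
  d$.mod_c <- d[[moderator]] - mean(d[[moderator]])
  d$.inter <- d$.focal_c * d$.mod_c
  rhs <- c(".focal_c", ".mod_c", ".inter", covariates)
  fml <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  terms_tbl <- term_table(sm$coefficients, fit$df.residual)
  pretty <- c("(Intercept)" = "(Intercept)",
              stats::setNames(c(focal, moderator, paste0(focal, ":", moderator)),
                              c(".focal_c", ".mod_c", ".inter")))
  terms_tbl$term <- dplyr::coalesce(pretty[terms_tbl$term], terms_tbl$term)
  vif <- vif_from_mm(stats::model.matrix(fit))
  names(vif) <- dplyr::coalesce(pretty[names(vif)], names(vif))
  if (any(vif > 10)) {
    warning("variance inflation factor above 10 for: ",
            paste(names(vif)[vif > 10], collapse = ", "), call. = FALSE)
  }
  cooks <- stats::cooks.distance(fit)
  structure(list(
    fit = fit, terms = terms_tbl, r_squared = sm$r.squared,
    vif = vif, cooks = cooks, cook_cutoff = 4 / nrow(d),
    n = nrow(d), outcome = outcome, focal = focal, moderator = moderator,
    covariates = covariates, method = "ols"
  ), class = "lc_regression")
}

#' Robust (Huber M-estimation) refit of a moderated regression
#'
#' Re-fits the same centred moderated-regression design by iteratively
#' reweighted least squares with the Huber loss (tuning constant 1.345,
#' scale by median absolute deviation), iterated to a relative coefficient
#' change below 1e-8. Less sensitive to outlying observations than
#' ordinary least squares; used to confirm OLS conclusions.
#'
#' @inheritParams fit_moderated_regression
#' @return object of class `lc_regression` (method `"huber"`).
#' @export
robust_regression <- function(table, outcome, focal, moderator,
                              covariates = character(0)) {
  table <- tibble::as_tibble(table)
  cols <- c(outcome, focal, moderator, covariates)
  d <- table[stats::complete.cases(table[cols]), cols]
  if (nrow(d) < length(cols) + 2) stop("too few complete rows", call. = FALSE)
  d$.focal_c <- d[[focal]] - mean(d[[focal]])
  d$.mod_c <- d[[moderator]] - mean(d[[moderator]])
  d$.inter <- d$.focal_c * d$.mod_c
  rhs <- c(".focal_c", ".mod_c", ".inter", covariates)
  fml <- stats::reformulate(rhs, response = outcome)
  fit <- MASS::rlm(fml, data = d, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-8)
  if (!fit$converged) stop("robust regression did not converge", call. = FALSE)
  sm <- summary(fit)
  df_resid <- nrow(d) - length(stats::coef(fit))
  terms_tbl <- term_table(sm$coefficients, df_resid)
  pretty <- c("(Intercept)" = "(Intercept)",
              stats::setNames(c(focal, moderator, paste0(focal, ":", moderator)),
                              c(".focal_c", ".mod_c", ".inter")))
  terms_tbl$term <- dplyr::coalesce(pretty[terms_tbl$term], terms_tbl$term)
  structure(list(
    fit = fit, terms = terms_tbl, r_squared = NA_real_,
    vif = vif_from_mm(stats::model.matrix(fit)), cooks = NULL,
    cook_cutoff = 4 / nrow(d), n = nrow(d), outcome = outcome, focal = focal,
    moderator = moderator, covariates = covariates, method = "huber"
  ), class = "lc_regression")
}

# log of the JZS integrand for a linear model with p covariates and
# coefficient of determination R2 at sample size n; g-prior scale r.
# g ~ InverseGamma(1/2, n r^2 / 2) (Zellner-Siow).
log_jzs_integrand <- function(g, n, p, R2, r) {
  0.5 * log(n * r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - n * r^2 / (2 * g) +
    ((n - p - 1) / 2) * log1p(g) - ((n - 1) / 2) * log1p(g * (1 - R2))
}

# Bayes factor of a linear model with p covariates against the
# intercept-only model, by 1-d quadrature over g (substituting g = e^u).
jzs_bf_vs_intercept <- function(n, p, R2, r, rel_tol = 1e-10) {
  if (p == 0) return(list(bf = 1, err = 0))
  f <- function(u) exp(log_jzs_integrand(exp(u), n, p, R2, r) + u)
  q <- stats::integrate(f, -30, 30, rel.tol = rel_tol, abs.tol = 0,
                        subdivisions = 500L, stop.on.error = FALSE)
  if (q$message != "OK" || !is.finite(q$value) || q$value <= 0) {
    stop("JZS integral did not converge (", q$message, ")", call. = FALSE)
  }
  list(bf = q$value, err = q$abs.error)
}

#' Default Bayes factor for nested linear models (JZS g-prior)
#'
#' Evidence for a full linear model over a nested null model using the
#' Jeffreys-Zellner-Siow default prior: standardized effects receive a
#' Zellner g-prior with a Zellner-Siow (inverse-gamma) mixture over g,
#' integrated numerically in one dimension. Each model is compared with the
#' intercept-only model and the ratio of the two marginal likelihoods gives
#' the full-vs-null Bayes factor. The default prior scale is
#' `sqrt(2)/4` ("medium" for regression).
#'
#' @param table data frame.
#' @param outcome outcome column name.
#' @param full_terms character vector of predictor columns for the full
#'   model.
#' @param null_terms subset of `full_terms` for the null model (default:
#'   intercept only).
#' @param r prior scale on standardized effects.
#' @return list of class `bf_result`: `bf10`, `log_bf10`, `r`, `n`,
#'   `integration_error`.
#' @examples
#' d <- simulate_mediation_dataset(mediation_dgp(n = 60, seed = 3))
#' jzs_bf(d, "ssrt", c("age", "connectivity"), "age")
#' @export
jzs_bf <- function(table, outcome, full_terms, null_terms = character(0),
                   r = sqrt(2) / 4) {
  table <- tibble::as_tibble(table)
  if (!all(null_terms %in% full_terms)) {
    stop("null_terms must be a subset of full_terms", call. = FALSE)
  }
  cols <- unique(c(outcome, full_terms))
  d <- table[stats::complete.cases(table[cols]), cols]
  n <- nrow(d)
  if (n <= length(full_terms) + 1) stop("too few complete rows", call. = FALSE)
  r2_of <- function(terms) {
    if (!length(terms)) return(0)
    fml <- stats::reformulate(sprintf("`%s`", terms), response = sprintf("`%s`", outcome))
    summary(stats::lm(fml, data = d))$r.squared
  }
  full <- jzs_bf_vs_intercept(n, length(full_terms), r2_of(full_terms), r)
  null <- jzs_bf_vs_intercept(n, length(null_terms), r2_of(null_terms), r)
  structure(list(bf10 = full$bf / null$bf,
                 log_bf10 = log(full$bf) - log(null$bf),
                 r = r, n = n,
                 integration_error = full$err + null$err),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor (full vs null): BF10 = %.4g (prior scale %.4g, n = %d)\n",
              x$bf10, x$r, x$n))
  invisible(x)
}

#' Subregion model comparison for the CNR-by-age interaction
#'
#' For each locus coeruleus subregion (rostral, middle, caudal), compares a
#' linear model containing that subregion's age-residualized CNR, age,
#' their (centred) interaction and the shared covariates against the null
#' model without the interaction term. Used in place of a single
#' multi-subregion regression when the joint interaction terms are too
#' collinear (VIF > 10).
#'
#' @param table covariate table containing `<prefix>_rostral`,
#'   `<prefix>_middle`, `<prefix>_caudal` columns.
#' @param outcome outcome column (default `"ssrt"`).
#' @param prefix subregion column prefix (default `"cnr"`, giving
#'   `cnr_rostral` etc.).
#' @param moderator moderator column (default `"age"`).
#' @param covariates shared covariate columns present in both models.
#' @param r prior scale passed to [jzs_bf()].
#' @return tibble with one row per subregion: `subregion`, `bf10`,
#'   `log_bf10`.
#' @export
subregion_model_comparison <- function(table, outcome = "ssrt", prefix = "cnr",
                                       moderator = "age",
                                       covariates = character(0),
                                       r = sqrt(2) / 4) {
  table <- tibble::as_tibble(table)
  subs <- c("rostral", "middle", "caudal")
  purrr::map_dfr(subs, function(s) {
    col <- paste0(prefix, "_", s)
    if (!col %in% names(table)) stop("missing column ", col, call. = FALSE)
    d <- table
    d$.focal_c <- d[[col]] - mean(d[[col]], na.rm = TRUE)
    d$.mod_c <- d[[moderator]] - mean(d[[moderator]], na.rm = TRUE)
    d$.inter <- d$.focal_c * d$.mod_c
    full <- c(".focal_c", ".mod_c", ".inter", covariates)
    null <- c(".focal_c", ".mod_c", covariates)
    res <- jzs_bf(d, outcome, full, null, r = r)
    tibble::tibble(subregion = s, bf10 = res$bf10, log_bf10 = res$log_bf10)
  })
}

# one-sample JZS t-test Bayes factor (Zellner-Siow Cauchy prior, scale r)
jzs_ttest_bf <- function(t, n, r) {
  nu <- n - 1
  log_post <- function(u) {
    g <- exp(u)
    -0.5 * log1p(n * g) - ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) +
      0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g) + u
  }
  num <- stats::integrate(function(u) exp(log_post(u)), -30, 30,
                          rel.tol = 1e-10, subdivisions = 500L,
                          stop.on.error = FALSE)
  if (num$message != "OK" || !is.finite(num$value)) {
    stop("JZS t-test integral did not converge", call. = FALSE)
  }
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num$value / den
}

#' Paired Bayesian t test
#'
#' Paired t statistic plus a default one-sample Jeffreys-Zellner-Siow Bayes
#' factor on the pairwise differences (prior scale `sqrt(2)/2`). Used to
#' compare signal-to-noise ratios between locus coeruleus subregions.
#'
#' @param x,y equal-length paired samples (n >= 3).
#' @param r Cauchy prior scale on the standardized effect.
#' @return list with `t`, `df`, `p_value`, `mean_diff`, `ci` (95% t
#'   interval for the mean difference) and `bf` (a `bf_result`).
#' @export
paired_bayes_ttest <- function(x, y, r = sqrt(2) / 2) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  d <- d[stats::complete.cases(d)]
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(d) == 0) stop("zero-variance differences", call. = FALSE)
  tt <- stats::t.test(d)
  t <- unname(tt$statistic)
  bf10 <- jzs_ttest_bf(t, n, r)
  list(t = t, df = n - 1, p_value = tt$p.value, mean_diff = mean(d),
       ci = unname(tt$conf.int),
       bf = structure(list(bf10 = bf10, log_bf10 = log(bf10), r = r, n = n,
                           integration_error = NA_real_),
                      class = "bf_result"))
}

#' Achieved power of a regression F test
#'
#' Power of the test of `df_num` coefficient(s) in a multiple linear
#' regression with `n_predictors` predictors at sample size `n`, for effect
#' size Cohen's f2, via the noncentral F distribution with noncentrality
#' `f2 * n`:
#' \deqn{power = P\{F(df_{num}, n - k - 1; \lambda = f^2 n) > F_{crit}(\alpha)\}}
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param n sample size (> `n_predictors + 1`).
#' @param n_predictors total number of predictors in the model.
#' @param df_num numerator degrees of freedom of the tested term(s).
#' @param alpha significance level.
#' @return achieved power in `[0, 1]`.
#' @examples
#' regression_power(f2 = 0.15, n = 63, n_predictors = 5) # about 0.86
#' @export
regression_power <- function(f2, n, n_predictors, df_num = 1, alpha = 0.05) {
  if (f2 <= 0) stop("f2 must be > 0", call. = FALSE)
  if (n <= n_predictors + 1) stop("n must exceed n_predictors + 1", call. = FALSE)
  df_den <- n - n_predictors - 1
  lambda <- f2 * n
  fcrit <- stats::qf(1 - alpha, df_num, df_den)
  stats::pf(fcrit, df_num, df_den, ncp = lambda, lower.tail = FALSE)
}
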