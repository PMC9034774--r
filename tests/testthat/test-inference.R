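test_that("residualization gives mean-zero residuals orthogonal to x", {
  d <- tibble::tibble(age = seq(50, 88, length.out = 20))
  withr::with_seed(71, {
    d$cnr <- 5 - 0.02 * d$age + rnorm(20, 0, 0.3)
  })
  out <- residualize(d, "cnr", "age")
  r <- out$cnr_resid
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(sum(r * d$age)), 1e-8)
  # exact linear relation leaves zero residuals
  d2 <- tibble::tibble(x = 1:10, y = 3 + 2 * (1:10))
  expect_lt(max(abs(residualize(d2, "y", "x")$y_resid)), 1e-10)
  # hat-matrix oracle
  X <- cbind(1, d$age)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(r, as.vector((diag(20) - H) %*% d$cnr), tolerance = 1e-10)
  expect_error(residualize(tibble::tibble(x = rep(1, 5), y = 1:5), "y", "x"),
               "constant")
})

sim_reg_table <- function(n = 62, beta_inter = 0.01, sd_y = 0, seed = 72) {
  withr::with_seed(seed, {
    x <- rnorm(n); w <- runif(n, 50, 88); sex <- rbinom(n, 1, 0.5)
    xc <- x - mean(x); wc <- w - mean(w)
    y <- 0.25 - 0.03 * xc + 0.002 * wc + beta_inter * xc * wc + 0.01 * sex +
      rnorm(n, 0, sd_y)
    tibble::tibble(ssrt = y, cnr = x, age = w, sex = sex)
  })
}

test_that("moderated regression recovers noiseless coefficients exactly", {
  tab <- sim_reg_table(sd_y = 0)
  # the zero-noise design triggers lm's perfect-fit warning by construction
  fit <- suppressWarnings(fit_moderated_regression(tab, "ssrt", "cnr", "age", "sex"))
  est <- fit$terms$estimate[fit$terms$term == "cnr:age"]
  expect_equal(unname(est), 0.01, tolerance = 1e-8)
  expect_equal(fit$cook_cutoff, 4 / 62)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("per-term statistics satisfy the partial eta-squared identity", {
  tab <- sim_reg_table(sd_y = 0.05)
  fit <- fit_moderated_regression(tab, "ssrt", "cnr", "age", "sex")
  td <- tidy(fit)
  expect_equal(td$partial_eta2, td$statistic^2 / (td$statistic^2 + td$df),
               tolerance = 1e-12)
  expect_true(all(td$partial_eta2 >= 0 & td$partial_eta2 <= 1))
  g <- glance(fit)
  expect_equal(g$n, 62L, ignore_attr = TRUE)
  expect_true(g$max_cooks >= 0)
})

test_that("Cook's distances match leave-one-out refits", {
  tab <- sim_reg_table(n = 15, sd_y = 0.04, seed = 73)
  fit <- fit_moderated_regression(tab, "ssrt", "cnr", "age", "sex")
  lmfit <- fit$fit
  X <- model.matrix(lmfit)
  p <- ncol(X)
  s2 <- sum(residuals(lmfit)^2) / lmfit$df.residual
  yhat <- fitted(lmfit)
  d_loo <- vapply(1:15, function(i) {
    refit <- lm.fit(X[-i, , drop = FALSE], model.response(model.frame(lmfit))[-i])
    yhat_i <- as.vector(X %*% refit$coefficients)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
  expect_equal(unname(fit$cooks), d_loo, tolerance = 1e-8)
})

test_that("collinearity is diagnosed", {
  tab <- sim_reg_table(sd_y = 0.05)
  tab$cnr2 <- tab$cnr * 2
  expect_error(
    suppressWarnings(fit_moderated_regression(tab, "ssrt", "cnr", "age",
                                              c("sex", "cnr2"))), "collinear")
  tab$cnr_near <- tab$cnr + rnorm(62, 0, 1e-4)
  expect_warning(fit_moderated_regression(tab, "ssrt", "cnr", "age",
                                          c("sex", "cnr_near")),
                 "inflation")
})

test_that("the JZS Bayes factor is exact against dense-grid integration", {
  d <- simulate_mediation_dataset(mediation_dgp(n = 40, seed = 74))
  bf <- jzs_bf(d, "ssrt", c("age", "connectivity"), "age")
  r2_full <- summary(lm(ssrt ~ age + connectivity, d))$r.squared
  r2_null <- summary(lm(ssrt ~ age, d))$r.squared
  trap <- function(R2, p, n = 40, r = sqrt(2) / 4) {
    u <- seq(-25, 25, length.out = 2e5)
    g <- exp(u)
    iv <- exp(0.5 * log(n * r^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
                n * r^2 / (2 * g) + ((n - p - 1) / 2) * log1p(g) -
                ((n - 1) / 2) * log1p(g * (1 - R2)) + u)
    sum((iv[-1] + iv[-length(iv)]) / 2 * diff(u))
  }
  expect_equal(bf$bf10, trap(r2_full, 2) / trap(r2_null, 1), tolerance = 0.01)
})

test_that("JZS Bayes factors behave sensibly at the extremes", {
  d <- simulate_mediation_dataset(mediation_dgp(n = 60, seed = 75))
  # identical full and null models: no evidence either way
  same <- jzs_bf(d, "ssrt", c("age", "sex"), c("age", "sex"))
  expect_equal(same$bf10, 1, tolerance = 1e-9)
  # strong standardized effect: decisive evidence
  withr::with_seed(76, {
    x <- rnorm(60)
    strong <- tibble::tibble(x = x, y = 0.8 * x + rnorm(60, 0, 0.6))
  })
  expect_gt(jzs_bf(strong, "y", "x")$bf10, 3)
  # null effect: evidence favours the null in the median over seeds
  bfs <- vapply(1:11, function(s) {
    withr::with_seed(90 + s, {
      nulltab <- tibble::tibble(x = rnorm(60), y = rnorm(60))
    })
    jzs_bf(nulltab, "y", "x")$bf10
  }, numeric(1))
  expect_lt(median(bfs), 1)
  expect_error(jzs_bf(d, "ssrt", "age", "sex"), "subset")
})

test_that("subregion comparison singles out the driving interaction", {
  gen <- function(seed, b_rost = -0.004) {
    withr::with_seed(seed, {
      n <- 60
      w <- runif(n, 50, 88); wc <- w - mean(w)
      cr <- rnorm(n); cm <- rnorm(n); cc <- rnorm(n)
      y <- 0.25 + b_rost * cr * wc + rnorm(n, 0, 0.05)
      tibble::tibble(ssrt = y, age = w, cnr_rostral = cr, cnr_middle = cm,
                     cnr_caudal = cc)
    })
  }
  wins <- vapply(1:20, function(s) {
    res <- subregion_model_comparison(gen(s))
    res$subregion[which.max(res$bf10)] == "rostral"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
  # all-null generator: no strong evidence anywhere in the median
  null_bfs <- vapply(1:11, function(s) {
    max(subregion_model_comparison(gen(100 + s, b_rost = 0))$bf10)
  }, numeric(1))
  expect_lt(median(null_bfs), 3)
  # relabeling symmetry: swapping columns swaps results
  tab <- gen(5)
  res1 <- subregion_model_comparison(tab)
  tab2 <- dplyr::rename(tab, cnr_rostral = "cnr_caudal", cnr_caudal = "cnr_rostral")
  res2 <- subregion_model_comparison(tab2)
  expect_equal(res1$bf10[res1$subregion == "rostral"],
               res2$bf10[res2$subregion == "caudal"], tolerance = 1e-9)
})

test_that("robust regression matches least squares on clean data", {
  tab <- sim_reg_table(n = 40, sd_y = 1e-4, seed = 77)
  ols <- fit_moderated_regression(tab, "ssrt", "cnr", "age", "sex")
  rob <- robust_regression(tab, "ssrt", "cnr", "age", "sex")
  expect_lt(max(abs(rob$terms$estimate - ols$terms$estimate)), 1e-4)
  expect_equal(rob$method, "huber")
})

test_that("robust regression resists a gross outlier", {
  tab <- sim_reg_table(n = 30, sd_y = 0.03, seed = 78)
  tab$ssrt[1] <- tab$ssrt[1] + 5
  ols <- fit_moderated_regression(tab, "ssrt", "cnr", "age", "sex")
  rob <- robust_regression(tab, "ssrt", "cnr", "age", "sex")
  true_b <- 0.01
  err_ols <- abs(ols$terms$estimate[ols$terms$term == "cnr:age"] - true_b)
  err_rob <- abs(rob$terms$estimate[rob$terms$term == "cnr:age"] - true_b)
  expect_lt(err_rob, err_ols)
})

test_that("the robust fit is a Huber IRLS fixed point", {
  tab <- sim_reg_table(n = 30, sd_y = 0.03, seed = 79)
  tab$ssrt[5] <- tab$ssrt[5] + 1
  rob <- robust_regression(tab, "ssrt", "cnr", "age", "sex")
  r <- residuals(rob$fit)
  s <- rob$fit$s
  w <- pmin(1, 1.345 * s / abs(r))
  X <- model.matrix(rob$fit)
  y <- r + fitted(rob$fit)
  beta_w <- solve(crossprod(X, w * X), crossprod(X, w * y))
  expect_equal(unname(coef(rob$fit)), as.vector(beta_w), tolerance = 1e-6)
})

test_that("paired Bayesian t test matches its quadrature oracle", {
  withr::with_seed(80, {
    x <- rnorm(30, 1, 1)
    y <- rnorm(30, 0, 1)
  })
  res <- paired_bayes_ttest(x, y)
  t <- res$t; n <- 30; nu <- n - 1; r <- sqrt(2) / 2
  u <- seq(-25, 25, length.out = 2e5)
  g <- exp(u)
  iv <- exp(-0.5 * log1p(n * g) - ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) +
              0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g) + u)
  num <- sum((iv[-1] + iv[-length(iv)]) / 2 * diff(u))
  oracle <- num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  expect_equal(res$bf$bf10, oracle, tolerance = 0.01)
})

test_that("paired test direction and degenerate input behave correctly", {
  withr::with_seed(81, {
    base <- rnorm(30)
    shifted <- base + 2 + rnorm(30, 0, 1)   # standardized shift around 2
    matched <- rnorm(30)
    matched2 <- matched + rnorm(30, 0, 1)   # equal means
  })
  expect_gt(paired_bayes_ttest(shifted, base)$bf$bf10, 10)
  expect_lt(paired_bayes_ttest(matched2, matched)$bf$bf10, 1)
  expect_error(paired_bayes_ttest(1:5, 1:5), "variance")
  expect_error(paired_bayes_ttest(1:4, 1:5), "equal length")
})

test_that("regression power follows the noncentral F distribution", {
  expect_equal(regression_power(0.15, 63, 5), 0.8559, tolerance = 1e-3)
  expect_equal(regression_power(0.15, 63, 5, alpha = 1), 1)
  expect_error(regression_power(0.15, 6, 5), "exceed")
  expect_error(regression_power(0, 63, 5), "f2")
  # monotone in effect size and sample size
  f2s <- c(0.05, 0.1, 0.15, 0.25)
  expect_true(all(diff(vapply(f2s, regression_power, numeric(1), n = 63,
                              n_predictors = 5)) > 0))
  ns <- c(30, 50, 70, 100)
  expect_true(all(diff(vapply(ns, function(n) regression_power(0.15, n, 5),
                              numeric(1))) > 0))
})

test_that("analytic power matches Monte-Carlo simulation of the F test", {
  # simulate the regression t/F test on a fixed design calibrated so the
  # tested coefficient's noncentrality is exactly f2 * n
  n <- 63; k <- 5; f2 <- 0.15
  beta <- sqrt(f2)
  reps <- 20000
  withr::with_seed(82, {
    X <- matrix(rnorm(n * k), n, k)
    # orthogonalize the tested column against the rest and scale its
    # sum of squares to n, so lambda = beta^2 * n holds exactly
    Z <- cbind(1, X[, -1])
    M <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
    x1 <- as.vector(M %*% X[, 1])
    X[, 1] <- x1 * sqrt(n) / sqrt(sum(x1^2))
    Xf <- cbind(1, X)
    XtXinv <- solve(crossprod(Xf))
    crit <- qt(0.975, n - k - 1)
    rej <- vapply(seq_len(reps), function(i) {
      y <- beta * X[, 1] + rnorm(n)
      cf <- XtXinv %*% crossprod(Xf, y)
      res <- y - Xf %*% cf
      s2 <- sum(res^2) / (n - k - 1)
      tstat <- cf[2] / sqrt(s2 * XtXinv[2, 2])
      abs(tstat) > crit
    }, logical(1))
  })
  power_mc <- mean(rej)
  power_an <- regression_power(f2, n, k)
  se <- sqrt(power_an * (1 - power_an) / reps)
  expect_lt(abs(power_mc - power_an), 3 * se)
})
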