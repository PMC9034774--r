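test_that("Gelman-Rubin statistic matches the hand-computed variance ratio", {
  # 2 chains x 10 draws toy array
  x <- cbind(c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2),
             c(4, 5, 6, 7, 8, 9, 8, 7, 6, 5))
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  expected <- sqrt(((n - 1) / n * W + B_over_n) / W)
  stopifnot(expected > 1)
  arr <- array(t(x), c(m, n, 1))
  got <- compute_rhat(arr)
  expect_equal(got$rhat, expected, tolerance = 1e-12)
})

test_that("R-hat flags identical and disjoint chains correctly", {
  same <- array(rep(seq(0, 1, length.out = 50), each = 3), c(3, 50, 1))
  expect_equal(compute_rhat(same)$rhat, 1, tolerance = 1e-12)
  withr::with_seed(51, {
    disjoint <- array(c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1)), c(2, 100, 1))
    disjoint[1, , 1] <- rnorm(100, 0, 0.1)
    disjoint[2, , 1] <- rnorm(100, 10, 0.1)
  })
  expect_gt(compute_rhat(disjoint)$rhat, 10)
  expect_error(compute_rhat(array(1:10, c(1, 10, 1))), "2 chains")
})

# a minimal synthetic fit object for testing the derived-posterior layer
fake_fit <- function(draws_mu, draws_tau) {
  K <- length(draws_mu)
  part <- array(0.2, c(2, K, 1, 11),
                dimnames = list(NULL, NULL, "p01", lcsst:::race_param_names()))
  part[, , 1, "mu_stop"] <- matrix(draws_mu, 2, K, byrow = TRUE)
  part[, , 1, "tau_stop"] <- matrix(draws_tau, 2, K, byrow = TRUE)
  part[, , 1, "mu_go_match"] <- 0.45
  part[, , 1, "tau_go_match"] <- 0.10
  group <- array(0.1, c(2, K, 22),
                 dimnames = list(NULL, NULL, lcsst:::group_param_names()))
  structure(list(participant = part, group = group,
                 participants = "p01", rhat_group = rep(1, 22),
                 converged = TRUE, burn_iterations = 0, rounds = 1),
            class = "sst_fit")
}

test_that("derived outcomes sum the stop racer's mean per draw", {
  f <- fake_fit(0.1, 0.061)
  der <- derive_outcomes(f)
  expect_equal(unique(as.vector(der$ssrt_draws)), 0.161)
  s <- der$summary[der$summary$measure == "ssrt", ]
  # degenerate posterior gives zero-width intervals
  expect_equal(s$q025, s$q975)
  expect_equal(s$median, 0.161)
  expect_equal(unique(as.vector(der$go_rt_draws)), 0.55)
})

test_that("interval endpoints match direct quantiles of the flattened draws", {
  withr::with_seed(52, {
    mus <- runif(200, 0.08, 0.2)
    taus <- runif(200, 0.02, 0.1)
  })
  f <- fake_fit(mus, taus)
  der <- derive_outcomes(f)
  draws <- rep(mus + taus, each = 1)
  draws2 <- as.vector(rbind(mus + taus, mus + taus))  # both chains identical
  s <- der$summary[der$summary$measure == "ssrt", ]
  expect_equal(s$median, unname(quantile(draws2, 0.5)))
  expect_equal(s$q17, unname(quantile(draws2, 0.17)))
  expect_equal(s$q83, unname(quantile(draws2, 0.83)))
  expect_equal(s$q025, unname(quantile(draws2, 0.025)))
  expect_equal(s$q975, unname(quantile(draws2, 0.975)))
})

test_that("fit configuration enforces sampler validity", {
  expect_error(fit_config(n_chains = 10), "twice")
  expect_error(fit_config(thin = 0), "thin")
  expect_error(fit_config(migration_prob = 2), "probability")
  cfg <- fit_config()
  expect_equal(cfg$n_chains, 33)
  expect_equal(cfg$thin, 10)
  expect_equal(cfg$migration_prob, 0.05)
  expect_equal(cfg$n_keep, 500)
})

test_that("a small hierarchical fit produces valid, reproducible draws", {
  design <- make_session_design(100, 30, 10, seed = 53)
  cohort <- simulate_cohort(group_hyperparams(), 3, design,
                            staircase_config(), seed = 54)
  cfg <- fit_config(n_chains = 22, thin = 1, n_keep = 40, burn_max = 150,
                    burn_check = 75, max_rounds = 0, seed = 55)
  fit1 <- suppressWarnings(fit_hierarchical(cohort$trials, cfg))
  expect_s3_class(fit1, "sst_fit")
  expect_equal(dim(fit1$group), c(22, 40, 22))
  expect_equal(dim(fit1$participant)[3], 3)
  # type invariants: positive ex-Gaussian draws, probabilities in [0, 1]
  pos <- fit1$participant[, , , 1:9]
  expect_true(all(pos > 0))
  probs <- pnorm(fit1$participant[, , , 10:11])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(fit1$group[, , 12:22] > 0))
  # derived SSRT positive for every draw
  expect_true(all(derive_outcomes(fit1)$ssrt_draws > 0))
  # seeded reproducibility
  fit2 <- suppressWarnings(fit_hierarchical(cohort$trials, cfg))
  expect_identical(fit1$group, fit2$group)
  # too few participants is an error
  one <- cohort$trials[cohort$trials$participant_id == "p01", ]
  expect_error(fit_hierarchical(one, cfg), "participants")
})

test_that("posterior predictive report is coherent", {
  design <- make_session_design(60, 20, 6, seed = 56)
  cohort <- simulate_cohort(group_hyperparams(), 2, design,
                            staircase_config(), seed = 57)
  cfg <- fit_config(n_chains = 22, thin = 1, n_keep = 20, burn_max = 60,
                    burn_check = 60, max_rounds = 0, seed = 58)
  fit <- suppressWarnings(fit_hierarchical(cohort$trials, cfg, qc = FALSE))
  ppc <- posterior_predictive(fit, design, staircase_config(),
                              n_sim_participants = 20, seed = 59)
  expect_true(all(ppc$pred_lo <= ppc$pred_hi, na.rm = TRUE))
  expect_true(all(c("prop_response", "accuracy", "median_rt") %in% ppc$statistic))
  # per-table response proportions sum to one within each trial type
  one <- lcsst:::ppc_stats(cohort$trials[cohort$trials$participant_id == "p01", ])
  sums <- tapply(one$value[one$statistic == "prop_response"],
                 one$trial_type[one$statistic == "prop_response"], sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_error(posterior_predictive(fit, design[0, ], staircase_config()),
               "empty")
})
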