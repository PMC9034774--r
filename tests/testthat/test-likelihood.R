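test_that("degenerate failure probabilities give forced outcomes", {
  p_gf1 <- std_params(p_gf = 1)
  omission <- tibble::tibble(trial_type = "go", direction = "left",
                             ssd_s = NA_real_, response = NA_character_,
                             rt_s = NA_real_)
  expect_equal(loglik_trial(omission, p_gf1), 0)      # probability one
  p_tf1 <- std_params(p_tf = 1)
  succ <- stop_trial_row(0.2)
  expect_identical(loglik_trial(succ, p_tf1), -Inf)   # impossible outcome
  # with a go-failure route open, the successful stop keeps that mass
  p_both <- std_params(p_tf = 1, p_gf = 0.3)
  expect_equal(loglik_trial(succ, p_both), log(0.3))
  expect_error(loglik_trial(dplyr::mutate(go_trial_row(0.5), ssd_s = 0.2),
                            std_params()), "SSD")
})

test_that("trial likelihood integrates to one over the outcome space", {
  withr::with_seed(41, {
    for (k in 1:4) {
      p <- race_model_params(
        go_match = c(runif(1, 0.35, 0.55), runif(1, 0.04, 0.1), runif(1, 0.05, 0.15)),
        go_mismatch = c(runif(1, 0.5, 0.9), runif(1, 0.05, 0.15), runif(1, 0.1, 0.3)),
        stop = c(runif(1, 0.1, 0.25), runif(1, 0.02, 0.05), runif(1, 0.03, 0.08)),
        p_tf = runif(1, 0, 0.3), p_gf = runif(1, 0, 0.1))
      dens <- function(t, resp, type, ssd) {
        vapply(t, function(tt) {
          tr <- tibble::tibble(trial_type = type, direction = "left",
                               ssd_s = ssd, response = resp, rt_s = tt)
          exp(loglik_trial(tr, p))
        }, numeric(1))
      }
      # go trial: both response densities plus the omission atom
      total_go <- stats::integrate(dens, 0, 6, resp = "left", type = "go",
                                   ssd = NA_real_, rel.tol = 1e-9)$value +
        stats::integrate(dens, 0, 6, resp = "right", type = "go",
                         ssd = NA_real_, rel.tol = 1e-9)$value + p$p_gf
      expect_lt(abs(total_go - 1), 1e-4)
      # stop trial: response densities plus the successful-stop atom
      ssd <- runif(1, 0.05, 0.4)
      succ <- tibble::tibble(trial_type = "stop", direction = "left",
                             ssd_s = ssd, response = NA_character_,
                             rt_s = NA_real_)
      total_stop <- stats::integrate(dens, 0, 6, resp = "left", type = "stop",
                                     ssd = ssd, rel.tol = 1e-9)$value +
        stats::integrate(dens, 0, 6, resp = "right", type = "stop",
                         ssd = ssd, rel.tol = 1e-9)$value +
        exp(loglik_trial(succ, p))
      expect_lt(abs(total_stop - 1), 1e-4)
    }
  })
})

test_that("stop-success probability has the right limits and monotonicity", {
  fast_stop <- race_model_params(c(0.8, 0.1, 0.1), c(0.9, 0.1, 0.1),
                                 c(0.05, 0.005, 0.005))
  expect_gt(stop_success_probability(fast_stop, 0), 0.999)
  expect_lt(stop_success_probability(std_params(), 5), 1e-6)
  grid <- seq(0, 1, by = 0.05)
  ps <- stop_success_probability(std_params(), grid)
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(stop_success_probability(std_params(), -0.1), "ssd")
})

test_that("stop-success probability matches a Monte-Carlo race", {
  p <- race_model_params(c(0.5, 0.1, 0.1), c(0.6, 0.1, 0.1),
                         c(0.2, 0.03, 0.05))
  ssd <- 0.25
  n <- 4e5
  withr::with_seed(43, {
    t_stop <- ssd + rnorm(n, 0.2, 0.03) + rexp(n, 1 / 0.05)
    t_go <- pmin(rnorm(n, 0.5, 0.1) + rexp(n, 1 / 0.1),
                 rnorm(n, 0.6, 0.1) + rexp(n, 1 / 0.1))
  })
  phat <- mean(t_stop < t_go)
  ptrue <- stop_success_probability(p, ssd)
  expect_lt(abs(phat - ptrue), 3 * sqrt(ptrue * (1 - ptrue) / n))
})

test_that("table likelihood agrees with the per-trial reference", {
  p <- std_params(p_tf = 0.1, p_gf = 0.03)
  d <- make_session_design(60, 20, 8, seed = 44)
  tt <- simulate_participant(p, d, staircase_config(), seed = 45)
  ref <- sum(vapply(seq_len(nrow(tt)), function(i) loglik_trial(tt[i, ], p),
                    numeric(1)))
  expect_equal(loglik_table(tt, p), ref, tolerance = 1e-5)
})

test_that("trigger failures raise the simulated response rate on stop trials", {
  d <- make_session_design(0, 3000, 0, seed = 46)
  sc <- staircase_config(initial_ssd = 0.2, step = 0)
  r_lo <- mean(!is.na(simulate_participant(std_params(p_tf = 0), d, sc,
                                           seed = 47)$response))
  r_hi <- mean(!is.na(simulate_participant(std_params(p_tf = 0.3), d, sc,
                                           seed = 47)$response))
  expect_gt(r_hi, r_lo)
})
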