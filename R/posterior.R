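#' Derived posterior outcomes: SSRT and go RT
#'
#' The stop-signal reaction time (SSRT) is the mean of the stop racer's
#' ex-Gaussian finish-time distribution, `mu_stop + tau_stop`, computed for
#' every retained MCMC draw to give a posterior distribution; the posterior
#' of the mean go RT is `mu_go_match + tau_go_match` in the same way.
#' Summaries report the median with 66% and 95% quantile intervals.
#'
#' @param fit an `sst_fit` from [fit_hierarchical()].
#' @return object of class `sst_derived`: list with `ssrt_draws` and
#'   `go_rt_draws` (draw x participant matrices), `summary` (tibble: one row
#'   per participant and measure with `median`, `q17`, `q83`, `q025`,
#'   `q975`) and `group_summary` (same summaries for the group-location
#'   sums).
#' @export
derive_outcomes <- function(fit) {
  stopifnot(inherits(fit, "sst_fit"))
  pa <- fit$participant
  flatten <- function(p1, p2) {
    d <- dim(pa)
    m <- pa[, , , p1, drop = FALSE] + pa[, , , p2, drop = FALSE]
    matrix(m, d[1] * d[2], d[3], dimnames = list(NULL, fit$participants))
  }
  ssrt <- flatten("mu_stop", "tau_stop")
  gort <- flatten("mu_go_match", "tau_go_match")
  qi <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.17, 0.83, 0.025, 0.975), names = FALSE)
    tibble::tibble(median = q[1], q17 = q[2], q83 = q[3], q025 = q[4], q975 = q[5])
  }
  per_part <- function(mat, measure) {
    purrr::map_dfr(colnames(mat), function(id) {
      dplyr::mutate(qi(mat[, id]), participant_id = id, measure = measure,
                    .before = 1)
    })
  }
  summary_tbl <- dplyr::bind_rows(per_part(ssrt, "ssrt"), per_part(gort, "go_rt"))
  ga <- fit$group
  g_ssrt <- as.vector(ga[, , "mu_stop_loc"] + ga[, , "tau_stop_loc"])
  g_gort <- as.vector(ga[, , "mu_go_match_loc"] + ga[, , "tau_go_match_loc"])
  group_summary <- dplyr::bind_rows(
    dplyr::mutate(qi(g_ssrt), measure = "ssrt", .before = 1),
    dplyr::mutate(qi(g_gort), measure = "go_rt", .before = 1)
  )
  structure(list(ssrt_draws = ssrt, go_rt_draws = gort,
                 summary = summary_tbl, group_summary = group_summary),
            class = "sst_derived")
}

# summary statistics of one trial table used by the posterior predictive
# check: per trial type, response proportions (left/right/none), choice
# accuracy among responses, and median RT per response side
ppc_stats <- function(trials) {
  trials <- tibble::as_tibble(trials)
  trials$resp_cat <- ifelse(is.na(trials$response), "none", trials$response)
  # fold no-go into stop: both are stop-signal trials for scoring
  trials$type2 <- ifelse(trials$trial_type == "go", "go", "stop")
  props <- trials |>
    dplyr::count(.data$type2, .data$resp_cat) |>
    dplyr::group_by(.data$type2) |>
    dplyr::mutate(value = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::transmute(trial_type = .data$type2, statistic = "prop_response",
                     response = .data$resp_cat, value = .data$value)
  acc <- trials |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::group_by(.data$type2) |>
    dplyr::summarise(value = mean(.data$response == .data$direction),
                     .groups = "drop") |>
    dplyr::transmute(trial_type = .data$type2, statistic = "accuracy",
                     response = "any", value = .data$value)
  med <- trials |>
    dplyr::filter(!is.na(.data$rt_s)) |>
    dplyr::group_by(.data$type2, .data$resp_cat) |>
    dplyr::summarise(value = stats::median(.data$rt_s), .groups = "drop") |>
    dplyr::transmute(trial_type = .data$type2, statistic = "median_rt",
                     response = .data$resp_cat, value = .data$value)
  dplyr::bind_rows(props, acc, med)
}

#' Posterior predictive check of the fitted race model
#'
#' Simulates synthetic participants from the joint posterior (a random
#' retained draw of the group-level parameters generates each simulated
#' participant's parameters, which are run through
#' [simulate_participant()]), then compares observed summary statistics to
#' the predictive distribution: per trial type (go; stop, with no-go folded
#' in) and response category, the response proportions, choice accuracy and
#' median RTs, with the predictive median and 95% quantile interval over
#' simulated participants. Observed values are medians across the fitted
#' participants.
#'
#' @param fit an `sst_fit`.
#' @param design session design for the simulations (defaults to the
#'   standard 360/80/40 session).
#' @param staircase staircase configuration for the simulations.
#' @param n_sim_participants number of simulated participants (default 100).
#' @param n_rt_curves maximum number of simulated go-RT vectors stored for
#'   density overlays (default 1000).
#' @param seed integer seed.
#' @return tibble of class `ppc_report`: columns `trial_type`, `statistic`,
#'   `response`, `observed`, `pred_median`, `pred_lo`, `pred_hi`; simulated
#'   go RT vectors in attribute `go_rt_curves`.
#' @export
posterior_predictive <- function(fit, design = make_session_design(seed = 1),
                                 staircase = staircase_config(),
                                 n_sim_participants = 100, n_rt_curves = 1000,
                                 seed = 1) {
  stopifnot(inherits(fit, "sst_fit"))
  if (nrow(design) == 0) stop("empty design", call. = FALSE)
  ga <- fit$group
  C <- dim(ga)[1]; K <- dim(ga)[2]
  obs <- split(fit$trials, fit$trials$participant_id) |>
    purrr::map_dfr(ppc_stats) |>
    dplyr::group_by(.data$trial_type, .data$statistic, .data$response) |>
    dplyr::summarise(observed = stats::median(.data$value), .groups = "drop")

  sims <- with_local_seed(seed, {
    purrr::map(seq_len(n_sim_participants), function(s) {
      ch <- sample.int(C, 1); it <- sample.int(K, 1)
      hy <- group_hyperparams(
        location = stats::setNames(ga[ch, it, 1:11], race_param_names()),
        scale = stats::setNames(pmax(ga[ch, it, 12:22], 1e-6), race_param_names()))
      v <- draw_participant_vec(hy)
      simulate_participant(vec_to_params(v), design, staircase,
                           seed = child_seed(seed, s),
                           participant_id = sprintf("sim%03d", s))
    })
  })
  sim_stats <- purrr::map_dfr(sims, ppc_stats, .id = "sim")
  pred <- sim_stats |>
    dplyr::group_by(.data$trial_type, .data$statistic, .data$response) |>
    dplyr::summarise(pred_median = stats::median(.data$value),
                     pred_lo = stats::quantile(.data$value, 0.025, names = FALSE),
                     pred_hi = stats::quantile(.data$value, 0.975, names = FALSE),
                     .groups = "drop")
  out <- dplyr::full_join(obs, pred,
                          by = c("trial_type", "statistic", "response"))
  curves <- purrr::map(sims[seq_len(min(n_rt_curves, length(sims)))], function(s) {
    s$rt_s[s$trial_type == "go" & !is.na(s$rt_s)]
  })
  attr(out, "go_rt_curves") <- curves
  class(out) <- c("ppc_report", class(out))
  out
}
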