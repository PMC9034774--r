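#' Race-model parameters for one participant
#'
#' The stop-signal race model describes each trial as a race between three
#' independent ex-Gaussian racers: a go process matching the stimulus, a go
#' process mismatching it, and (on stop/no-go trials) a stop process that
#' starts at the stop-signal delay. Two attentional-failure probabilities
#' complete the model: `p_tf` (trigger failure: the stop process fails to
#' start) and `p_gf` (go failure: neither go process starts, producing an
#' omission).
#'
#' @param go_match,go_mismatch,stop `exgauss_params` triples (or 3-element
#'   lists/vectors `mu, sigma, tau`).
#' @param p_tf,p_gf failure probabilities in `[0, 1]`.
#' @return list of class `race_model_params`.
#' @examples
#' race_model_params(
#'   go_match = exgauss_params(0.45, 0.06, 0.09),
#'   go_mismatch = exgauss_params(0.55, 0.08, 0.12),
#'   stop = exgauss_params(0.18, 0.03, 0.05),
#'   p_tf = 0.05, p_gf = 0.02
#' )
#' @export
race_model_params <- function(go_match, go_mismatch, stop, p_tf = 0, p_gf = 0) {
  as_eg <- function(x) {
    if (inherits(x, "exgauss_params")) return(x)
    x <- unlist(x, use.names = FALSE)
    exgauss_params(x[1], x[2], x[3])
  }
  if (any(c(p_tf, p_gf) < 0) || any(c(p_tf, p_gf) > 1)) {
    stop("p_tf and p_gf must lie in [0, 1]", call. = FALSE)
  }
  structure(list(go_match = as_eg(go_match), go_mismatch = as_eg(go_mismatch),
                 stop = as_eg(stop), p_tf = p_tf, p_gf = p_gf),
            class = "race_model_params")
}

other_direction <- function(direction) ifelse(direction == "left", "right", "left")

#' Simulate a single stop-signal trial
#'
#' Runs one race. With probability `p_gf` no go racer starts (an omission
#' unless a stop racer also never matters); otherwise matching and
#' mismatching finish times are drawn from their ex-Gaussians. On stop and
#' no-go trials the stop racer starts at `ssd` with probability `1 - p_tf`.
#' The recorded response is the earliest go finisher, unless the stop racer
#' finishes before both go racers (successful stop, no response).
#'
#' Uses the current RNG state; seed upstream (e.g. via
#' [simulate_participant()]) for reproducibility.
#'
#' @param params `race_model_params`.
#' @param trial_type `"go"`, `"stop"` or `"nogo"`.
#' @param direction go-stimulus direction, `"left"` or `"right"`.
#' @param ssd stop-signal delay in seconds (ignored on go trials).
#' @return one-row tibble with `trial_type`, `direction`, `ssd_s`,
#'   `response` (`NA` when no response) and `rt_s`.
#' @export
simulate_trial <- function(params, trial_type, direction = "left", ssd = NA_real_) {
  stopifnot(inherits(params, "race_model_params"))
  trial_type <- match.arg(trial_type, c("go", "stop", "nogo"))
  if (trial_type != "go") {
    if (is.na(ssd) || ssd < 0) stop("ssd must be >= 0 on stop/nogo trials", call. = FALSE)
  } else {
    ssd <- NA_real_
  }

  go_started <- stats::runif(1) >= params$p_gf
  resp <- NA_character_
  rt <- NA_real_
  if (go_started) {
    t_match <- rexgauss(1, params$go_match$mu, params$go_match$sigma, params$go_match$tau)
    t_mis <- rexgauss(1, params$go_mismatch$mu, params$go_mismatch$sigma, params$go_mismatch$tau)
    t_go <- min(t_match, t_mis)
    go_resp <- if (t_match <= t_mis) direction else other_direction(direction)
    stop_wins <- FALSE
    if (trial_type != "go" && stats::runif(1) >= params$p_tf) {
      t_stop <- ssd + rexgauss(1, params$stop$mu, params$stop$sigma, params$stop$tau)
      stop_wins <- t_stop < t_go
    }
    if (!stop_wins) {
      resp <- go_resp
      rt <- t_go
    }
  }
  tibble::tibble(trial_type = trial_type, direction = direction,
                 ssd_s = ssd, response = resp, rt_s = rt)
}

#' Simulate a full session for one participant
#'
#' Walks the session design in order, drawing each trial from the race model
#' and tracking the stop-signal delay with the one-up/one-down staircase:
#' after a successful stop the SSD increases by one step, after a failed
#' stop (a response was emitted) it decreases, clamped to the configured
#' bounds. The tracker reacts only to observed behaviour, so trigger-failed
#' stop trials still move the staircase down. No-go trials keep the nominal
#' 5-ms SSD and do not move the staircase.
#'
#' @param params `race_model_params`.
#' @param design an `sst_design` (see [make_session_design()]).
#' @param staircase a [staircase_config()].
#' @param seed integer seed.
#' @param participant_id identifier stored in the output table.
#' @return tibble with columns `participant_id`, `trial_index`, `trial_type`,
#'   `direction`, `ssd_s`, `response`, `rt_s`.
#' @examples
#' design <- make_session_design(20, 8, 2, seed = 2)
#' p <- race_model_params(c(0.45, 0.06, 0.09), c(0.55, 0.08, 0.12),
#'                        c(0.18, 0.03, 0.05), 0.05, 0.02)
#' simulate_participant(p, design, staircase_config(), seed = 3)
#' @export
simulate_participant <- function(params, design, staircase = staircase_config(),
                                 seed = 1, participant_id = "p1") {
  stopifnot(inherits(params, "race_model_params"),
            inherits(staircase, "staircase_config"))
  design <- tibble::as_tibble(design)
  n <- nrow(design)
  if (n == 0) stop("empty design", call. = FALSE)
  gm <- params$go_match; gmm <- params$go_mismatch; st <- params$stop
  with_local_seed(seed, {
    # pre-draw racer finish times for all trials; the staircase only
    # affects the stop racer's start, applied in the sequential pass
    t_match <- rexgauss(n, gm$mu, gm$sigma, gm$tau)
    t_mis <- rexgauss(n, gmm$mu, gmm$sigma, gmm$tau)
    t_stop0 <- rexgauss(n, st$mu, st$sigma, st$tau)
    go_started <- stats::runif(n) >= params$p_gf
    stop_triggers <- stats::runif(n) >= params$p_tf
    ssd_now <- staircase$initial_ssd
    ssd <- rep(NA_real_, n)
    response <- rep(NA_character_, n)
    rt <- rep(NA_real_, n)
    types <- design$trial_type
    dirs <- design$direction
    for (i in seq_len(n)) {
      type <- types[i]
      ssd_i <- switch(type, go = NA_real_, nogo = NOGO_SSD, stop = ssd_now)
      ssd[i] <- ssd_i
      if (go_started[i]) {
        t_go <- min(t_match[i], t_mis[i])
        stop_wins <- type != "go" && stop_triggers[i] &&
          (ssd_i + t_stop0[i]) < t_go
        if (!stop_wins) {
          response[i] <- if (t_match[i] <= t_mis[i]) dirs[i] else other_direction(dirs[i])
          rt[i] <- t_go
        }
      }
      if (type == "stop") {
        ssd_now <- if (is.na(response[i])) ssd_now + staircase$step else
          ssd_now - staircase$step
        ssd_now <- min(max(ssd_now, staircase$min_ssd), staircase$max_ssd)
      }
    }
    tibble::tibble(participant_id = participant_id,
                   trial_index = design$trial_index,
                   trial_type = types, direction = dirs,
                   ssd_s = ssd, response = response, rt_s = rt)
  })
}

#' Group-level hyperparameters of the hierarchical race model
#'
#' Location and scale of the group-level normal distribution for each of the
#' 11 participant-level parameters. Ex-Gaussian parameters live on the
#' natural (seconds) scale with truncation to positive support at the
#' participant level; the failure probabilities live on the probit scale so
#' the group normals stay unbounded.
#'
#' The defaults describe a plausible older-adult cohort: mean go RT around
#' 0.59 s, mean stop-racer finish time (the SSRT) around 0.16 s, a clearly
#' slower mismatching racer (choice error rates of a few percent), a modest
#' trigger-failure rate and a low go-failure rate.
#'
#' @param location,scale named numeric vectors over the parameter names
#'   `mu_go_match, sigma_go_match, tau_go_match, mu_go_mismatch,
#'   sigma_go_mismatch, tau_go_mismatch, mu_stop, sigma_stop, tau_stop,
#'   ptf_probit, pgf_probit`. Scales must be positive.
#' @return list of class `group_hyperparams`.
#' @export
group_hyperparams <- function(location = NULL, scale = NULL) {
  loc_default <- c(
    mu_go_match = 0.50, sigma_go_match = 0.06, tau_go_match = 0.09,
    mu_go_mismatch = 0.80, sigma_go_mismatch = 0.10, tau_go_mismatch = 0.20,
    mu_stop = 0.12, sigma_stop = 0.03, tau_stop = 0.04,
    ptf_probit = -1.5, pgf_probit = -2.2
  )
  sc_default <- c(
    mu_go_match = 0.07, sigma_go_match = 0.015, tau_go_match = 0.03,
    mu_go_mismatch = 0.10, sigma_go_mismatch = 0.02, tau_go_mismatch = 0.05,
    mu_stop = 0.035, sigma_stop = 0.008, tau_stop = 0.015,
    ptf_probit = 0.35, pgf_probit = 0.35
  )
  loc <- loc_default
  sc <- sc_default
  if (!is.null(location)) loc[names(location)] <- location
  if (!is.null(scale)) sc[names(scale)] <- scale
  if (any(is.na(loc)) || any(is.na(sc))) stop("unknown parameter name", call. = FALSE)
  if (any(sc <= 0)) stop("group scales must be > 0", call. = FALSE)
  structure(list(location = loc[race_param_names()], scale = sc[race_param_names()]),
            class = "group_hyperparams")
}

race_param_names <- function() {
  c("mu_go_match", "sigma_go_match", "tau_go_match",
    "mu_go_mismatch", "sigma_go_mismatch", "tau_go_mismatch",
    "mu_stop", "sigma_stop", "tau_stop", "ptf_probit", "pgf_probit")
}

positive_param_idx <- function() 1:9

# vector (11, transformed scale) -> race_model_params
vec_to_params <- function(v) {
  race_model_params(
    go_match = exgauss_params(v[1], v[2], v[3]),
    go_mismatch = exgauss_params(v[4], v[5], v[6]),
    stop = exgauss_params(v[7], v[8], v[9]),
    p_tf = inv_probit(v[10]), p_gf = inv_probit(v[11])
  )
}

params_to_vec <- function(p) {
  c(p$go_match$mu, p$go_match$sigma, p$go_match$tau,
    p$go_mismatch$mu, p$go_mismatch$sigma, p$go_mismatch$tau,
    p$stop$mu, p$stop$sigma, p$stop$tau,
    probit(p$p_tf), probit(p$p_gf))
}

# Draw one participant parameter vector from the group normals, rejecting
# non-positive draws for the ex-Gaussian parameters.
draw_participant_vec <- function(hyper, max_tries = 1000) {
  pos <- positive_param_idx()
  for (i in seq_len(max_tries)) {
    v <- stats::rnorm(11, hyper$location, hyper$scale)
    if (all(v[pos] > 0)) return(v)
  }
  stop("could not draw positive participant parameters; check hyperparameters",
       call. = FALSE)
}

#' Simulate a cohort of participants with known ground truth
#'
#' Draws per-participant race-model parameters from the group-level normals
#' (ex-Gaussian parameters truncated to positive support by rejection,
#' failure probabilities back-transformed from the probit scale) and
#' simulates one session per participant.
#'
#' @param hyper [group_hyperparams()].
#' @param n_participants number of participants (>= 1).
#' @param design session design shared across participants.
#' @param staircase staircase configuration.
#' @param seed integer seed.
#' @return list with `trials` (one tibble, all participants) and
#'   `true_params` (tibble, one row per participant with the 11 natural-scale
#'   parameters plus `p_tf`, `p_gf` and true `ssrt = mu_stop + tau_stop`).
#' @examples
#' cohort <- simulate_cohort(group_hyperparams(), 2,
#'                           make_session_design(30, 10, 4, seed = 1),
#'                           staircase_config(), seed = 5)
#' @export
simulate_cohort <- function(hyper, n_participants, design,
                            staircase = staircase_config(), seed = 1) {
  stopifnot(inherits(hyper, "group_hyperparams"))
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  vecs <- with_local_seed(seed, {
    lapply(seq_len(n_participants), function(i) draw_participant_vec(hyper))
  })
  ids <- sprintf("p%02d", seq_len(n_participants))
  trials <- purrr::map2_dfr(vecs, seq_len(n_participants), function(v, i) {
    simulate_participant(vec_to_params(v), design, staircase,
                         seed = child_seed(seed, i), participant_id = ids[i])
  })
  truth <- purrr::map2_dfr(vecs, ids, function(v, id) {
    tibble::as_tibble(as.list(stats::setNames(v, race_param_names()))) |>
      dplyr::mutate(participant_id = id,
                    p_tf = inv_probit(.data$ptf_probit),
                    p_gf = inv_probit(.data$pgf_probit),
                    ssrt = .data$mu_stop + .data$tau_stop,
                    .before = 1)
  })
  list(trials = trials, true_params = truth)
}
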