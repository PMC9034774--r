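#' Priors for the hierarchical race model
#'
#' Weakly informative priors on the group-level normals. Location parameters
#' get normal priors; the go-racer Gaussian means are centred at 1.5 s and
#' the stop-racer mean at 1.0 s (deliberately slow prior centres suitable
#' for an older cohort), sigma and tau locations at 0.1 s, and the
#' probit-scale failure locations at -1.5, all with prior SD 1.0. Group
#' scales get half-normal priors: SD 0.15 for the seconds-scale parameters
#' (between-participant SDs beyond ~150 ms are not plausible for RT
#' components and the heavy prior tail only degrades sampling geometry)
#' and SD 0.5 on the probit scale.
#'
#' @param loc_mean,loc_sd,scale_sd optional named numeric vectors overriding
#'   individual entries (names as in [group_hyperparams()]).
#' @return list of class `sst_priors`.
#' @export
default_priors <- function(loc_mean = NULL, loc_sd = NULL, scale_sd = NULL) {
  lm <- c(mu_go_match = 1.5, sigma_go_match = 0.1, tau_go_match = 0.1,
          mu_go_mismatch = 1.5, sigma_go_mismatch = 0.1, tau_go_mismatch = 0.1,
          mu_stop = 1.0, sigma_stop = 0.1, tau_stop = 0.1,
          ptf_probit = -1.5, pgf_probit = -1.5)
  ls <- stats::setNames(rep(1.0, 11), race_param_names())
  ss <- stats::setNames(c(rep(0.15, 9), 0.5, 0.5), race_param_names())
  if (!is.null(loc_mean)) lm[names(loc_mean)] <- loc_mean
  if (!is.null(loc_sd)) ls[names(loc_sd)] <- loc_sd
  if (!is.null(scale_sd)) ss[names(scale_sd)] <- scale_sd
  structure(list(loc_mean = lm[race_param_names()],
                 loc_sd = ls[race_param_names()],
                 scale_sd = ss[race_param_names()]),
            class = "sst_priors")
}

#' Sampler configuration for the hierarchical race-model fit
#'
#' Differential-evolution MCMC settings. The default chain count is 33
#' (three times the 11 participant-level parameters), with thinning of every
#' 10th sample and a 5% migration probability. Burn-in is adaptive: it ends
#' once the running Gelman-Rubin statistic of every group-level parameter
#' drops below `burn_rhat`, capped at `burn_max` raw iterations; `n_keep`
#' thinned samples per chain are then retained.
#'
#' @param n_chains number of chains; must be at least twice the parameter
#'   count (22), default 33.
#' @param thin keep every `thin`-th iteration (>= 1).
#' @param migration_prob per-iteration probability of a migration step.
#' @param n_keep retained thinned samples per chain.
#' @param burn_max maximum raw burn-in iterations.
#' @param burn_check check the running R-hat every this many raw iterations.
#' @param burn_rhat running R-hat threshold ending burn-in (default 1.2).
#' @param max_rounds if the retained draws still show R-hat >= 1.1, fold
#'   them into burn-in and sample again, at most this many times.
#' @param seed integer seed.
#' @param priors an [default_priors()] object.
#' @param gl_nodes Gauss-Legendre node count for the stop-success integral
#'   inside the sampler.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_chains = 33, thin = 10, migration_prob = 0.05,
                       n_keep = 500, burn_max = 2000, burn_check = 100,
                       burn_rhat = 1.2, max_rounds = 2, seed = 1,
                       priors = default_priors(), gl_nodes = 16) {
  n_par <- length(race_param_names())
  if (n_chains < 2 * n_par) {
    stop("n_chains must be at least twice the parameter count (", 2 * n_par, ")",
         call. = FALSE)
  }
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (migration_prob < 0 || migration_prob > 1) {
    stop("migration_prob must be a probability", call. = FALSE)
  }
  structure(list(n_chains = n_chains, thin = thin,
                 migration_prob = migration_prob, n_keep = n_keep,
                 burn_max = burn_max, burn_check = burn_check,
                 burn_rhat = burn_rhat, max_rounds = max_rounds,
                 seed = seed, priors = priors, gl_nodes = gl_nodes),
            class = "fit_config")
}

group_param_names <- function() {
  c(paste0(race_param_names(), "_loc"), paste0(race_param_names(), "_scale"))
}

# log prior density of participant vectors theta (11 x C) under per-chain
# hypers phi (22 x C): truncated normals for the positive parameters
# (normalizer log Phi(loc/scale)), plain normals on the probit scale.
lp_participant <- function(theta, phi) {
  loc <- phi[1:11, , drop = FALSE]
  sc <- phi[12:22, , drop = FALSE]
  pos <- positive_param_idx()
  lp <- colSums(stats::dnorm(theta, loc, sc, log = TRUE))
  support <- colSums(theta[pos, , drop = FALSE] <= 0) == 0
  lp[!support] <- -Inf
  lp
}

# log target of hypers phi (22 x C) given all participant vectors
# theta_all (11 x C x N) plus the hyperpriors.
lp_hyper <- function(phi, theta_all, priors) {
  C <- ncol(phi)
  N <- dim(theta_all)[3]
  loc <- phi[1:11, , drop = FALSE]
  sc <- phi[12:22, , drop = FALSE]
  bad <- colSums(sc <= 0) > 0
  sc_safe <- pmax(sc, 1e-12)
  lp <- numeric(C)
  for (i in seq_len(N)) {
    lp <- lp + colSums(stats::dnorm(theta_all[, , i], loc, sc_safe, log = TRUE))
  }
  lp <- lp + colSums(stats::dnorm(loc, priors$loc_mean, priors$loc_sd, log = TRUE))
  lp <- lp + colSums(stats::dnorm(sc, 0, priors$scale_sd, log = TRUE) + log(2))
  lp[bad] <- -Inf
  lp
}

# per-chain log target contribution of one group-normal (loc_j, scale_j)
# pair given that parameter's participant values th_j (C x N). The positive
# participant-level parameters are restricted to their support by the
# likelihood (implicit truncation); the group normal itself is not
# renormalized, the standard convention for this model family.
hyper_pair_lp <- function(loc_j, sc_j, th_j, pm, ps, ss) {
  C <- length(loc_j)
  N <- ncol(th_j)
  bad <- sc_j <= 0
  scs <- pmax(sc_j, 1e-12)
  lp <- rowSums(stats::dnorm(th_j, matrix(loc_j, C, N), matrix(scs, C, N),
                             log = TRUE))
  lp <- lp + stats::dnorm(loc_j, pm, ps, log = TRUE) +
    stats::dnorm(sc_j, 0, ss, log = TRUE) + log(2)
  lp[bad] <- -Inf
  lp
}

# slice-sample each chain's group scale on the log scale; the conditional
# log target given the sum of squares ssq of N centred participant values is
# -N log(s) - ssq/(2 s^2) - s^2/(2 ss^2) (+ log-scale Jacobian)
slice_scales <- function(sc, ssq, N, ss, w = 0.7, max_step = 20) {
  f <- function(u, q) -N * u - q / (2 * exp(2 * u)) - exp(2 * u) / (2 * ss^2) + u
  out <- sc
  for (c in seq_along(sc)) {
    u0 <- log(sc[c]); q <- ssq[c]
    y <- f(u0, q) - stats::rexp(1)
    lo <- u0 - w * stats::runif(1)
    hi <- lo + w
    k <- max_step
    while (k > 0 && f(lo, q) > y) { lo <- lo - w; k <- k - 1 }
    k <- max_step
    while (k > 0 && f(hi, q) > y) { hi <- hi + w; k <- k - 1 }
    repeat {
      u1 <- stats::runif(1, lo, hi)
      if (f(u1, q) >= y) break
      if (u1 < u0) lo <- u1 else hi <- u1
    }
    out[c] <- exp(u1)
  }
  out
}

de_proposal <- function(state, gamma, jitter = 1e-3) {
  d <- nrow(state)
  C <- ncol(state)
  a <- integer(C); b <- integer(C)
  for (c in seq_len(C)) {
    ab <- sample(seq_len(C)[-c], 2)
    a[c] <- ab[1]; b[c] <- ab[2]
  }
  state + gamma * (state[, a, drop = FALSE] - state[, b, drop = FALSE]) +
    matrix(stats::runif(d * C, -jitter, jitter), d, C)
}

migration_subset <- function(C) {
  k <- sample.int(C, 1)
  sample.int(C, k)
}

init_participant_chains <- function(cmp, C) {
  go_rt <- c(cmp$go_match_rt, cmp$go_mis_rt)
  m <- if (length(go_rt)) mean(go_rt) else 0.6
  theta <- matrix(0, 11, C)
  tau_gm <- stats::runif(C, 0.05, 0.15)
  theta[1, ] <- pmax(m - tau_gm + stats::rnorm(C, 0, 0.02), 0.05)
  theta[2, ] <- stats::runif(C, 0.03, 0.10)
  theta[3, ] <- tau_gm
  theta[4, ] <- theta[1, ] + stats::runif(C, 0.02, 0.20)
  theta[5, ] <- stats::runif(C, 0.03, 0.12)
  theta[6, ] <- stats::runif(C, 0.05, 0.20)
  theta[7, ] <- stats::runif(C, 0.08, 0.25)
  theta[8, ] <- stats::runif(C, 0.02, 0.06)
  theta[9, ] <- stats::runif(C, 0.02, 0.10)
  theta[10, ] <- stats::qnorm(stats::runif(C, 0.02, 0.20))
  theta[11, ] <- stats::qnorm(stats::runif(C, 0.005, 0.06))
  theta
}

#' Fit the hierarchical Bayesian race model
#'
#' Estimates the ex-Gaussian race model with trigger and go failures for a
#' cohort of participants by differential-evolution MCMC. Participant-level
#' parameters are drawn from group-level normal distributions (probit scale
#' for the failure probabilities, truncation to positive support for the
#' ex-Gaussian parameters); group locations and scales receive the priors in
#' [default_priors()]. Each iteration updates every participant's chains
#' with a crossover proposal and the group-level chains with a crossover on
#' the 22 hyperparameters; with the configured probability a migration step
#' (cyclic state swap over a random chain subset, Metropolis-accepted)
#' replaces the crossover. Burn-in is adaptive (see [fit_config()]); if the
#' retained draws still show a group-level Gelman-Rubin statistic at or
#' above 1.1 the run is extended up to `max_rounds` times and flagged by
#' warning if convergence is still not reached.
#'
#' @param trials trial table for the whole cohort (column `participant_id`),
#'   ideally already RT-cleaned with [preprocess_rts()].
#' @param config a [fit_config()].
#' @param qc apply [qc_participant()] and drop failing participants
#'   (default TRUE; at least 2 must survive).
#' @return object of class `sst_fit`: arrays `participant`
#'   (chain x draw x participant x parameter) and `group`
#'   (chain x draw x hyperparameter), parameter names, the data, config and
#'   convergence information.
#' @export
fit_hierarchical <- function(trials, config = fit_config(), qc = TRUE) {
  stopifnot(inherits(config, "fit_config"))
  trials <- validate_trial_table(trials)
  split_tabs <- split(trials, trials$participant_id)
  if (qc) {
    keep <- vapply(split_tabs, function(tt) qc_participant(tt)$pass, logical(1))
    split_tabs <- split_tabs[keep]
  }
  N <- length(split_tabs)
  if (N < 2) stop("need at least 2 participants passing QC", call. = FALSE)
  ids <- names(split_tabs)
  cmps <- lapply(split_tabs, compile_trials)
  C <- config$n_chains
  gl <- gauss_legendre(config$gl_nodes)
  priors <- config$priors
  g_theta <- 2.38 / sqrt(2 * 11)
  g_phi <- 2.38 / sqrt(2 * 22)

  with_local_seed(config$seed, {
    theta <- array(0, c(11, C, N))
    for (i in seq_len(N)) {
      theta[, , i] <- init_participant_chains(cmps[[i]], C)
    }
    stk <- stack_cohort(cmps)
    ll <- loglik_all(stk, theta, gl)
    loc0 <- apply(theta, 1, mean)
    phi <- rbind(
      matrix(loc0, 11, C) + matrix(stats::rnorm(11 * C, 0, 0.02), 11, C),
      matrix(stats::runif(11 * C, 0.02, 0.30), 11, C)
    )
    # probit-scale group scales start wider
    phi[21:22, ] <- matrix(stats::runif(2 * C, 0.2, 0.6), 2, C)

    iterate <- function(n_iter, collect) {
      group_buf <- list(); part_buf <- list()
      for (it in seq_len(n_iter)) {
        migrate <- stats::runif(1) < config$migration_prob
        # --- participant updates
        if (migrate) {
          for (i in seq_len(N)) {
            cur <- theta[, , i]
            lp_cur <- ll[, i] + lp_participant(cur, phi)
            S <- migration_subset(C)
            if (length(S) > 1) {
              donor <- c(S[length(S)], S[-length(S)])
              prop_state <- cur[, donor, drop = FALSE]
              lp_prop <- ll[donor, i] +
                lp_participant(prop_state, phi[, S, drop = FALSE])
              acc <- log(stats::runif(length(S))) < lp_prop - lp_cur[S]
              if (any(acc)) {
                theta[, S[acc], i] <<- prop_state[, acc]
                ll[S[acc], i] <<- ll[donor[acc], i]
              }
            }
          }
        } else {
          # two crossover sweeps per iteration, evaluated for the whole
          # cohort in one stacked likelihood call: first on a random subset
          # of all 11 dimensions (all of them half of the time), then a
          # targeted move on the stop-racer/failure subspace, whose
          # posterior is weakly identified and mixes slowest
          sweep <- function(dims) {
            gam <- 2.38 / sqrt(2 * length(dims)) * stats::runif(1, 0.5, 1.5)
            prop <- theta
            for (i in seq_len(N)) {
              prop[dims, , i] <- de_proposal(theta[, , i], gam)[dims, , drop = FALSE]
            }
            lp_pr <- lp_participant_all(prop, phi)
            lp_cur <- ll + lp_participant_all(theta, phi)
            ll_prop <- loglik_all(stk, prop, gl)
            acc <- matrix(log(stats::runif(C * N)), C, N) <
              (ll_prop + lp_pr) - lp_cur
            for (i in seq_len(N)) {
              a <- acc[, i]
              if (any(a)) {
                theta[, a, i] <<- prop[, a, i]
                ll[a, i] <<- ll_prop[a, i]
              }
            }
          }
          dims <- if (stats::runif(1) < 0.5) 1:11 else {
            d <- which(stats::runif(11) < 0.5)
            if (!length(d)) sample.int(11, 1) else d
          }
          sweep(dims)
          dims2 <- which(stats::runif(11) < 0.5 & seq_len(11) >= 7)
          if (!length(dims2)) dims2 <- sample(7:11, 1)
          sweep(dims2)
          # independence move: redraw a subset of the data-poor dimensions
          # (mismatch racer, failure probabilities) from the chain's group
          # prior; the prior terms cancel in the Metropolis ratio, so the
          # move is accepted on the likelihood ratio alone and mixes those
          # dimensions (and hence their group scales) almost independently
          weak <- c(4, 5, 6, 10, 11)
          dims3 <- weak[stats::runif(5) < 0.5]
          if (!length(dims3)) dims3 <- sample(weak, 1)
          prop <- theta
          for (i in seq_len(N)) {
            prop[dims3, , i] <- stats::rnorm(length(dims3) * C,
                                             phi[dims3, , drop = FALSE],
                                             phi[11 + dims3, , drop = FALSE])
          }
          ok_support <- apply(prop[positive_param_idx(), , , drop = FALSE] > 0,
                              c(2, 3), all)
          ll_prop <- loglik_all(stk, prop, gl)
          acc <- ok_support &
            matrix(log(stats::runif(C * N)), C, N) < (ll_prop - ll)
          for (i in seq_len(N)) {
            a <- acc[, i]
            if (any(a)) {
              theta[dims3, a, i] <<- prop[dims3, a, i]
              ll[a, i] <<- ll_prop[a, i]
            }
          }
        }
        # --- group-level update
        if (migrate) {
          lp_cur <- lp_hyper(phi, theta, priors)
          S <- migration_subset(C)
          if (length(S) > 1) {
            donor <- c(S[length(S)], S[-length(S)])
            prop_state <- phi[, donor, drop = FALSE]
            lp_prop <- lp_hyper_subset(prop_state, theta, priors, S)
            acc <- log(stats::runif(length(S))) < lp_prop - lp_cur[S]
            if (any(acc)) phi[, S[acc]] <<- prop_state[, acc]
          }
        } else {
          # the conditional target of the hypers factorizes over the 11
          # group normals: exact Gibbs for each location (conjugate normal)
          # and univariate slice sampling for each scale
          for (j in seq_len(11)) {
            th_j <- matrix(theta[j, , ], nrow = C)   # C x N
            pm <- priors$loc_mean[j]; ps <- priors$loc_sd[j]
            ss <- priors$scale_sd[j]
            sc <- phi[11 + j, ]
            v <- 1 / (N / sc^2 + 1 / ps^2)
            mu_post <- v * (rowSums(th_j) / sc^2 + pm / ps^2)
            loc <- stats::rnorm(C, mu_post, sqrt(v))
            phi[j, ] <<- loc
            ssq <- rowSums((th_j - loc)^2)
            phi[11 + j, ] <<- slice_scales(sc, ssq, N, ss)
          }
        }
        if (it %% config$thin == 0) {
          group_buf[[length(group_buf) + 1]] <- t(phi)
          if (collect) part_buf[[length(part_buf) + 1]] <- theta
        }
      }
      list(group = group_buf, part = part_buf)
    }

    # adaptive burn-in
    burn_used <- 0
    burn_hist <- list()
    repeat {
      todo <- min(config$burn_check, config$burn_max - burn_used)
      if (todo <= 0) break
      res <- iterate(todo, collect = FALSE)
      burn_used <- burn_used + todo
      burn_hist <- c(burn_hist, res$group)
      nh <- length(burn_hist)
      if (nh >= 4) {
        half <- burn_hist[(floor(nh / 2) + 1):nh]
        arr <- buf_to_array(half, C, 22)
        rh <- rhat_array(arr)
        if (all(is.finite(rh)) && max(rh) < config$burn_rhat) break
      }
    }

    # sampling (with extension rounds if the kept draws have not converged)
    rounds <- 0
    repeat {
      res <- iterate(config$n_keep * config$thin, collect = TRUE)
      group_arr <- buf_to_array(res$group, C, 22)
      rh <- rhat_array(group_arr)
      rounds <- rounds + 1
      if (max(rh) < 1.1 || rounds > config$max_rounds) break
    }
    part_arr <- array(NA_real_, c(C, length(res$part), N, 11))
    for (k in seq_along(res$part)) part_arr[, k, , ] <- aperm(res$part[[k]], c(2, 3, 1))
    dimnames(group_arr) <- list(NULL, NULL, group_param_names())
    dimnames(part_arr) <- list(NULL, NULL, ids, race_param_names())

    converged <- max(rh) < 1.1
    if (!converged) {
      warning(sprintf(
        "race-model fit flagged as non-convergent: max group-level R-hat = %.3f >= 1.1",
        max(rh)), call. = FALSE)
    }
    structure(list(
      participant = part_arr, group = group_arr,
      param_names = race_param_names(), group_names = group_param_names(),
      participants = ids, trials = trials, config = config,
      burn_iterations = burn_used, rounds = rounds,
      rhat_group = rh, converged = converged
    ), class = "sst_fit")
  })
}

# lp_hyper for a subset of chains (used by migration)
lp_hyper_subset <- function(phi_sub, theta_all, priors, chains) {
  theta_sub <- theta_all[, chains, , drop = FALSE]
  lp_hyper(phi_sub, theta_sub, priors)
}

buf_to_array <- function(buf, C, K) {
  arr <- array(NA_real_, c(C, length(buf), K))
  for (k in seq_along(buf)) arr[, k, ] <- buf[[k]]
  arr
}

# Gelman-Rubin over an array (chain x iter x param)
rhat_array <- function(arr) {
  apply(arr, 3, function(ch) gelman_rubin(t(ch)))
}

# x: iterations x chains
gelman_rubin <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (m < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
  if (n < 2) return(NA_real_)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  # floored at 1: the classic estimator drops slightly below 1 when the
  # between-chain variance vanishes
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

#' Gelman-Rubin convergence diagnostics
#'
#' Computes the potential scale reduction statistic (R-hat) for every
#' group-level parameter of a fitted race model (or every parameter of a
#' plain `chain x iteration x parameter` array), with the conventional
#' convergence criterion R-hat < 1.1 for all parameters.
#'
#' @param samples an `sst_fit` or a 3-d array (chain x iteration x parameter).
#' @param level for `sst_fit` objects: `"group"` (default) or
#'   `"participant"` (R-hat for every participant-level parameter).
#' @return tibble of class `rhat_report` with columns `parameter`, `rhat`,
#'   and attribute `converged`.
#' @export
compute_rhat <- function(samples, level = c("group", "participant")) {
  level <- match.arg(level)
  if (inherits(samples, "sst_fit")) {
    arr <- if (level == "group") samples$group else {
      d <- dim(samples$participant)
      out <- array(samples$participant, c(d[1], d[2], d[3] * d[4]))
      dimnames(out) <- list(NULL, NULL, as.vector(outer(
        dimnames(samples$participant)[[3]],
        dimnames(samples$participant)[[4]], paste, sep = ".")))
      out
    }
  } else {
    arr <- samples
  }
  if (length(dim(arr)) != 3) stop("expected a chain x iteration x parameter array",
                                  call. = FALSE)
  if (dim(arr)[1] < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
  rh <- rhat_array(arr)
  nm <- dimnames(arr)[[3]] %||% paste0("param", seq_along(rh))
  out <- tibble::tibble(parameter = nm, rhat = rh)
  attr(out, "converged") <- all(is.finite(rh)) && max(rh) < 1.1
  class(out) <- c("rhat_report", class(out))
  out
}

# prior density of every participant's chain states under per-chain hypers:
# returns a C x N matrix
lp_participant_all <- function(theta_arr, phi) {
  N <- dim(theta_arr)[3]
  out <- matrix(0, ncol(phi), N)
  for (i in seq_len(N)) out[, i] <- lp_participant(theta_arr[, , i], phi)
  out
}
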