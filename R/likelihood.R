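#' Probability of successfully stopping at a given delay
#'
#' Probability that the stop racer, starting at `ssd`, finishes before both
#' go racers, given that all three racers start:
#' \deqn{\int f_{stop}(s - ssd)\,[1 - F_{match}(s)]\,[1 - F_{mismatch}(s)]\,ds}
#' evaluated by adaptive quadrature over a window covering at least
#' \eqn{1 - 10^{-8}} of the stop racer's mass. Monotonically nonincreasing
#' in `ssd`. Trigger and go failures are deliberately not included; they
#' are mixed in by [loglik_trial()].
#'
#' @param params `race_model_params`.
#' @param ssd stop-signal delay in seconds (>= 0); vectorized.
#' @return probability in `[0, 1]` for each `ssd`.
#' @examples
#' p <- race_model_params(c(0.5, 0.1, 0.1), c(0.6, 0.1, 0.1), c(0.2, 0.03, 0.05))
#' stop_success_probability(p, c(0, 0.25, 0.5))
#' @export
stop_success_probability <- function(params, ssd) {
  stopifnot(inherits(params, "race_model_params"))
  if (any(ssd < 0)) stop("ssd must be >= 0", call. = FALSE)
  st <- params$stop
  gm <- params$go_match
  gmm <- params$go_mismatch
  vapply(ssd, function(d) {
    upper <- d + st$mu + 10 * (st$sigma + st$tau)
    f <- function(s) {
      dexgauss(s - d, st$mu, st$sigma, st$tau) *
        pexgauss(s, gm$mu, gm$sigma, gm$tau, lower.tail = FALSE) *
        pexgauss(s, gmm$mu, gmm$sigma, gmm$tau, lower.tail = FALSE)
    }
    # the stop density has support below its start through the Gaussian
    # component; extend the lower limit accordingly
    lower <- d + st$mu - 10 * st$sigma
    val <- stats::integrate(f, lower, upper, rel.tol = 1e-8, abs.tol = 1e-10,
                            stop.on.error = FALSE)$value
    min(max(val, 0), 1)
  }, numeric(1))
}

#' Log-likelihood of a single trial under the race model
#'
#' Implements the defective-density mixture of the ex-Gaussian race model
#' with attentional failures. Writing \eqn{f_c, F_c} for the responding
#' racer's density/CDF and \eqn{S = 1 - F} for survival:
#' \itemize{
#' \item go trial, response at time t: \eqn{(1-p_{gf}) f_c(t) S_{other}(t)}
#' \item go omission: \eqn{p_{gf}}
#' \item stop/no-go trial, response at t:
#'   \eqn{(1-p_{gf}) f_c(t) S_{other}(t)\,[p_{tf} + (1-p_{tf}) S_{stop}(t-ssd)]}
#' \item successful stop: \eqn{p_{gf} + (1-p_{gf})(1-p_{tf}) P_{success}(ssd)}
#' }
#' A go failure on a stop trial counts toward successful stopping: the
#' tracker (and the scorer) only see that no response occurred. An RT below
#' the SSD is valid; the stop survival argument is then negative and the
#' survival is 1.
#'
#' @param trial one-row data frame with `trial_type`, `direction`, `ssd_s`,
#'   `response`, `rt_s` (response `NA` for omissions/successful stops).
#' @param params `race_model_params`.
#' @return log-density (may be `-Inf` for impossible outcomes).
#' @export
loglik_trial <- function(trial, params) {
  stopifnot(inherits(params, "race_model_params"), nrow(trial) == 1)
  type <- trial$trial_type
  if (!type %in% c("go", "stop", "nogo")) stop("unknown trial type", call. = FALSE)
  responded <- !is.na(trial$response)
  if (type == "go" && !is.na(trial$ssd_s)) {
    stop("go trials must not carry an SSD", call. = FALSE)
  }
  p_gf <- params$p_gf
  p_tf <- params$p_tf
  if (!responded) {
    if (type == "go") return(log(p_gf))
    psucc <- stop_success_probability(params, trial$ssd_s)
    return(log(p_gf + (1 - p_gf) * (1 - p_tf) * psucc))
  }
  t <- trial$rt_s
  if (is.na(t)) stop("responses must carry an RT", call. = FALSE)
  match_resp <- trial$response == trial$direction
  racer <- if (match_resp) params$go_match else params$go_mismatch
  other <- if (match_resp) params$go_mismatch else params$go_match
  ll <- log1p(-p_gf) +
    dexgauss(t, racer$mu, racer$sigma, racer$tau, log = TRUE) +
    pexgauss(t, other$mu, other$sigma, other$tau, lower.tail = FALSE, log.p = TRUE)
  if (type != "go") {
    s_stop <- pexgauss(t - trial$ssd_s, params$stop$mu, params$stop$sigma,
                       params$stop$tau, lower.tail = FALSE)
    ll <- ll + log(p_tf + (1 - p_tf) * s_stop)
  }
  ll
}

# ---- vectorized likelihood machinery used by the sampler --------------------

# Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

# Compact per-participant data summary for fast likelihood evaluation.
# Trials are grouped by outcome; successful stops are tallied per unique SSD.
compile_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  responded <- !is.na(trials$response)
  is_go <- trials$trial_type == "go"
  match_resp <- responded & trials$response == trials$direction
  list(
    go_match_rt = trials$rt_s[is_go & responded & match_resp],
    go_mis_rt = trials$rt_s[is_go & responded & !match_resp],
    n_go_omit = sum(is_go & !responded),
    sr_match_rt = trials$rt_s[!is_go & responded & match_resp],
    sr_match_ssd = trials$ssd_s[!is_go & responded & match_resp],
    sr_mis_rt = trials$rt_s[!is_go & responded & !match_resp],
    sr_mis_ssd = trials$ssd_s[!is_go & responded & !match_resp],
    stop_ssd_tab = {
      s <- trials$ssd_s[!is_go & !responded]
      if (length(s)) {
        tab <- table(round(s, 6))
        list(ssd = as.numeric(names(tab)), count = as.numeric(tab))
      } else list(ssd = numeric(0), count = numeric(0))
    }
  )
}

LOGLIK_FLOOR <- -1e10

# Log-likelihood of one participant's compiled trials for each column of a
# C-column parameter matrix theta (11 x C; sampling scale: natural seconds
# for the ex-Gaussian parameters, probit for the failure probabilities).
loglik_chains <- function(cmp, theta, gl = gauss_legendre(16)) {
  as.numeric(loglik_all(stack_cohort(list(cmp)),
                        array(theta, c(11, ncol(theta), 1)), gl))
}

#' Log-likelihood of a trial table for one participant
#'
#' Sums [loglik_trial()] over a table, using the fast vectorized kernel the
#' sampler uses internally (high-order quadrature for the stop-success
#' integrals).
#'
#' @param trials trial table (one participant).
#' @param params `race_model_params`.
#' @return scalar log-likelihood.
#' @export
loglik_table <- function(trials, params) {
  cmp <- compile_trials(trials)
  theta <- matrix(params_to_vec(params), ncol = 1)
  as.numeric(loglik_chains(cmp, theta, gauss_legendre(32)))
}

# ---- stacked cohort evaluation ---------------------------------------------
# One likelihood call for the whole cohort: response trials of every
# participant are concatenated into four blocks (go / signal-respond x
# match / mismatch) with a participant index; the heavy elementwise math
# runs in the compiled kernels of src/race_likelihood.cpp.

stack_cohort <- function(cmps) {
  N <- length(cmps)
  grab <- function(rt_field, ssd_field = NULL) {
    rts <- lapply(cmps, `[[`, rt_field)
    part <- rep(seq_len(N), lengths(rts))
    ssds <- if (!is.null(ssd_field)) unlist(lapply(cmps, `[[`, ssd_field),
                                            use.names = FALSE) else
      numeric(sum(lengths(rts)))
    list(rt = unlist(rts, use.names = FALSE), ssd = ssds, part = part)
  }
  stop_tab <- lapply(cmps, `[[`, "stop_ssd_tab")
  list(
    N = N,
    go_match = grab("go_match_rt"),
    go_mis = grab("go_mis_rt"),
    sr_match = grab("sr_match_rt", "sr_match_ssd"),
    sr_mis = grab("sr_mis_rt", "sr_mis_ssd"),
    n_go_omit = vapply(cmps, `[[`, numeric(1), "n_go_omit"),
    stop_ssd = unlist(lapply(stop_tab, `[[`, "ssd"), use.names = FALSE),
    stop_count = unlist(lapply(stop_tab, `[[`, "count"), use.names = FALSE),
    stop_part = rep(seq_len(N), vapply(stop_tab, function(s) length(s$ssd),
                                       integer(1)))
  )
}

# theta: 11 x C x N array on the sampling scale -> C x N log-likelihood
loglik_all <- function(stk, theta, gl = gauss_legendre(16)) {
  C <- dim(theta)[2]
  N <- dim(theta)[3]
  bad <- apply(theta[1:9, , , drop = FALSE] <= 0, c(2, 3), any)  # C x N
  if (any(bad)) {
    dummy <- c(0.5, 0.1, 0.1, 0.5, 0.1, 0.1, 0.5, 0.1, 0.1, 0, 0)
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) theta[, idx[r, 1], idx[r, 2]] <- dummy
  }
  # parameter planes as N x C matrices (participant x chain)
  pl <- lapply(1:11, function(p) t(matrix(theta[p, , ], C, N)))
  PTF <- stats::pnorm(pl[[10]])
  PGF <- stats::pnorm(pl[[11]])
  blk <- function(b, racer, other, with_stop) {
    if (!length(b$rt)) return(matrix(0, C, N))
    resp_block_cpp(b$rt, b$ssd, b$part,
                   pl[[racer[1]]], pl[[racer[2]]], pl[[racer[3]]],
                   pl[[other[1]]], pl[[other[2]]], pl[[other[3]]],
                   pl[[7]], pl[[8]], pl[[9]], PTF, PGF, with_stop)
  }
  ll <- blk(stk$go_match, 1:3, 4:6, FALSE) +
    blk(stk$go_mis, 4:6, 1:3, FALSE) +
    blk(stk$sr_match, 1:3, 4:6, TRUE) +
    blk(stk$sr_mis, 4:6, 1:3, TRUE) +
    t(stk$n_go_omit * log(PGF))

  if (length(stk$stop_ssd)) {
    pt <- stk$stop_part
    psucc <- stop_success_cpp(stk$stop_ssd, pt,
                              pl[[1]], pl[[2]], pl[[3]],
                              pl[[4]], pl[[5]], pl[[6]],
                              pl[[7]], pl[[8]], pl[[9]],
                              gl$nodes, gl$weights)
    ptf <- PTF[pt, , drop = FALSE]
    pgf <- PGF[pt, , drop = FALSE]
    pterm <- pgf + (1 - pgf) * (1 - ptf) * psucc
    agg <- rowsum(stk$stop_count * log(pterm), pt)
    cols <- as.integer(rownames(agg))
    ll[, cols] <- ll[, cols] + t(agg)
  }
  ll[!is.finite(ll)] <- LOGLIK_FLOOR
  ll <- pmax(ll, LOGLIK_FLOOR)
  ll[bad] <- -Inf
  ll
}
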