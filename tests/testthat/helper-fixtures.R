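# shared fixtures: plausible racer parameters and compact designs
std_params <- function(p_tf = 0, p_gf = 0) {
  race_model_params(
    go_match = c(0.45, 0.06, 0.09),
    go_mismatch = c(0.65, 0.10, 0.15),
    stop = c(0.18, 0.03, 0.05),
    p_tf = p_tf, p_gf = p_gf
  )
}

go_trial_row <- function(rt, response = "left", direction = "left") {
  tibble::tibble(trial_type = "go", direction = direction, ssd_s = NA_real_,
                 response = response, rt_s = rt)
}

stop_trial_row <- function(ssd, rt = NA_real_, response = NA_character_,
                           direction = "left") {
  tibble::tibble(trial_type = "stop", direction = direction, ssd_s = ssd,
                 response = response, rt_s = rt)
}

make_trials <- function(go_rts, participant_id = "p1", n_stop_resp = 0) {
  n <- length(go_rts)
  tibble::tibble(
    participant_id = participant_id,
    trial_index = seq_len(n),
    trial_type = "go",
    direction = rep(c("left", "right"), length.out = n),
    ssd_s = NA_real_,
    response = rep(c("left", "right"), length.out = n),
    rt_s = go_rts
  )
}

# numerical convolution of normal and exponential densities: the
# independent oracle for the ex-Gaussian density
exgauss_pdf_oracle <- function(t, mu, sigma, tau) {
  vapply(t, function(tt) {
    stats::integrate(function(u) stats::dnorm(u, mu, sigma) *
                       stats::dexp(tt - u, 1 / tau),
                     lower = mu - 12 * sigma, upper = tt,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}
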