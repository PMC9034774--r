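#' Data-generating process for the moderated-mediation covariate table
#'
#' Defines the known-truth path model used to test the inferential layer.
#' With X the (age-residualized) locus coeruleus CNR, M the preSMA-rIFG
#' connectivity scalar, W the participant's age (mean-centred before
#' forming products) and Y the SSRT in seconds:
#' \deqn{M = a_0 + a_1 X + e_M}
#' \deqn{Y = b_0 + c_1 X + b_1 M + b_2 (M W) + c_2 (X W) + g W +
#'   \beta_{sex} sex + \beta_{vol}(preSMA + rIFG) + e_Y}
#' The true index of moderated mediation is \eqn{a_1 b_2}.
#'
#' Default coefficient magnitudes reflect an older-adult cohort: ages
#' uniform on 50--88 years, SSRT residual SD 0.05 s, and a moderated
#' indirect effect detectable around n = 150--200.
#'
#' @param n number of participants (>= 10).
#' @param a0,a1 mediator-equation intercept and X effect.
#' @param b0 outcome intercept (seconds).
#' @param c1,b1,b2,c2,g outcome-equation coefficients (direct effect,
#'   mediator effect, mediator-by-age, direct-by-age, age main effect).
#' @param beta_sex,beta_vol covariate effects on the outcome.
#' @param sd_m,sd_y residual SDs of M and Y (> 0).
#' @param seed integer seed.
#' @return list of class `mediation_dgp`.
#' @export
mediation_dgp <- function(n = 200, a0 = 0, a1 = 0.4, b0 = 0.25,
                          c1 = -0.03, b1 = -0.04, b2 = -0.003, c2 = -0.002,
                          g = 0.002, beta_sex = 0.01, beta_vol = -0.005,
                          sd_m = 0.5, sd_y = 0.05, seed = 1) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (sd_m <= 0 || sd_y <= 0) stop("residual SDs must be > 0", call. = FALSE)
  structure(list(n = n, a0 = a0, a1 = a1, b0 = b0, c1 = c1, b1 = b1, b2 = b2,
                 c2 = c2, g = g, beta_sex = beta_sex, beta_vol = beta_vol,
                 sd_m = sd_m, sd_y = sd_y, seed = seed),
            class = "mediation_dgp")
}

#' Simulate a covariate table from the moderated-mediation path model
#'
#' Draws X ~ N(0, 1) (CNR residual), age ~ Uniform(50, 88), sex ~
#' Bernoulli(0.5), grey-matter volumes ~ N(0, 1), then M and Y from the
#' path equations of [mediation_dgp()] with age mean-centred in the product
#' terms. The true index of moderated mediation (`a1 * b2`) is recorded as
#' an attribute.
#'
#' @param dgp a [mediation_dgp()].
#' @return tibble with columns `participant_id`, `lc_cnr_resid` (X),
#'   `connectivity` (M), `age` (W, years), `ssrt` (Y, seconds), `sex`,
#'   `presma_vol`, `rifg_vol`, `total_gm_vol`; attributes `true_index` and
#'   `dgp`.
#' @examples
#' tab <- simulate_mediation_dataset(mediation_dgp(n = 50, seed = 2))
#' attr(tab, "true_index")
#' @export
simulate_mediation_dataset <- function(dgp = mediation_dgp()) {
  stopifnot(inherits(dgp, "mediation_dgp"))
  with_local_seed(dgp$seed, {
    n <- dgp$n
    x <- stats::rnorm(n)
    age <- stats::runif(n, 50, 88)
    wc <- age - mean(age)
    sex <- stats::rbinom(n, 1, 0.5)
    presma <- stats::rnorm(n)
    rifg <- stats::rnorm(n)
    total_gm <- 0.5 * (presma + rifg) + stats::rnorm(n, 0, 0.7)
    m <- dgp$a0 + dgp$a1 * x + stats::rnorm(n, 0, dgp$sd_m)
    y <- dgp$b0 + dgp$c1 * x + dgp$b1 * m + dgp$b2 * m * wc + dgp$c2 * x * wc +
      dgp$g * wc + dgp$beta_sex * sex + dgp$beta_vol * (presma + rifg) +
      stats::rnorm(n, 0, dgp$sd_y)
    out <- tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n)),
      lc_cnr_resid = x, connectivity = m, age = age, ssrt = y,
      sex = sex, presma_vol = presma, rifg_vol = rifg, total_gm_vol = total_gm
    )
    attr(out, "true_index") <- dgp$a1 * dgp$b2
    attr(out, "dgp") <- dgp
    out
  })
}
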