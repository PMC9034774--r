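#' Reaction-time exclusions before model fitting
#'
#' Applies the standard RT cleaning used before fitting the race model:
#' implausibly fast responses (RT < 0.25 s) are removed on every trial type,
#' and go RTs further than 2.5 standard deviations from the participant's
#' mean go RT are removed. The SD rule is computed per participant on the
#' go RTs that survive the fast rule.
#'
#' @param trials trial table (may contain several participants).
#' @param fast_cutoff fast-RT cutoff in seconds (default 0.25).
#' @param sd_mult outlier multiplier for go RTs (default 2.5).
#' @return list with `trials` (filtered tibble) and `report` (tibble with
#'   per-participant counts removed by each rule).
#' @examples
#' d <- tibble::tibble(participant_id = "p1", trial_index = 1:3,
#'   trial_type = "go", direction = "left", ssd_s = NA_real_,
#'   response = "left", rt_s = c(0.10, 0.50, 0.52))
#' preprocess_rts(d)$report
#' @export
preprocess_rts <- function(trials, fast_cutoff = 0.25, sd_mult = 2.5) {
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  if (!"rt_s" %in% names(trials)) stop("trial table lacks an rt_s column", call. = FALSE)

  fast <- !is.na(trials$rt_s) & trials$rt_s < fast_cutoff
  kept <- trials[!fast, , drop = FALSE]

  out <- kept |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      is_go_rt <- df$trial_type == "go" & !is.na(df$rt_s)
      m <- mean(df$rt_s[is_go_rt])
      s <- stats::sd(df$rt_s[is_go_rt])
      # a single go RT (or identical RTs) gives sd 0/NA: nothing excluded
      if (is.na(s)) s <- 0
      slow <- is_go_rt & s > 0 & abs(df$rt_s - m) > sd_mult * s
      df$.excl_sd <- slow
      df
    }) |>
    dplyr::ungroup()

  report <- tibble::tibble(
    participant_id = unique(trials$participant_id)
  ) |>
    dplyr::left_join(
      trials[fast, , drop = FALSE] |> dplyr::count(.data$participant_id, name = "n_fast"),
      by = "participant_id") |>
    dplyr::left_join(
      out[out$.excl_sd, , drop = FALSE] |> dplyr::count(.data$participant_id, name = "n_sd_outlier"),
      by = "participant_id") |>
    dplyr::mutate(n_fast = dplyr::coalesce(.data$n_fast, 0L),
                  n_sd_outlier = dplyr::coalesce(.data$n_sd_outlier, 0L),
                  n_removed = .data$n_fast + .data$n_sd_outlier)

  list(trials = dplyr::select(out[!out$.excl_sd, , drop = FALSE], -".excl_sd"),
       report = report)
}

#' Behavioural quality control for one participant
#'
#' Consensus-style inclusion checks for stop-signal data: (1) accuracy of
#' the two-alternative choice on go trials must be above chance by a
#' one-sided exact binomial test at `alpha`; (2) the proportion of
#' commission errors, p(response | stop signal), must lie within
#' `[0.25, 0.75]` (bounds inclusive).
#'
#' @param trials trial table for a single participant, containing go and
#'   stop trials.
#' @param alpha significance level of the exact binomial test (default 0.05).
#' @return list with `pass` (logical), `reasons` (character), `go_accuracy`,
#'   `p_respond_signal`, and the binomial p-value.
#' @export
qc_participant <- function(trials, alpha = 0.05) {
  trials <- tibble::as_tibble(trials)
  is_go <- trials$trial_type == "go"
  is_stop <- trials$trial_type %in% c("stop", "nogo")
  if (!any(is_stop)) stop("no stop trials: cannot assess stopping behaviour", call. = FALSE)
  if (!any(is_go)) stop("no go trials: cannot assess choice accuracy", call. = FALSE)

  responded_go <- is_go & !is.na(trials$response)
  n_resp <- sum(responded_go)
  n_correct <- sum(responded_go & trials$response == trials$direction)
  acc <- if (n_resp > 0) n_correct / n_resp else NA_real_
  p_binom <- if (n_resp > 0) {
    stats::binom.test(n_correct, n_resp, p = 0.5, alternative = "greater")$p.value
  } else 1

  p_resp_signal <- mean(!is.na(trials$response[is_stop]))

  reasons <- character(0)
  if (!(p_binom < alpha)) {
    reasons <- c(reasons, sprintf(
      "go accuracy %.3f not above chance (exact binomial p = %.3f)", acc, p_binom))
  }
  if (p_resp_signal < 0.25 || p_resp_signal > 0.75) {
    reasons <- c(reasons, sprintf(
      "p(response|signal) = %.3f outside [0.25, 0.75]", p_resp_signal))
  }
  list(pass = length(reasons) == 0, reasons = reasons,
       go_accuracy = acc, p_respond_signal = p_resp_signal,
       binom_p = p_binom)
}
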