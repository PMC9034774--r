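#' Stop-signal session design
#'
#' Build the ordered trial layout of a stop-signal task (SST) session:
#' go trials, stop-signal trials and no-go trials in a seeded random
#' interleaving. Left/right go-stimulus directions are balanced within each
#' trial type (to within one trial when the count is odd). No-go trials are
#' treated as stop trials with a nominal stop-signal delay of 5 ms.
#'
#' The defaults mirror a two-run scanner session: 360 go, 80 stop and 40
#' no-go trials.
#'
#' @param n_go,n_stop,n_nogo non-negative trial counts.
#' @param seed integer seed for the interleaving permutation.
#' @return a tibble of class `sst_design` with columns `trial_index`,
#'   `trial_type` (`"go"`, `"stop"`, `"nogo"`) and `direction` (`"left"`,
#'   `"right"`), and attributes `n_go`, `n_stop`, `n_nogo`.
#' @examples
#' design <- make_session_design(360, 80, 40, seed = 1)
#' dplyr::count(design, trial_type)
#' @export
make_session_design <- function(n_go = 360, n_stop = 80, n_nogo = 40, seed = 1) {
  counts <- c(n_go = n_go, n_stop = n_stop, n_nogo = n_nogo)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("trial counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("empty design: at least one trial count must be positive", call. = FALSE)
  }
  types <- rep(c("go", "stop", "nogo"), times = counts)
  # balanced directions within type (difference at most 1 for odd counts)
  dir_for <- function(n) {
    if (n == 0) return(character(0))
    d <- rep(c("left", "right"), length.out = n)
    d
  }
  dirs <- unlist(lapply(counts, dir_for), use.names = FALSE)
  out <- with_local_seed(seed, {
    ord <- sample.int(length(types))
    tibble::tibble(
      trial_index = seq_along(types),
      trial_type  = types[ord],
      direction   = dirs[ord]
    )
  })
  attr(out, "n_go") <- as.integer(n_go)
  attr(out, "n_stop") <- as.integer(n_stop)
  attr(out, "n_nogo") <- as.integer(n_nogo)
  class(out) <- c("sst_design", class(out))
  out
}

#' Nominal stop-signal delay assigned to no-go trials (seconds)
#'
#' No-go trials (stop signal present from stimulus onset) are modelled as
#' stop trials with a 5-ms nominal delay.
#' @export
NOGO_SSD <- 0.005

#' Staircase configuration for the stop-signal delay
#'
#' One-up/one-down tracking of the stop-signal delay (SSD): after a
#' successful stop the SSD increases by `step` (stopping becomes harder),
#' after a failed stop it decreases by `step`, clamped to
#' `[min_ssd, max_ssd]`. A 50-ms step targets 50% successful stopping.
#'
#' @param initial_ssd starting SSD in seconds.
#' @param step staircase step in seconds (default 0.05).
#' @param min_ssd,max_ssd clamping bounds in seconds.
#' @return a list of class `staircase_config`.
#' @examples
#' staircase_config()
#' @export
staircase_config <- function(initial_ssd = 0.25, step = 0.05,
                             min_ssd = 0, max_ssd = 0.9) {
  if (!(min_ssd <= initial_ssd && initial_ssd <= max_ssd) || min_ssd < 0) {
    stop("require 0 <= min_ssd <= initial_ssd <= max_ssd", call. = FALSE)
  }
  if (step < 0) stop("step must be >= 0", call. = FALSE)
  structure(list(initial_ssd = initial_ssd, step = step,
                 min_ssd = min_ssd, max_ssd = max_ssd),
            class = "staircase_config")
}
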