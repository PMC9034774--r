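#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom Rcpp evalCpp
#' @useDynLib lcsst, .registration = TRUE
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps every generator reproducible
# without clobbering the session RNG.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + 97 * as.double(stream)) %% 2147483587
}

probit <- function(p) stats::qnorm(p)
inv_probit <- function(z) stats::pnorm(z)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a stop-signal trial table
#'
#' Checks the column contract used throughout the package (`participant_id`,
#' `trial_index`, `trial_type`, `direction`, `ssd_s`, `response`, `rt_s`) and
#' cell-level consistency. On failure the error names the offending row and
#' column.
#'
#' @param trials a data frame of trials.
#' @return the validated table, invisibly (as a tibble).
#' @export
validate_trial_table <- function(trials) {
  trials <- tibble::as_tibble(trials)
  needed <- c("participant_id", "trial_index", "trial_type", "direction",
              "ssd_s", "response", "rt_s")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cell <- function(col, bad) {
    if (any(bad)) {
      row <- which(bad)[1]
      stop(sprintf("invalid trial table value at row %d, column '%s'", row, col),
           call. = FALSE)
    }
  }
  bad_cell("trial_type", !trials$trial_type %in% c("go", "stop", "nogo"))
  bad_cell("direction", !trials$direction %in% c("left", "right"))
  bad_cell("ssd_s", !(is.na(trials$ssd_s) | (is.finite(trials$ssd_s) & trials$ssd_s >= 0)))
  bad_cell("response", !(is.na(trials$response) | trials$response %in% c("left", "right")))
  bad_cell("rt_s", !(is.na(trials$rt_s) | (is.finite(trials$rt_s) & trials$rt_s > 0)))
  bad_cell("rt_s", !is.na(trials$response) & is.na(trials$rt_s))
  bad_cell("response", is.na(trials$response) & !is.na(trials$rt_s))
  invisible(trials)
}
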