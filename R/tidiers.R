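#' Tidy a moderated-regression fit
#'
#' @param x an `lc_regression`.
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `statistic`, `df`, `p_value`, `partial_eta2`, `vif`.
#' @method tidy lc_regression
#' @export
tidy.lc_regression <- function(x, ...) {
  out <- x$terms
  out$vif <- c(NA_real_, unname(x$vif))[match(out$term, c("(Intercept)", names(x$vif)))]
  out
}

#' Model-level summary of a moderated-regression fit
#'
#' @param x an `lc_regression`.
#' @param ... unused.
#' @return one-row tibble: `r_squared`, `n`, `df_residual`, `max_vif`,
#'   `max_cooks`, `cook_cutoff`, `n_influential`, `method`.
#' @method glance lc_regression
#' @export
glance.lc_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    n = x$n,
    df_residual = x$fit$df.residual %||% (x$n - nrow(x$terms)),
    max_vif = max(x$vif),
    max_cooks = if (is.null(x$cooks)) NA_real_ else max(x$cooks),
    cook_cutoff = x$cook_cutoff,
    n_influential = if (is.null(x$cooks)) NA_integer_ else
      sum(x$cooks > x$cook_cutoff),
    method = x$method
  )
}

#' @export
print.lc_regression <- function(x, ...) {
  cat(sprintf("Moderated regression (%s): %s ~ %s * %s%s, n = %d\n",
              x$method, x$outcome, x$focal, x$moderator,
              if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              x$n))
  print(x$terms)
  invisible(x)
}

#' Tidy a hierarchical race-model fit
#'
#' Posterior summaries (mean, median, 95% quantile interval) of every
#' group-level parameter.
#'
#' @param x an `sst_fit`.
#' @param ... unused.
#' @method tidy sst_fit
#' @export
tidy.sst_fit <- function(x, ...) {
  ga <- x$group
  purrr::map_dfr(dimnames(ga)[[3]], function(nm) {
    v <- as.vector(ga[, , nm])
    tibble::tibble(parameter = nm, mean = mean(v), median = stats::median(v),
                   q025 = stats::quantile(v, 0.025, names = FALSE),
                   q975 = stats::quantile(v, 0.975, names = FALSE))
  })
}

#' Fit-level summary of a hierarchical race-model fit
#'
#' @param x an `sst_fit`.
#' @param ... unused.
#' @method glance sst_fit
#' @export
glance.sst_fit <- function(x, ...) {
  tibble::tibble(
    n_participants = length(x$participants),
    n_chains = dim(x$group)[1],
    n_draws = dim(x$group)[2],
    burn_iterations = x$burn_iterations,
    max_rhat_group = max(x$rhat_group),
    converged = x$converged
  )
}

#' Tidy a moderated-mediation result
#'
#' Path coefficients plus the index of moderated mediation with its
#' bootstrap interval.
#'
#' @param x an `lc_mediation`.
#' @param ... unused.
#' @method tidy lc_mediation
#' @export
tidy.lc_mediation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::rename(x$paths, term = "path", boot_lo = "boot_lo", boot_hi = "boot_hi"),
    tibble::tibble(term = "index", estimate = x$index$estimate,
                   std_error = NA_real_, boot_lo = x$index$ci[1],
                   boot_hi = x$index$ci[2])
  )
}

#' Result-level summary of a moderated-mediation fit
#'
#' @param x an `lc_mediation`.
#' @param ... unused.
#' @method glance lc_mediation
#' @export
glance.lc_mediation <- function(x, ...) {
  tibble::tibble(
    index = x$index$estimate, index_lo = x$index$ci[1],
    index_hi = x$index$ci[2], index_p = x$index$p,
    proportion_moderated = x$proportion_moderated,
    n = x$n, n_boot = x$n_boot, n_redrawn = x$n_redrawn
  )
}
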