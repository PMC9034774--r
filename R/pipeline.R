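#' End-to-end run configuration
#'
#' One nested configuration driving [run_all()]: simulate a behavioural
#' cohort, preprocess and fit the race model, extract phantom CNR, and run
#' the inferential layer. Every stochastic stage carries an explicit seed
#' derived from `seed`. The configuration round-trips through YAML
#' unchanged (see [read_run_config()]).
#'
#' @param seed master integer seed.
#' @param design list with `n_go`, `n_stop`, `n_nogo`.
#' @param staircase list with `initial_ssd`, `step`, `min_ssd`, `max_ssd`.
#' @param cohort list with `n_participants`.
#' @param fit list of [fit_config()] arguments (e.g. `n_chains`, `thin`,
#'   `n_keep`, `burn_max`).
#' @param phantom list with `noise_sd` and optional `offset_sd` (SD of the
#'   per-participant jitter applied to the subregion offsets).
#' @param analysis list with `n` (covariate-table size) and `n_boot`.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       design = list(n_go = 360, n_stop = 80, n_nogo = 40),
                       staircase = list(initial_ssd = 0.25, step = 0.05,
                                        min_ssd = 0, max_ssd = 0.9),
                       cohort = list(n_participants = 8),
                       fit = list(n_chains = 24, thin = 2, n_keep = 150,
                                  burn_max = 1000),
                       phantom = list(noise_sd = 5, offset_sd = 0.5),
                       analysis = list(n = 200, n_boot = 2000)) {
  cfg <- list(seed = seed, design = design, staircase = staircase,
              cohort = cohort, fit = fit, phantom = phantom,
              analysis = analysis)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  need <- list(
    seed = character(0),
    design = c("n_go", "n_stop", "n_nogo"),
    staircase = c("initial_ssd", "step", "min_ssd", "max_ssd"),
    cohort = "n_participants",
    fit = character(0),
    phantom = "noise_sd",
    analysis = c("n", "n_boot")
  )
  for (top in names(need)) {
    if (is.null(cfg[[top]])) stop("run config missing field: ", top, call. = FALSE)
    for (sub in need[[top]]) {
      if (is.null(cfg[[top]][[sub]])) {
        stop("run config missing field: ", top, "$", sub, call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns the path invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_result <- function(status, outputs = character(0), error = NULL, info = list()) {
  list(status = status, outputs = outputs, error = error, info = info)
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: (1) session design and cohort simulation with known
#' ground truth; (2) RT preprocessing and behavioural QC; (3) hierarchical
#' race-model fit with convergence diagnostics and SSRT posteriors; (4)
#' per-participant brainstem phantoms and CNR extraction; (5) the
#' inferential layer (moderated regression, interaction Bayes factor,
#' moderated mediation) on a path-model covariate table. Stages communicate
#' only through files in `out_dir`, so each can be audited or re-run; the
#' pipeline halts at the first failing stage and returns a partial report.
#' Identical configuration and seeds reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return list of class `lc_run_report`: per-stage status and outputs with
#'   MD5 hashes, QC outcomes, convergence flag and a headline-statistics
#'   table. Also written to `run_report.json`.
#' @export
run_all <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  headline <- list()
  qc_out <- NULL
  halt <- FALSE
  seed <- config$seed
  pth <- function(f) file.path(out_dir, f)

  run_stage <- function(name, fun) {
    if (halt) {
      stages[[name]] <<- stage_result("skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- stage_result("error", error = conditionMessage(res))
      halt <<- TRUE
      message("stage '", name, "' failed: ", conditionMessage(res))
    } else {
      stages[[name]] <<- res
    }
    invisible(NULL)
  }

  run_stage("simulate", function() {
    design <- make_session_design(config$design$n_go, config$design$n_stop,
                                  config$design$n_nogo,
                                  seed = child_seed(seed, 1))
    sc <- staircase_config(config$staircase$initial_ssd, config$staircase$step,
                           config$staircase$min_ssd, config$staircase$max_ssd)
    cohort <- simulate_cohort(group_hyperparams(), config$cohort$n_participants,
                              design, sc, seed = child_seed(seed, 2))
    readr::write_csv(cohort$trials, pth("trials.csv"))
    readr::write_csv(cohort$true_params, pth("true_params.csv"))
    stage_result("ok", c("trials.csv", "true_params.csv"),
                 info = list(n_trials = nrow(cohort$trials)))
  })

  run_stage("preprocess", function() {
    trials <- readr::read_csv(pth("trials.csv"), show_col_types = FALSE,
                              progress = FALSE)
    validate_trial_table(trials)
    pp <- preprocess_rts(trials)
    qc <- split(pp$trials, pp$trials$participant_id) |>
      purrr::imap(function(tt, id) {
        q <- qc_participant(tt)
        list(participant_id = id, pass = q$pass, reasons = q$reasons,
             go_accuracy = q$go_accuracy, p_respond_signal = q$p_respond_signal)
      })
    qc_out <<- qc
    readr::write_csv(pp$trials, pth("trials_clean.csv"))
    readr::write_csv(pp$report, pth("rt_exclusions.csv"))
    jsonlite::write_json(qc, pth("qc.json"), auto_unbox = TRUE, pretty = TRUE)
    stage_result("ok", c("trials_clean.csv", "rt_exclusions.csv", "qc.json"),
                 info = list(n_pass = sum(vapply(qc, `[[`, logical(1), "pass"))))
  })

  run_stage("fit", function() {
    trials <- readr::read_csv(pth("trials_clean.csv"), show_col_types = FALSE,
                              progress = FALSE)
    fc_args <- config$fit
    fc_args$seed <- child_seed(seed, 3)
    fc <- do.call(fit_config, fc_args)
    fit <- suppressWarnings(fit_hierarchical(trials, fc))
    der <- derive_outcomes(fit)
    readr::write_csv(der$summary, pth("ssrt_summary.csv"))
    conv <- list(converged = fit$converged,
                 max_rhat_group = max(fit$rhat_group),
                 burn_iterations = fit$burn_iterations)
    jsonlite::write_json(conv, pth("convergence.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    headline$group_ssrt_median <<-
      der$group_summary$median[der$group_summary$measure == "ssrt"]
    headline$max_rhat_group <<- max(fit$rhat_group)
    stage_result("ok", c("ssrt_summary.csv", "convergence.json"), info = conv)
  })

  run_stage("cnr", function() {
    n <- config$cohort$n_participants
    offset_sd <- config$phantom$offset_sd %||% 0
    base_offsets <- c(caudal = 4, middle = 5, rostral = 6)
    rows <- with_local_seed(child_seed(seed, 4), {
      purrr::map_dfr(seq_len(n), function(i) {
        off <- pmax(base_offsets + stats::rnorm(3, 0, offset_sd), 0.5)
        # reference SD set equal to the noise SD so the configured offsets
        # are the true CNR values of the noisy phantom
        ph <- make_phantom(phantom_spec(offsets = off,
                                        ref_sd = config$phantom$noise_sd,
                                        noise_sd = config$phantom$noise_sd,
                                        seed = child_seed(seed, 100 + i)))
        st <- reference_stats(ph$volume, ph$ref_mask)
        cn <- cnr_map(ph$volume, st)
        summ <- extract_summary(cn, ph$lc_mask, ph$subregions, ph$volume, st)
        dplyr::mutate(summ, participant_id = sprintf("p%02d", i),
                      true_caudal = off[["caudal"]], true_middle = off[["middle"]],
                      true_rostral = off[["rostral"]], .before = 1)
      })
    })
    readr::write_csv(rows, pth("cnr_summary.csv"))
    stage_result("ok", "cnr_summary.csv",
                 info = list(mean_abs_err = mean(abs(
                   c(rows$cnr_caudal - rows$true_caudal,
                     rows$cnr_middle - rows$true_middle,
                     rows$cnr_rostral - rows$true_rostral)))))
  })

  run_stage("analyze", function() {
    tab <- simulate_mediation_dataset(mediation_dgp(
      n = config$analysis$n, seed = child_seed(seed, 5)))
    reg <- fit_moderated_regression(tab, "ssrt", "lc_cnr_resid", "age",
                                    c("sex", "presma_vol", "rifg_vol"))
    bf <- jzs_bf(dplyr::mutate(tab,
                               .inter = (tab$lc_cnr_resid - mean(tab$lc_cnr_resid)) *
                                 (tab$age - mean(tab$age))),
                 "ssrt",
                 c("lc_cnr_resid", "age", ".inter", "sex", "presma_vol", "rifg_vol"),
                 c("lc_cnr_resid", "age", "sex", "presma_vol", "rifg_vol"))
    med <- moderated_mediation(tab, n_boot = config$analysis$n_boot,
                               seed = child_seed(seed, 6))
    readr::write_csv(tidy(reg), pth("regression_terms.csv"))
    jsonlite::write_json(
      list(paths = med$paths, index = med$index,
           conditional = med$conditional, n = med$n, n_boot = med$n_boot,
           interaction_bf10 = bf$bf10),
      pth("mediation.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    headline$interaction_bf10 <<- bf$bf10
    headline$mediation_index <<- med$index$estimate
    headline$mediation_index_ci <<- med$index$ci
    stage_result("ok", c("regression_terms.csv", "mediation.json"),
                 info = list(interaction_bf10 = bf$bf10,
                             index = med$index$estimate))
  })

  all_outputs <- unlist(lapply(stages, `[[`, "outputs"), use.names = FALSE)
  hashes <- as.list(tools::md5sum(file.path(out_dir, all_outputs)))
  names(hashes) <- all_outputs
  report <- structure(list(
    config = unclass(config),
    stages = stages,
    file_hashes = hashes,
    qc = qc_out,
    headline = headline,
    completed = !halt
  ), class = "lc_run_report")
  jsonlite::write_json(report, pth("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  report
}

#' @export
print.lc_run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %s%s\n", nm, s$status,
                if (!is.null(s$error)) paste0(" (", s$error, ")") else ""))
  }
  if (length(x$headline)) {
    cat("Headline statistics:\n")
    for (nm in names(x$headline)) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(signif(unlist(x$headline[[nm]]), 5), collapse = ", ")))
    }
  }
  invisible(x)
}
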