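# Config-driven pipeline: exclusions -> scoring -> recalibration ->
# evaluation -> cross-validation, with a machine-readable run manifest.

#' Run the full analysis pipeline
#'
#' Replicates the analysis flow on one or more cohorts: eligibility
#' exclusions and horizon censoring; 10-year ASCVD risk by the original
#' equation; recalibration-in-the-large on the pooled training stratum;
#' the mortality equation on its own exclusion set; evaluation per stratum
#' (each cohort and pooled, by total/men/women); k-fold cross-validation
#' of the recalibration; and a JSON run manifest.
#'
#' The run configuration is a JSON file (or an equivalent list) with
#' fields: `cohorts` (array of `{file, label}` or
#' `{simulate, label, n, true_model, seed_offset}` where `simulate` is
#' `"kora_like"`, `"hnr_like"` or a simulation-config JSON path),
#' optional `pce_coeffs` / `esc_coeffs` paths, `horizon` (default 10),
#' `recalibration` (`{training: "pooled", mode: "logit"}`), `evaluation`
#' (`{freq_method, bootstrap_B, cv_k}`), and `seed`.
#'
#' @param config path to a run-config JSON file, or a list.
#' @param out_dir output directory (created if absent).
#' @param seed overrides the config seed when given.
#' @return invisibly, a list with the report data frame, per-stratum
#'   calibration tables, the fitted recalibrated equation and the CV
#'   summary.
#' @export
run_analysis <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("run config not found: ", config, call. = FALSE)
    }
    jsonlite::read_json(config, simplifyVector = FALSE)
  } else config
  if (is.null(cfg$cohorts) || length(cfg$cohorts) == 0L) {
    stop("run config must list at least one cohort", call. = FALSE)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  horizon <- if (is.null(cfg$horizon)) 10 else as.numeric(cfg$horizon)
  ev_opts <- cfg$evaluation
  B <- if (is.null(ev_opts$bootstrap_B)) 0L else as.integer(ev_opts$bootstrap_B)
  cv_k <- if (is.null(ev_opts$cv_k)) 10L else as.integer(ev_opts$cv_k)
  freq_method <- if (is.null(ev_opts$freq_method)) "crude" else
    ev_opts$freq_method
  recal_mode <- if (is.null(cfg$recalibration$mode)) "logit" else
    cfg$recalibration$mode

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pce_cf <- if (is.null(cfg$pce_coeffs)) read_pce_coeffs() else {
    if (!file.exists(cfg$pce_coeffs)) {
      stop("coefficient file not found: ", cfg$pce_coeffs, call. = FALSE)
    }
    read_pce_coeffs(cfg$pce_coeffs)
  }
  esc_cf <- if (is.null(cfg$esc_coeffs)) read_esc_coeffs() else {
    if (!file.exists(cfg$esc_coeffs)) {
      stop("coefficient file not found: ", cfg$esc_coeffs, call. = FALSE)
    }
    read_esc_coeffs(cfg$esc_coeffs)
  }
  eq_pce <- pce_equation(pce_cf)
  eq_esc <- esc_equation(esc_cf)

  raw <- lapply(seq_along(cfg$cohorts), function(i) {
    .load_run_cohort(cfg$cohorts[[i]], base_seed = cfg$seed, index = i)
  })
  labels <- vapply(raw, cohort_name, character(1))
  if (anyDuplicated(labels)) stop("cohort labels must be unique",
                                  call. = FALSE)

  asc <- lapply(raw, function(x) {
    censor_at_horizon(apply_exclusions(x, exclusion_config()), horizon)
  })
  esc <- lapply(raw, function(x) {
    censor_at_horizon(apply_exclusions(x, esc_exclusion_config()), horizon)
  })
  pooled_asc <- .pool_cohorts(asc, "pooled")
  pooled_esc <- .pool_cohorts(esc, "pooled")

  eq_recal <- recalibrate_equation(eq_pce, pooled_asc, endpoint = "ascvd",
                                   mode = recal_mode,
                                   id = "pce_recalibrated")
  write_equation(eq_recal, file.path(out_dir, "pce_recalibrated.json"))

  strata <- function(cohorts, pooled) {
    out <- list()
    for (x in c(list(pooled), cohorts)) {
      lab <- cohort_name(x)
      out[[paste0(lab, "_total")]] <- x
      df <- as.data.frame(x)
      out[[paste0(lab, "_men")]] <-
        cohort(df[df$sex == "M", ], name = paste0(lab, "_men"))
      out[[paste0(lab, "_women")]] <-
        cohort(df[df$sex == "F", ], name = paste0(lab, "_women"))
    }
    out
  }
  asc_strata <- strata(asc, pooled_asc)
  esc_strata <- strata(esc, pooled_esc)

  reports <- list()
  calibs <- list()
  run_eval <- function(x, eq, endpoint, stratum, tag) {
    r <- tryCatch(
      evaluation_report(x, eq, endpoint = endpoint, horizon = horizon,
                        stratum = stratum, B = B,
                        seed = cfg$seed + 17L, freq_method = freq_method),
      error = function(e) {
        stop("evaluation failed at stage '", tag, "', stratum '", stratum,
             "': ", conditionMessage(e), call. = FALSE)
      })
    fname <- file.path(out_dir,
                       sprintf("calibration_%s_%s.csv", stratum, tag))
    write_calibration(r$calibration, fname)
    ro <- roc_export(predict_risk(eq, x)$risk10,
                     .endpoint_events(x, endpoint),
                     path = file.path(out_dir,
                                      sprintf("roc_%s_%s.csv", stratum,
                                              tag)))
    calibs[[paste(stratum, tag, sep = ":")]] <<- r$calibration
    reports[[length(reports) + 1L]] <<- r
    invisible(r)
  }
  for (nm in names(asc_strata)) {
    run_eval(asc_strata[[nm]], eq_pce, "ascvd", nm, "pce_original")
    run_eval(asc_strata[[nm]], eq_recal, "ascvd", nm, "pce_recalibrated")
  }
  for (nm in names(esc_strata)) {
    run_eval(esc_strata[[nm]], eq_esc, "cv_death", nm, "esc")
  }
  table2 <- write_report_table(reports, file.path(out_dir, "report.csv"))

  cv <- kfold_cross_validate(pooled_asc, eq_pce, k = cv_k,
                             seed = cfg$seed + 29L, endpoint = "ascvd",
                             mode = recal_mode)
  utils::write.csv(cv$folds, file.path(out_dir, "cv_folds.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cv$pooled, file.path(out_dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "cvrecal",
    version = as.character(utils::packageVersion("cvrecal")),
    seed = cfg$seed,
    horizon = horizon,
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    cohorts = labels,
    recalibration = list(
      correction = eq_recal$recalibration$correction,
      observed_freq = eq_recal$recalibration$observed_freq,
      mean_pred = eq_recal$recalibration$mean_pred,
      mode = recal_mode))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = table2, calibration = calibs,
                 recalibrated = eq_recal, cv = cv))
}

.load_run_cohort <- function(entry, base_seed, index) {
  if (!is.null(entry$file)) {
    if (!file.exists(entry$file)) {
      stop("cohort file not found: ", entry$file, call. = FALSE)
    }
    x <- read_cohort(entry$file, name = entry$label)
    return(x)
  }
  if (is.null(entry$simulate)) {
    stop("cohort entry needs either a file or a simulate preset",
         call. = FALSE)
  }
  scfg <- switch(entry$simulate,
    kora_like = kora_like_config(),
    hnr_like = hnr_like_config(),
    read_sim_config(entry$simulate))
  if (!is.null(entry$n)) scfg$n <- as.integer(entry$n)
  if (!is.null(entry$true_model)) {
    tm <- as.list(entry$true_model)
    if (!is.null(tm$theta)) tm$theta <- unlist(tm$theta)
    scfg$true_model <- tm
  }
  if (!is.null(entry$censoring)) scfg$censoring <- entry$censoring
  offset <- if (is.null(entry$seed_offset)) index else entry$seed_offset
  x <- simulate_cohort(scfg, seed = base_seed + 1000L * offset)
  if (!is.null(entry$label)) {
    x <- cohort(as.data.frame(x), name = entry$label)
  }
  x
}

.pool_cohorts <- function(cohorts, name) {
  dfs <- lapply(cohorts, function(x) {
    df <- as.data.frame(x)
    df$subject_id <- paste(cohort_name(x), df$subject_id, sep = "/")
    df
  })
  cohort(do.call(rbind, dfs), name = name)
}
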