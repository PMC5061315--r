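# Calibration and discrimination metrics: observed frequency, incidence
# rate, overestimation %, decile calibration, Harrell's C, ROC export.

#' Observed event frequency at the horizon
#'
#' Default estimator is the crude proportion of subjects with an event
#' within the horizon. `method = "km"` returns one minus the product-limit
#' (Kaplan-Meier) survival at the horizon, which adjusts for censoring
#' before the horizon.
#'
#' @param x a [cohort()] with horizon censoring applied.
#' @param endpoint `"ascvd"` or `"cv_death"`.
#' @param horizon horizon in years (default 10).
#' @param method `"crude"` (default) or `"km"`.
#' @return probability.
#' @export
observed_event_frequency <- function(x, endpoint = c("ascvd", "cv_death"),
                                     horizon = 10,
                                     method = c("crude", "km")) {
  stopifnot(inherits(x, "cohort"))
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  if (nrow(x) == 0L) stop("cohort is empty", call. = FALSE)
  ev <- .endpoint_events(x, endpoint)
  if (method == "crude") return(mean(ev))
  tcol <- if (endpoint == "ascvd") "fu_ascvd_years" else "fu_cvdeath_years"
  tt <- as.data.frame(x)[[tcol]]
  fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  s <- summary(fit, times = min(horizon, max(tt)), extend = TRUE)$surv
  1 - s
}

#' Incidence rate per 1,000 person-years
#'
#' Number of incident events divided by the sum of person-years of all
#' subjects at risk, times 1,000.
#'
#' @inheritParams observed_event_frequency
#' @return events per 1,000 person-years.
#' @export
incidence_rate <- function(x, endpoint = c("ascvd", "cv_death"),
                           horizon = 10) {
  stopifnot(inherits(x, "cohort"))
  endpoint <- match.arg(endpoint)
  ev <- .endpoint_events(x, endpoint)
  tcol <- if (endpoint == "ascvd") "fu_ascvd_years" else "fu_cvdeath_years"
  tt <- as.data.frame(x)[[tcol]]
  if (anyNA(tt)) stop("follow-up times must be known", call. = FALSE)
  py <- sum(pmin(tt, horizon))
  if (py <= 0) stop("total person-years is zero", call. = FALSE)
  1000 * sum(ev) / py
}

#' Overestimation percentage
#'
#' `[(estimated rate / observed rate) - 1] * 100`. Positive values indicate
#' overestimation of the observed event rate, negative values
#' underestimation.
#'
#' @param estimated,observed rates on a common scale (e.g. percent); the
#'   observed rate must be positive.
#' @return percentage.
#' @export
overestimation_pct <- function(estimated, observed) {
  if (any(observed <= 0)) {
    stop("observed rate must be positive", call. = FALSE)
  }
  (estimated / observed - 1) * 100
}

#' Decile calibration table
#'
#' Ranks subjects by predicted risk and splits them into (up to) ten
#' groups at the sample deciles of the prediction distribution, keeping
#' tied predictions in one group; reports per-group size, mean prediction
#' and observed event frequency, plus a totals row. `n_se` columns give the
#' binomial Monte-Carlo standard error of the observed frequency under the
#' group's mean prediction.
#'
#' @param risk10 predicted risks.
#' @param event logical events by the horizon, aligned with `risk10`.
#' @param groups number of quantile groups (default 10).
#' @return a `calibration_table`: data frame with columns `decile`, `n`,
#'   `mean_pred`, `observed_freq`, `se_pred`; attribute `ties` flags
#'   collapsed groups; the totals row has `decile = "total"`.
#' @export
calibration_deciles <- function(risk10, event, groups = 10) {
  n <- length(risk10)
  if (n != length(event)) stop("inputs must be aligned", call. = FALSE)
  if (n < groups) {
    stop("need at least ", groups, " subjects for ", groups,
         "-tile calibration; got ", n, call. = FALSE)
  }
  qs <- stats::quantile(risk10, probs = seq_len(groups - 1L) / groups,
                        type = 2, names = FALSE)
  breaks <- unique(c(-Inf, qs, Inf))
  grp <- cut(risk10, breaks = breaks, labels = FALSE, right = TRUE)
  k <- max(grp)
  rows <- lapply(seq_len(k), function(g) {
    idx <- grp == g
    mp <- mean(risk10[idx])
    data.frame(decile = as.character(g), n = sum(idx), mean_pred = mp,
               observed_freq = mean(event[idx]),
               se_pred = sqrt(mp * (1 - mp) / sum(idx)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(decile = "total", n = n, mean_pred = mean(risk10),
                      observed_freq = mean(event),
                      se_pred = sqrt(mean(risk10) * (1 - mean(risk10)) / n),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  structure(out, class = c("calibration_table", "data.frame"),
            ties = k < groups, groups_requested = groups,
            groups_effective = k)
}

#' Harrell's concordance statistic for censored data
#'
#' Over all subject pairs, a pair is usable iff the smaller observed time
#' belongs to a subject with an event; ties in time where both subjects
#' have events are usable, ties where only one is an event are not. A
#' usable pair is concordant when the earlier-event subject has the higher
#' prediction; prediction ties count 0.5.
#' `C = (concordant + 0.5 * ties) / usable`.
#'
#' The confidence interval (when `B > 0`) is a seeded nonparametric
#' bootstrap over subjects, percentile method.
#'
#' @param risk10 predicted risks (any strictly increasing transform gives
#'   the same C).
#' @param time observed follow-up times.
#' @param event logical event indicators.
#' @param B bootstrap replicates for the CI (default 0: no CI).
#' @param seed seed for the bootstrap (required when `B > 0`).
#' @param conf confidence level (default 0.95).
#' @return list with `c`, `usable`, `concordant`, `tied`, and (when
#'   `B > 0`) `ci_low`, `ci_high`.
#' @export
harrells_c <- function(risk10, time, event, B = 0, seed = NULL,
                       conf = 0.95) {
  n <- length(risk10)
  if (length(time) != n || length(event) != n) {
    stop("inputs must be aligned", call. = FALSE)
  }
  if (anyNA(risk10) || anyNA(time) || anyNA(event)) {
    stop("inputs must be fully observed", call. = FALSE)
  }
  res <- .concordance_counts(risk10, time, event)
  if (res$usable == 0) {
    stop("no usable pairs (need at least one event before another ",
         "subject's time)", call. = FALSE)
  }
  out <- list(c = (res$concordant + 0.5 * res$tied) / res$usable,
              usable = res$usable, concordant = res$concordant,
              tied = res$tied)
  if (B > 0) {
    if (is.null(seed)) stop("seed required for bootstrap CI", call. = FALSE)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    cb <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- .concordance_counts(risk10[idx], time[idx], event[idx])
      if (r$usable == 0) NA_real_
      else (r$concordant + 0.5 * r$tied) / r$usable
    }, numeric(1))
    cb <- cb[!is.na(cb)]
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(cb, c(alpha, 1 - alpha), names = FALSE, type = 2)
    out$ci_low <- qs[1L]
    out$ci_high <- qs[2L]
    out$B <- B
  }
  out
}

# pair counting via one vectorized pass per event subject: for event i,
# partners are all j with t_j > t_i, plus j with t_j == t_i and an event
# (counted once per unordered pair).
.concordance_counts <- function(risk10, time, event) {
  ev_idx <- which(event)
  usable <- 0; concordant <- 0; tied <- 0
  for (i in ev_idx) {
    later <- time > time[i]
    usable <- usable + sum(later)
    concordant <- concordant + sum(later & risk10 < risk10[i])
    tied <- tied + sum(later & risk10 == risk10[i])
    # event-event time ties: count each unordered pair once (j > i)
    same <- which(time == time[i] & event)
    same <- same[same > i]
    usable <- usable + length(same)
    # an exact time tie between two events has no "earlier" subject; the
    # pair is usable and contributes 0.5 whatever the predictions
    tied <- tied + sum(risk10[same] == risk10[i])
    concordant <- concordant + 0.5 * sum(risk10[same] != risk10[i])
  }
  list(usable = usable, concordant = concordant, tied = tied)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Standard empirical ROC over thresholds at every distinct prediction for
#' the event-by-horizon dichotomy; AUC by the trapezoid rule (equal to the
#' Mann-Whitney U statistic divided by `n1 * n0`).
#'
#' @param risk10 predicted risks.
#' @param event logical events by the horizon; both classes must be
#'   present.
#' @param path optional file; when given, the (FPR, TPR) pairs are written
#'   as comma-delimited text for plotting.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`,
#'   ordered by increasing FPR) and `auc`.
#' @export
roc_export <- function(risk10, event, path = NULL) {
  if (length(risk10) != length(event)) {
    stop("inputs must be aligned", call. = FALSE)
  }
  n1 <- sum(event); n0 <- sum(!event)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  ord <- order(risk10, decreasing = TRUE)
  p <- risk10[ord]; e <- event[ord]
  # collapse tied predictions into single thresholds
  last_of_run <- c(p[-1] != p[-length(p)], TRUE)
  tp <- cumsum(e)[last_of_run]
  fp <- cumsum(!e)[last_of_run]
  points <- data.frame(threshold = c(Inf, p[last_of_run]),
                       fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  if (!is.null(path)) {
    utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  }
  list(points = points, auc = auc)
}

#' Evaluate an equation on a cohort stratum
#'
#' Builds one evaluation report: observed event frequency, mean estimated
#' risk, overestimation %, incidence rate, Harrell's C (with bootstrap CI
#' when `B > 0`) and the decile calibration table. Percentages are reported
#' on the 0-100 scale.
#'
#' @param x a [cohort()] after exclusions and horizon censoring.
#' @param eq a `risk_equation`.
#' @param endpoint `"ascvd"` or `"cv_death"`.
#' @param horizon horizon in years.
#' @param stratum label for the report row.
#' @param B,seed bootstrap control for the C-statistic CI.
#' @param freq_method observed-frequency estimator (see
#'   [observed_event_frequency()]).
#' @return an `evaluation_report` list.
#' @export
evaluation_report <- function(x, eq, endpoint = c("ascvd", "cv_death"),
                              horizon = 10, stratum = cohort_name(x),
                              B = 0, seed = NULL,
                              freq_method = c("crude", "km")) {
  endpoint <- match.arg(endpoint)
  freq_method <- match.arg(freq_method)
  ev <- .endpoint_events(x, endpoint)
  pred <- predict_risk(eq, x)
  tcol <- if (endpoint == "ascvd") "fu_ascvd_years" else "fu_cvdeath_years"
  tt <- as.data.frame(x)[[tcol]]
  obs <- observed_event_frequency(x, endpoint, horizon, freq_method)
  est <- mean(pred$risk10)
  cc <- harrells_c(pred$risk10, tt, ev, B = B, seed = seed)
  structure(list(
    equation = eq$id, stratum = stratum, n = nrow(x), events = sum(ev),
    observed_freq_pct = 100 * obs, mean_estimated_pct = 100 * est,
    overestimation_pct = overestimation_pct(100 * est, 100 * obs),
    incidence_rate_per_1000py = incidence_rate(x, endpoint, horizon),
    c_statistic = cc$c, c_ci_low = cc$ci_low, c_ci_high = cc$ci_high,
    calibration = calibration_deciles(pred$risk10, ev)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s on %s (n = %d, events = %d)\n",
              x$equation, x$stratum, x$n, x$events))
  cat(sprintf("  observed %.1f%%  estimated %.1f%%  overestimation %.1f%%\n",
              x$observed_freq_pct, x$mean_estimated_pct,
              x$overestimation_pct))
  ci <- if (!is.null(x$c_ci_low)) {
    sprintf(" [%.2f, %.2f]", x$c_ci_low, x$c_ci_high)
  } else ""
  cat(sprintf("  C = %.3f%s  incidence %.1f / 1,000 PY\n", x$c_statistic,
              ci, x$incidence_rate_per_1000py))
  invisible(x)
}

#' Write evaluation reports as a summary table
#'
#' One row per (stratum, equation): observed %, estimated %,
#' overestimation %, C with CI, incidence rate. Values are written at full
#' precision with companion columns rounded to one decimal; an internal
#' consistency check re-derives the overestimation column from the row's
#' own observed/estimated fields at write time.
#'
#' @param reports list of `evaluation_report` objects.
#' @param path output file (comma-delimited).
#' @return the assembled data frame, invisibly.
#' @export
write_report_table <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    stopifnot(inherits(r, "evaluation_report"))
    recompute <- overestimation_pct(r$mean_estimated_pct,
                                    r$observed_freq_pct)
    if (abs(recompute - r$overestimation_pct) > 1e-8) {
      stop("internal inconsistency: overestimation does not match its ",
           "formula for stratum ", r$stratum, call. = FALSE)
    }
    data.frame(stratum = r$stratum, equation = r$equation, n = r$n,
               events = r$events,
               observed_pct = r$observed_freq_pct,
               estimated_pct = r$mean_estimated_pct,
               overestimation_pct = r$overestimation_pct,
               c_statistic = r$c_statistic,
               c_ci_low = if (is.null(r$c_ci_low)) NA_real_ else r$c_ci_low,
               c_ci_high = if (is.null(r$c_ci_high)) NA_real_ else r$c_ci_high,
               incidence_per_1000py = r$incidence_rate_per_1000py,
               observed_pct_r1 = round(r$observed_freq_pct, 1),
               estimated_pct_r1 = round(r$mean_estimated_pct, 1),
               overestimation_pct_r1 = round(r$overestimation_pct, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write a decile calibration table as delimited text
#'
#' @param tab a `calibration_table`.
#' @param path output file (comma-delimited).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(tab, path) {
  stopifnot(inherits(tab, "calibration_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
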