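# Calibration-in-the-large: an intercept-level correction equal to the log
# odds-ratio of observed event frequency to mean predicted risk, applied on
# the logit of predicted risk (default) or inside the survival exponent.

.logit <- function(p) log(p / (1 - p))
.expit <- function(x) 1 / (1 + exp(-x))

#' Compute the calibration-in-the-large correction factor
#'
#' `c = ln[ (O / (1 - O)) / (Pbar / (1 - Pbar)) ]` where `O` is the
#' observed event frequency by the horizon and `Pbar` the arithmetic mean
#' of the predicted 10-year risks. `c = 0` means the score is calibrated
#' in the large; negative `c` shrinks over-estimated risks.
#'
#' @param risk10 numeric vector of predicted 10-year risks.
#' @param event logical vector: event by the horizon (after administrative
#'   censoring), aligned with `risk10`.
#' @param source_label label recording what the factor was trained on.
#' @return a `recal_factor` object with fields `correction`,
#'   `observed_freq`, `mean_pred`, `n`, `source_label`.
#' @export
compute_correction <- function(risk10, event, source_label = "training") {
  if (length(risk10) != length(event)) {
    stop("risk10 and event must be aligned", call. = FALSE)
  }
  if (anyNA(risk10) || anyNA(event)) {
    stop("risk10 and event must be fully observed", call. = FALSE)
  }
  n <- length(risk10)
  obs <- mean(event)
  pbar <- mean(risk10)
  if (obs <= 0 || obs >= 1) {
    stop("degenerate input: observed event frequency is ", obs,
         "; log-odds undefined (need at least one event and one non-event)",
         call. = FALSE)
  }
  if (pbar <= 0 || pbar >= 1) {
    stop("degenerate input: mean predicted risk is ", pbar, call. = FALSE)
  }
  structure(list(correction = .logit(obs) - .logit(pbar),
                 observed_freq = obs, mean_pred = pbar, n = n,
                 source_label = source_label),
            class = "recal_factor")
}

#' @export
print.recal_factor <- function(x, ...) {
  cat(sprintf("<recal_factor> c = %.4f (O = %.4f, mean pred = %.4f, n = %d, %s)\n",
              x$correction, x$observed_freq, x$mean_pred, x$n,
              x$source_label))
  invisible(x)
}

#' Apply a correction factor to predicted risks
#'
#' Logit shift: `expit(logit(p) + c)`. Strictly increasing in `p`, the
#' identity at `c = 0`, and exactly invertible by the opposite shift, so
#' rank order of any prediction vector is preserved.
#'
#' @param p predicted risks, strictly inside (0, 1).
#' @param f a `recal_factor`, or a bare numeric correction.
#' @return corrected risks.
#' @export
apply_correction <- function(p, f) {
  cc <- if (inherits(f, "recal_factor")) f$correction else as.numeric(f)
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("degenerate input: predictions must lie strictly in (0, 1)",
         call. = FALSE)
  }
  .expit(.logit(p) + cc)
}

#' Recalibrate a risk equation on a training cohort
#'
#' Computes the calibration-in-the-large factor from the equation's
#' predictions and the observed events on the training cohort (after
#' horizon censoring) and returns a new equation whose predictions are the
#' corrected originals; the original equation is untouched. The default
#' `mode = "logit"` shifts the log-odds of the predicted risk; for
#' PCE-form equations `mode = "exponent"` instead multiplies
#' `exp(LP - mean_lp)` by `e^c` inside the survival formula (sensitivity
#' analysis).
#'
#' @param eq a `risk_equation`.
#' @param training a [cohort()] that passed exclusions and horizon
#'   censoring.
#' @param endpoint which endpoint the factor targets: `"ascvd"` or
#'   `"cv_death"`.
#' @param mode correction scale, `"logit"` (default) or `"exponent"`.
#' @param id identifier of the recalibrated equation.
#' @return a `recal_equation` (also a `risk_equation`) carrying the fitted
#'   `recal_factor` as `$recalibration`.
#' @export
recalibrate_equation <- function(eq, training, endpoint = c("ascvd", "cv_death"),
                                 mode = c("logit", "exponent"),
                                 id = paste0(eq$id, "_recalibrated")) {
  stopifnot(inherits(eq, "risk_equation"), inherits(training, "cohort"))
  endpoint <- match.arg(endpoint)
  mode <- match.arg(mode)
  if (mode == "exponent" && !inherits(eq, "pce_equation")) {
    stop("mode = \"exponent\" is only defined for PCE-form equations",
         call. = FALSE)
  }
  ev <- .endpoint_events(training, endpoint)
  pred <- predict_risk(eq, training)
  f <- compute_correction(pred$risk10, ev,
                          source_label = paste0(cohort_name(training), ":",
                                                endpoint))
  structure(list(id = id, base = eq, recalibration = f, mode = mode,
                 endpoint = endpoint),
            class = c("recal_equation", "risk_equation"))
}

.endpoint_events <- function(x, endpoint) {
  col <- if (endpoint == "ascvd") "event_ascvd" else "event_cvdeath"
  ev <- as.data.frame(x)[[col]]
  if (anyNA(ev)) {
    stop("endpoint '", endpoint, "' has unknown event indicators; apply ",
         "exclusions first", call. = FALSE)
  }
  ev
}

#' @export
predict_risk.recal_equation <- function(eq, x, ...) {
  base <- predict_risk(eq$base, x)
  cc <- eq$recalibration$correction
  if (eq$mode == "logit") {
    base$risk10 <- apply_correction(base$risk10, cc)
  } else {
    # shift inside the survival exponent: 1 - s0 ^ (exp(LP - M) * e^c)
    df <- as.data.frame(x)
    for (sx in c("male", "female")) {
      idx <- df$sex == if (sx == "male") "M" else "F"
      if (!any(idx)) next
      stratum <- eq$base$coeffs$strata[[sx]]
      base$risk10[idx] <- 1 - stratum$s0_10 ^
        (exp(base$linear_predictor[idx] - stratum$mean_lp) * exp(cc))
    }
  }
  base$equation <- eq$id
  base
}

# ---- serialization ---------------------------------------------------------

#' Write / read a (possibly recalibrated) PCE equation as JSON
#'
#' The file uses the coefficient-file schema; a recalibrated equation adds a
#' `recalibration` block `{correction, observed_freq, mean_pred, n,
#' training_label, mode}` so a recalibrated score is shareable and
#' re-loadable with identical predictions.
#'
#' @param eq a `pce_equation` or a `recal_equation` wrapping one.
#' @param path output / input JSON file.
#' @return `write_equation()`: `path`, invisibly. `read_equation()`: a
#'   `risk_equation`.
#' @export
write_equation <- function(eq, path) {
  if (inherits(eq, "recal_equation")) {
    base <- eq$base
    recal <- list(correction = eq$recalibration$correction,
                  observed_freq = eq$recalibration$observed_freq,
                  mean_pred = eq$recalibration$mean_pred,
                  n = eq$recalibration$n,
                  training_label = eq$recalibration$source_label,
                  mode = eq$mode, endpoint = eq$endpoint, id = eq$id)
  } else {
    base <- eq
    recal <- NULL
  }
  if (!inherits(base, "pce_equation")) {
    stop("only PCE-form equations serialize to the coefficient schema",
         call. = FALSE)
  }
  cf <- base$coeffs
  strata <- lapply(names(cf$strata), function(sx) {
    s <- cf$strata[[sx]]
    terms <- s$terms[s$terms != 0]
    list(sex = sx, race = s$race, terms = as.list(terms),
         mean_lp = s$mean_lp, s0_10 = s$s0_10)
  })
  out <- list(equation = "pce", version = cf$version,
              source_citation = cf$source_citation, strata = strata)
  if (!is.null(recal)) out$recalibration <- recal
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_equation
#' @export
read_equation <- function(path) {
  coeffs <- read_pce_coeffs(path)
  base <- pce_equation(coeffs, id = "pce_original")
  r <- coeffs$recalibration
  if (is.null(r)) return(base)
  f <- structure(list(correction = as.numeric(r$correction),
                      observed_freq = as.numeric(r$observed_freq),
                      mean_pred = as.numeric(r$mean_pred),
                      n = as.integer(r$n),
                      source_label = r$training_label),
                 class = "recal_factor")
  structure(list(id = if (is.null(r$id)) "pce_recalibrated" else r$id,
                 base = base, recalibration = f,
                 mode = if (is.null(r$mode)) "logit" else r$mode,
                 endpoint = if (is.null(r$endpoint)) "ascvd" else r$endpoint),
            class = c("recal_equation", "risk_equation"))
}

# ---- cross-validation ------------------------------------------------------

#' k-fold cross-validation of the recalibration
#'
#' Subjects are partitioned into `k` folds, stratified on the endpoint
#' event indicator so every training split has an estimable observed
#' frequency; the split is fully determined by `seed`. For each fold the
#' correction factor is fitted on the other `k - 1` folds and the
#' held-out fold is evaluated (observed and mean estimated risk,
#' overestimation, Harrell's C of the recalibrated score).
#'
#' @param x a [cohort()] after exclusions and horizon censoring.
#' @param eq the `risk_equation` to recalibrate (e.g. [pce_equation()]).
#' @param k number of folds (default 10); must be `>= 2` and `<= n`.
#' @param seed integer seed for the fold assignment.
#' @param endpoint `"ascvd"` or `"cv_death"`.
#' @param mode correction scale, as in [recalibrate_equation()].
#' @return list with `folds` (one row per fold: n, events, correction,
#'   observed %, estimated %, overestimation %, C) and `pooled`
#'   (across-fold means, including mean |overestimation|).
#' @export
kfold_cross_validate <- function(x, eq, k = 10, seed,
                                 endpoint = c("ascvd", "cv_death"),
                                 mode = c("logit", "exponent")) {
  stopifnot(inherits(x, "cohort"), inherits(eq, "risk_equation"))
  endpoint <- match.arg(endpoint)
  mode <- match.arg(mode)
  n <- nrow(x)
  if (k < 2 || k > n) stop("need 2 <= k <= n", call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducible folds",
                          call. = FALSE)
  ev <- .endpoint_events(x, endpoint)
  if (sum(ev) == 0L || sum(!ev) == 0L) {
    stop("cross-validation needs at least one event and one non-event",
         call. = FALSE)
  }
  fold <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # event-stratified assignment: events spread round-robin over folds,
  # non-events water-filled so fold sizes stay balanced and no fold is
  # empty (k = n degenerates to leave-one-out)
  ev_idx <- sample(which(ev))
  ne_idx <- sample(which(!ev))
  fold[ev_idx] <- rep_len(seq_len(k), length(ev_idx))
  sizes <- tabulate(fold[ev_idx], k)
  slots <- integer(k)
  for (j in seq_along(ne_idx)) {
    i <- which.min(sizes + slots)
    slots[i] <- slots[i] + 1L
  }
  fold[ne_idx] <- rep(seq_len(k), times = slots)
  pred_all <- predict_risk(eq, x)
  df <- as.data.frame(x)
  time_col <- if (endpoint == "ascvd") "fu_ascvd_years" else "fu_cvdeath_years"
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    test <- fold == i
    if (sum(ev[!test]) == 0L || all(ev[!test])) {
      stop("training split for fold ", i, " has no ",
           if (all(ev[!test])) "non-events" else "events",
           "; reduce k", call. = FALSE)
    }
    f <- compute_correction(pred_all$risk10[!test], ev[!test],
                            source_label = sprintf("cv_fold_%d_train", i))
    p_test <- if (mode == "logit") {
      apply_correction(pred_all$risk10[test], f)
    } else {
      # exponent mode: rebuild from LP with shifted exponent
      pr <- pred_all[test, , drop = FALSE]
      out <- pr$risk10
      for (sx in c("male", "female")) {
        idx <- df$sex[test] == if (sx == "male") "M" else "F"
        if (!any(idx)) next
        st <- eq$coeffs$strata[[sx]]
        out[idx] <- 1 - st$s0_10 ^
          (exp(pr$linear_predictor[idx] - st$mean_lp) * exp(f$correction))
      }
      out
    }
    obs_pct <- 100 * mean(ev[test])
    est_pct <- 100 * mean(p_test)
    # held-out folds without events (possible at large k, e.g. leave-one-
    # out) report NA metrics rather than refusing
    over <- if (obs_pct > 0) overestimation_pct(est_pct, obs_pct)
            else NA_real_
    cc <- tryCatch(harrells_c(p_test, df[[time_col]][test], ev[test],
                              B = 0)$c,
                   error = function(e) NA_real_)
    folds[[i]] <- data.frame(fold = i, n = sum(test), events = sum(ev[test]),
                             correction = f$correction,
                             observed_pct = obs_pct, estimated_pct = est_pct,
                             overestimation_pct = over, c_statistic = cc)
  }
  folds <- do.call(rbind, folds)
  pooled <- list(mean_observed_pct = mean(folds$observed_pct),
                 mean_estimated_pct = mean(folds$estimated_pct),
                 mean_overestimation_pct = mean(folds$overestimation_pct,
                                                na.rm = TRUE),
                 mean_abs_overestimation_pct =
                   mean(abs(folds$overestimation_pct), na.rm = TRUE),
                 mean_c_statistic = mean(folds$c_statistic, na.rm = TRUE))
  list(folds = folds, pooled = pooled)
}

# save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
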