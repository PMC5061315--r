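# Synthetic cohorts with the marginal structure of population-based German
# cohort baselines, plus a configurable true event-generating model, so
# the whole pipeline is exercisable without the (undeposited) study data.

#' Simulation configuration for a synthetic cohort
#'
#' Continuous covariates are sampled per sex: age from a Normal truncated
#' to \[40, 79\]; total cholesterol, HDL and SBP from log-normal families
#' fitted to the stated median and quartiles (two-parameter fit to the
#' median and the IQR ratio, matching right-skewed lipid/pressure data);
#' binary factors from Bernoulli. Covariates are independent. Outcomes
#' follow `true_model` (see [attach_outcomes()]).
#'
#' @param name cohort label.
#' @param n cohort size.
#' @param frac_male probability a subject is male.
#' @param male,female per-sex blocks: lists with `age_mean`, `age_sd`,
#'   `tc_median`, `tc_q1`, `tc_q3`, `hdl_median`, `hdl_q1`, `hdl_q3`,
#'   `sbp_median`, `sbp_q1`, `sbp_q3`, `p_bp_treated`, `p_smoker`,
#'   `p_diabetes`.
#' @param fu_mean,fu_sd target realized mean and SD of follow-up (years);
#'   the censoring-time location is solved so that
#'   `E[min(C, horizon)] = fu_mean`.
#' @param true_model list with `type` one of `"pce_true"` (events drawn so
#'   that the true 10-year risk equals the PCE prediction), `"pce_scaled"`
#'   (the score overestimates by `gamma` on the odds scale: true odds =
#'   PCE odds / `gamma`), or `"custom_lp"`
#'   (`1 - exp(-h0 * 10 * exp(theta' x))`, `theta` named over cohort
#'   covariate columns).
#' @param fatal_fraction share of events also flagged as cardiovascular
#'   death (mortality endpoint).
#' @param censoring `"normal"` (truncated-Normal censoring times) or
#'   `"none"` (everyone followed the full horizon).
#' @param seed integer seed; simulation output is fully determined by it.
#' @return a `cohort_sim_config` object.
#' @export
cohort_sim_config <- function(name, n, frac_male, male, female,
                              fu_mean = 9, fu_sd = 2,
                              true_model = list(type = "pce_true"),
                              fatal_fraction = 0.4,
                              censoring = c("normal", "none"),
                              seed = 1L) {
  censoring <- match.arg(censoring)
  stopifnot(n > 0, frac_male >= 0, frac_male <= 1,
            fatal_fraction >= 0, fatal_fraction <= 1)
  for (blk in list(male, female)) .validate_sex_block(blk)
  if (!true_model$type %in% c("pce_true", "pce_scaled", "custom_lp")) {
    stop("unknown true_model type: ", true_model$type, call. = FALSE)
  }
  if (true_model$type == "pce_scaled" && is.null(true_model$gamma)) {
    stop("true_model pce_scaled needs a gamma", call. = FALSE)
  }
  structure(list(name = name, n = as.integer(n), frac_male = frac_male,
                 male = male, female = female, fu_mean = fu_mean,
                 fu_sd = fu_sd, true_model = true_model,
                 fatal_fraction = fatal_fraction, censoring = censoring,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

.sex_block_fields <- c("age_mean", "age_sd", "tc_median", "tc_q1", "tc_q3",
                       "hdl_median", "hdl_q1", "hdl_q3", "sbp_median",
                       "sbp_q1", "sbp_q3", "p_bp_treated", "p_smoker",
                       "p_diabetes")

.validate_sex_block <- function(blk) {
  missing <- setdiff(.sex_block_fields, names(blk))
  if (length(missing) > 0L) {
    stop("sex block missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in c("tc", "hdl", "sbp")) {
    q1 <- blk[[paste0(v, "_q1")]]; md <- blk[[paste0(v, "_median")]]
    q3 <- blk[[paste0(v, "_q3")]]
    if (!(0 < q1 && q1 < md && md < q3)) {
      stop("block '", v, "' has no log-normal fit: need 0 < q1 < median ",
           "< q3, got (", q1, ", ", md, ", ", q3, ")", call. = FALSE)
    }
  }
  invisible(blk)
}

# log-normal parameters from median and IQR ratio
.lnorm_fit <- function(median, q1, q3) {
  list(meanlog = log(median),
       sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Preset simulation configurations
#'
#' `kora_like_config()` and `hnr_like_config()` populate the per-sex
#' covariate marginals, follow-up structure and event model with the
#' baseline characteristics of the two German population cohorts the
#' package emulates (southern cohort: n = 5,238, mean follow-up 8.6 +/-
#' 2.0 years; western cohort: n = 4,208, 9.0 +/- 2.1 years).
#'
#' @param n cohort size (defaults to the emulated cohort's size).
#' @param true_model,censoring,seed passed to [cohort_sim_config()].
#' @return a `cohort_sim_config`.
#' @export
kora_like_config <- function(n = 5238, true_model = list(type = "pce_true"),
                             censoring = "normal", seed = 1L) {
  cohort_sim_config(
    name = "kora_like", n = n, frac_male = 2584 / 5238,
    male = list(age_mean = 56.4, age_sd = 9.6,
                tc_median = 235, tc_q1 = 208, tc_q3 = 263,
                hdl_median = 48, hdl_q1 = 40, hdl_q3 = 58,
                sbp_median = 136, sbp_q1 = 125, sbp_q3 = 149,
                p_bp_treated = 0.19, p_smoker = 0.25, p_diabetes = 0.05),
    female = list(age_mean = 55.5, age_sd = 9.7,
                  tc_median = 233, tc_q1 = 209, tc_q3 = 264,
                  hdl_median = 60, hdl_q1 = 49, hdl_q3 = 72,
                  sbp_median = 128, sbp_q1 = 116, sbp_q3 = 144,
                  p_bp_treated = 0.22, p_smoker = 0.17, p_diabetes = 0.04),
    fu_mean = 8.6, fu_sd = 2.0, true_model = true_model,
    fatal_fraction = 175 / 383, censoring = censoring, seed = seed)
}

#' @rdname kora_like_config
#' @export
hnr_like_config <- function(n = 4208, true_model = list(type = "pce_true"),
                            censoring = "normal", seed = 1L) {
  cohort_sim_config(
    name = "hnr_like", n = n, frac_male = 2005 / 4208,
    male = list(age_mean = 58.8, age_sd = 7.6,
                tc_median = 226, tc_q1 = 202, tc_q3 = 249,
                hdl_median = 49, hdl_q1 = 42, hdl_q3 = 59,
                sbp_median = 137, sbp_q1 = 125, sbp_q3 = 149,
                p_bp_treated = 0.30, p_smoker = 0.26, p_diabetes = 0.08),
    female = list(age_mean = 59.1, age_sd = 7.7,
                  tc_median = 232, tc_q1 = 208, tc_q3 = 260,
                  hdl_median = 64, hdl_q1 = 53, hdl_q3 = 75,
                  sbp_median = 125, sbp_q1 = 113, sbp_q3 = 141,
                  p_bp_treated = 0.32, p_smoker = 0.22, p_diabetes = 0.06),
    fu_mean = 9.0, fu_sd = 2.1, true_model = true_model,
    fatal_fraction = 74 / 271, censoring = censoring, seed = seed)
}

#' Sample baseline covariates for a synthetic cohort
#'
#' Draws the covariate columns only; outcome columns are left unknown
#' (attach them with [attach_outcomes()]). Fully determined by the seed.
#'
#' @param cfg a [cohort_sim_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return a [cohort()] with ages in \[40, 79\], no prevalent disease and
#'   complete risk factors (so it passes [apply_exclusions()] with zero
#'   removals).
#' @export
sample_covariates <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- cfg$n
  male <- stats::runif(n) < cfg$frac_male
  age <- tc <- hdl <- sbp <- numeric(n)
  treated <- smoker <- diabetes <- logical(n)
  for (sx in c("male", "female")) {
    idx <- if (sx == "male") male else !male
    m <- sum(idx)
    if (m == 0L) next
    blk <- cfg[[sx]]
    age[idx] <- .rtruncnorm(m, blk$age_mean, blk$age_sd, 40, 79)
    for (v in c("tc", "hdl", "sbp")) {
      fit <- .lnorm_fit(blk[[paste0(v, "_median")]], blk[[paste0(v, "_q1")]],
                        blk[[paste0(v, "_q3")]])
      draw <- stats::rlnorm(m, fit$meanlog, fit$sdlog)
      if (v == "tc") tc[idx] <- draw
      else if (v == "hdl") hdl[idx] <- draw
      else sbp[idx] <- draw
    }
    treated[idx] <- stats::runif(m) < blk$p_bp_treated
    smoker[idx] <- stats::runif(m) < blk$p_smoker
    diabetes[idx] <- stats::runif(m) < blk$p_diabetes
  }
  cohort(data.frame(
    subject_id = sprintf("%s_%06d", cfg$name, seq_len(n)),
    sex = ifelse(male, "M", "F"),
    age = age, total_chol_mgdl = tc, hdl_mgdl = hdl, sbp_mmhg = sbp,
    bp_treated = treated, smoker = smoker, diabetes = diabetes,
    prev_chf = FALSE, prev_mi = FALSE, prev_stroke = FALSE,
    fu_ascvd_years = NA_real_, event_ascvd = NA,
    fu_cvdeath_years = NA_real_, event_cvdeath = NA,
    stringsAsFactors = FALSE), name = cfg$name)
}

# inverse-CDF sampling from a truncated Normal
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# location mu such that E[min(N(mu, sd), horizon)] equals the target
# realized mean follow-up
.solve_censor_mu <- function(target, sd, horizon = 10) {
  f <- function(mu) {
    z <- (horizon - mu) / sd
    mu * stats::pnorm(z) + horizon * (1 - stats::pnorm(z)) -
      sd * stats::dnorm(z) - target
  }
  stats::uniroot(f, lower = target - 1, upper = horizon + 6 * sd,
                 tol = 1e-10)$root
}

#' True 10-year event risk under a simulation's event model
#'
#' @param x a [cohort()] with covariates sampled.
#' @param cfg a [cohort_sim_config()].
#' @return numeric vector of true risks in (0, 1); clipped values (possible
#'   only under `custom_lp` misconfiguration) carry a `clipped` attribute
#'   with the count.
#' @export
true_risk <- function(x, cfg) {
  tm <- cfg$true_model
  p <- switch(tm$type,
    pce_true = predict_risk(pce_equation(), x)$risk10,
    pce_scaled = {
      # gamma is the odds-scale overestimation factor of the score: the
      # true risk has odds equal to the PCE odds divided by gamma, so
      # gamma > 1 yields a cohort in which the original score
      # overestimates by construction
      p0 <- predict_risk(pce_equation(), x)$risk10
      if (tm$gamma == 1) p0 else {
        odds <- (p0 / (1 - p0)) / tm$gamma
        odds / (1 + odds)
      }
    },
    custom_lp = {
      df <- as.data.frame(x)
      xm <- as.matrix(df[, names(tm$theta), drop = FALSE]) * 1
      1 - exp(-tm$h0 * 10 * exp(drop(xm %*% tm$theta)))
    })
  clipped <- sum(p <= 0 | p >= 1)
  if (clipped > 0L) {
    warning(clipped, " true risks clipped into (0, 1)", call. = FALSE)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  attr(p, "clipped") <- clipped
  p
}

#' Attach simulated outcomes to a covariate-only cohort
#'
#' Per subject the true 10-year risk `p_i` is computed from
#' `cfg$true_model`; the event time is exponential with rate
#' `-log(1 - p_i) / 10`, so that `P(event <= 10) = p_i` exactly. Censoring
#' times are Normal (location solved so the realized mean follow-up under
#' the horizon matches `fu_mean`), truncated to be positive, or infinite
#' when `cfg$censoring = "none"`. Observed time is the minimum of event
#' time, censoring time and the 10-year horizon. A Bernoulli
#' (`fatal_fraction`) subset of events is additionally flagged as
#' cardiovascular death at the same time; for other subjects the mortality
#' endpoint is censored at their follow-up time.
#'
#' @param x a [cohort()] from [sample_covariates()].
#' @param cfg the same [cohort_sim_config()].
#' @param seed outcome-stage seed; defaults to `cfg$seed + 500000` (kept
#'   distinct from the covariate stage so the two draws are independent).
#' @return the completed [cohort()].
#' @export
attach_outcomes <- function(x, cfg, seed = cfg$seed + 500000L) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "cohort_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(x)
  p <- true_risk(x, cfg)
  rate <- -log(1 - p) / 10
  t_event <- stats::rexp(n, rate)
  if (cfg$censoring == "none") {
    t_cens <- rep(Inf, n)
  } else {
    mu <- .solve_censor_mu(cfg$fu_mean, cfg$fu_sd)
    t_cens <- pmax(stats::rnorm(n, mu, cfg$fu_sd), 0.01)
  }
  fu <- pmin(t_event, t_cens, 10)
  event <- t_event <= pmin(t_cens, 10)
  fatal <- event & (stats::runif(n) < cfg$fatal_fraction)
  df <- as.data.frame(x)
  df$fu_ascvd_years <- fu
  df$event_ascvd <- event
  df$fu_cvdeath_years <- ifelse(fatal, fu, pmin(t_cens, 10))
  df$event_cvdeath <- fatal
  cohort(df, name = cohort_name(x), exclusion_log = exclusion_log(x))
}

#' Simulate a complete synthetic cohort
#'
#' [sample_covariates()] followed by [attach_outcomes()].
#'
#' @param cfg a [cohort_sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return a [cohort()] with covariates and outcomes.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  cfg$seed <- as.integer(seed)
  attach_outcomes(sample_covariates(cfg), cfg)
}

#' Read / write a simulation configuration as JSON
#'
#' Presets round-trip exactly through this pair.
#'
#' @param cfg a [cohort_sim_config()].
#' @param path JSON file.
#' @return `write_sim_config()`: `path`, invisibly; `read_sim_config()`:
#'   a `cohort_sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- as.list(raw$true_model)
  if (!is.null(tm$theta)) tm$theta <- unlist(tm$theta)
  cohort_sim_config(name = raw$name, n = raw$n, frac_male = raw$frac_male,
                    male = as.list(raw$male), female = as.list(raw$female),
                    fu_mean = raw$fu_mean, fu_sd = raw$fu_sd,
                    true_model = tm, fatal_fraction = raw$fatal_fraction,
                    censoring = raw$censoring, seed = raw$seed)
}
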