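# Closed-form 10-year risk engines: Pooled Cohort Equations (survival form
# 1 - S0^exp(LP - mean LP)) and ESC SCORE (cause-specific Weibull baseline
# survival combined over CHD and non-CHD causes).

.pce_term_matrix <- function(age, tc, hdl, sbp, bp_treated, smoker, diabetes) {
  la <- log(age); ltc <- log(tc); lhdl <- log(hdl); lsbp <- log(sbp)
  tr <- as.numeric(bp_treated)
  cbind(ln_age = la,
        ln_age_sq = la^2,
        ln_tc = ltc,
        ln_age_ln_tc = la * ltc,
        ln_hdl = lhdl,
        ln_age_ln_hdl = la * lhdl,
        ln_sbp_treated = tr * lsbp,
        ln_age_ln_sbp_treated = tr * la * lsbp,
        ln_sbp_untreated = (1 - tr) * lsbp,
        ln_age_ln_sbp_untreated = (1 - tr) * la * lsbp,
        smoker = as.numeric(smoker),
        ln_age_smoker = la * as.numeric(smoker),
        diabetes = as.numeric(diabetes))
}

.check_pce_inputs <- function(age, tc, hdl, sbp) {
  if (any(!is.finite(age) | age <= 0) || any(!is.finite(tc) | tc <= 0) ||
      any(!is.finite(hdl) | hdl <= 0) || any(!is.finite(sbp) | sbp <= 0)) {
    stop("age, total cholesterol, HDL and SBP must be positive and known",
         call. = FALSE)
  }
}

#' Pooled Cohort Equations linear predictor
#'
#' Sum over the equation's terms of coefficient times term value. Term
#' values use natural logs of age, total cholesterol (mg/dL), HDL (mg/dL)
#' and SBP (mmHg); the treated-SBP terms apply iff `bp_treated`, otherwise
#' the untreated terms; binary terms are 0/1. All covariate arguments are
#' vectorized.
#'
#' @param sex `"male"` or `"female"`; selects the coefficient stratum
#'   (scalar — call per sex).
#' @param age years.
#' @param tc,hdl total and HDL cholesterol, mg/dL.
#' @param sbp systolic blood pressure, mmHg.
#' @param bp_treated,smoker,diabetes logicals.
#' @param coeffs a `pce_coeffs` object (see [read_pce_coeffs()]).
#' @return numeric vector of linear-predictor values.
#' @export
pce_linear_predictor <- function(sex, age, tc, hdl, sbp, bp_treated,
                                 smoker, diabetes,
                                 coeffs = read_pce_coeffs()) {
  sex <- match.arg(sex, c("male", "female"))
  stratum <- coeffs$strata[[sex]]
  if (is.null(stratum)) stop("no coefficient stratum for sex ", sex,
                             call. = FALSE)
  .check_pce_inputs(age, tc, hdl, sbp)
  tm <- .pce_term_matrix(age, tc, hdl, sbp, bp_treated, smoker, diabetes)
  # row-wise sum (not BLAS %*%) so results are bit-identical under row
  # permutation
  cf <- stratum$terms[colnames(tm)]
  unname(rowSums(tm * matrix(cf, nrow(tm), ncol(tm), byrow = TRUE)))
}

#' Pooled Cohort Equations 10-year risk
#'
#' `risk10 = 1 - s0_10 ^ exp(LP - mean_lp)` where `s0_10` is the baseline
#' 10-year survival and `mean_lp` the population mean linear predictor of
#' the sex stratum.
#'
#' @inheritParams pce_linear_predictor
#' @return numeric vector of 10-year ASCVD risks in (0, 1).
#' @export
pce_risk10 <- function(sex, age, tc, hdl, sbp, bp_treated, smoker, diabetes,
                       coeffs = read_pce_coeffs()) {
  sex <- match.arg(sex, c("male", "female"))
  lp <- pce_linear_predictor(sex, age, tc, hdl, sbp, bp_treated, smoker,
                             diabetes, coeffs)
  stratum <- coeffs$strata[[sex]]
  1 - stratum$s0_10 ^ exp(lp - stratum$mean_lp)
}

#' ESC SCORE 10-year cardiovascular-mortality risk
#'
#' For each cause c in {CHD, non-CHD CVD}: baseline survival
#' `S0(a) = exp(-exp(alpha_c) * (a - 20)^p_c)`; hazard-ratio weight
#' `w_c = exp(beta_chol_c (chol - 6) + beta_sbp_c (sbp - 120) +
#' beta_smoker_c smoker)`; cause risk `1 - (S0(a + 10)/S0(a))^w_c`. The
#' total 10-year risk combines the two causes, by default as their sum
#' capped at 1; `combine = "complement"` uses
#' `1 - (1 - r_chd)(1 - r_non_chd)` instead.
#'
#' @param sex `"male"` or `"female"` (scalar).
#' @param age years, must exceed 20 (vectorized).
#' @param chol_mmol total cholesterol in mmol/L (convert mg/dL with
#'   [chol_mgdl_to_mmoll()]).
#' @param sbp systolic blood pressure, mmHg.
#' @param smoker logical.
#' @param coeffs an `esc_coeffs` object (see [read_esc_coeffs()]).
#' @param combine cause-combination rule; `"sum"` (default) or
#'   `"complement"`.
#' @return numeric vector of 10-year cardiovascular-mortality risks.
#' @export
esc_risk10 <- function(sex, age, chol_mmol, sbp, smoker,
                       coeffs = read_esc_coeffs(),
                       combine = c("sum", "complement")) {
  sex <- match.arg(sex, c("male", "female"))
  combine <- match.arg(combine)
  if (any(!is.finite(age) | age <= 20)) {
    stop("ESC SCORE requires age > 20 years", call. = FALSE)
  }
  if (any(!is.finite(chol_mmol)) || any(!is.finite(sbp))) {
    stop("cholesterol (mmol/L) and SBP must be known", call. = FALSE)
  }
  causes <- coeffs$strata[[sex]]
  ref <- coeffs$reference
  risk <- lapply(causes, function(cc) {
    s0_now <- exp(-exp(cc$alpha) * (age - 20)^cc$p)
    s0_then <- exp(-exp(cc$alpha) * (age + 10 - 20)^cc$p)
    w <- exp(cc$beta_chol * (chol_mmol - ref$chol_mmol) +
             cc$beta_sbp * (sbp - ref$sbp_mmhg) +
             cc$beta_smoker * as.numeric(smoker))
    1 - (s0_then / s0_now)^w
  })
  if (combine == "sum") {
    pmin(1, risk$chd + risk$non_chd_cvd)
  } else {
    1 - (1 - risk$chd) * (1 - risk$non_chd_cvd)
  }
}

# ---- risk-equation objects -------------------------------------------------
# A risk equation bundles an identifier with a prediction rule over cohorts,
# so original and recalibrated scores share one interface.

#' Risk equation constructors
#'
#' Wrap a coefficient set into an equation object usable with
#' [predict_risk()]. `pce_equation()` predicts 10-year ASCVD risk;
#' `esc_equation()` predicts 10-year cardiovascular mortality (cholesterol
#' is derived from the mg/dL column via the fixed conversion).
#'
#' @param coeffs a `pce_coeffs` / `esc_coeffs` object.
#' @param id equation identifier used in reports.
#' @param combine for `esc_equation()`, the cause-combination rule
#'   (see [esc_risk10()]).
#' @return a `risk_equation` object.
#' @export
pce_equation <- function(coeffs = read_pce_coeffs(), id = "pce_original") {
  stopifnot(inherits(coeffs, "pce_coeffs"))
  structure(list(id = id, coeffs = coeffs),
            class = c("pce_equation", "risk_equation"))
}

#' @rdname pce_equation
#' @export
esc_equation <- function(coeffs = read_esc_coeffs(), id = "esc_low_risk",
                         combine = "sum") {
  stopifnot(inherits(coeffs, "esc_coeffs"))
  structure(list(id = id, coeffs = coeffs, combine = combine),
            class = c("esc_equation", "risk_equation"))
}

#' Predict per-subject 10-year risk for a cohort
#'
#' Pure function of the cohort rows: permuting rows permutes predictions
#' identically.
#'
#' @param eq a `risk_equation`.
#' @param x a [cohort()].
#' @param ... passed to methods.
#' @return a data frame with columns `subject_id`, `equation`, `risk10` and
#'   (for PCE-form equations) `linear_predictor`.
#' @export
predict_risk <- function(eq, x, ...) UseMethod("predict_risk")

#' @export
predict_risk.pce_equation <- function(eq, x, ...) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)
  need <- c("age", "total_chol_mgdl", "hdl_mgdl", "sbp_mmhg", "bp_treated",
            "smoker", "diabetes")
  .require_complete_for_prediction(df, need, eq$id)
  lp <- numeric(nrow(df))
  risk <- numeric(nrow(df))
  for (sx in c("male", "female")) {
    idx <- df$sex == if (sx == "male") "M" else "F"
    if (!any(idx)) next
    lp[idx] <- pce_linear_predictor(sx, df$age[idx], df$total_chol_mgdl[idx],
                                    df$hdl_mgdl[idx], df$sbp_mmhg[idx],
                                    df$bp_treated[idx], df$smoker[idx],
                                    df$diabetes[idx], eq$coeffs)
    stratum <- eq$coeffs$strata[[sx]]
    risk[idx] <- 1 - stratum$s0_10 ^ exp(lp[idx] - stratum$mean_lp)
  }
  data.frame(subject_id = df$subject_id, equation = eq$id, risk10 = risk,
             linear_predictor = lp, stringsAsFactors = FALSE)
}

#' @export
predict_risk.esc_equation <- function(eq, x, ...) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)
  .require_complete_for_prediction(df, c("age", "total_chol_mgdl", "sbp_mmhg",
                                         "smoker"), eq$id)
  chol <- chol_mgdl_to_mmoll(df$total_chol_mgdl)
  risk <- numeric(nrow(df))
  for (sx in c("male", "female")) {
    idx <- df$sex == if (sx == "male") "M" else "F"
    if (!any(idx)) next
    risk[idx] <- esc_risk10(sx, df$age[idx], chol[idx], df$sbp_mmhg[idx],
                            df$smoker[idx], eq$coeffs, combine = eq$combine)
  }
  data.frame(subject_id = df$subject_id, equation = eq$id, risk10 = risk,
             stringsAsFactors = FALSE)
}

.require_complete_for_prediction <- function(df, cols, id) {
  for (col in cols) {
    bad <- is.na(df[[col]])
    if (any(bad)) {
      stop("equation '", id, "' needs '", col, "' but it is missing for ",
           "subject(s): ", paste(utils::head(df$subject_id[bad], 5L),
                                 collapse = ", "),
           if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L),
           call. = FALSE)
    }
  }
}

#' @export
print.risk_equation <- function(x, ...) {
  cat("<risk_equation '", x$id, "'>\n", sep = "")
  invisible(x)
}
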