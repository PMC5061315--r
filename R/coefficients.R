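# Versioned coefficient sets for the risk equations. Constants live in JSON
# files (inst/extdata ships the defaults); code only interprets them.

#' @importFrom jsonlite read_json write_json
NULL

.pce_term_names <- c(
  "ln_age", "ln_age_sq", "ln_tc", "ln_age_ln_tc", "ln_hdl", "ln_age_ln_hdl",
  "ln_sbp_treated", "ln_age_ln_sbp_treated",
  "ln_sbp_untreated", "ln_age_ln_sbp_untreated",
  "smoker", "ln_age_smoker", "diabetes")

#' Load a Pooled Cohort Equations coefficient set
#'
#' Reads a JSON constants file with schema
#' `{equation, version, source_citation, strata: [{sex, (race), terms:
#' {name: value}, mean_lp, s0_10}]}`. Term names not present in a stratum
#' carry coefficient 0. `mean_lp` is the population mean of the linear
#' predictor and `s0_10` the baseline 10-year survival.
#'
#' @param path JSON file; defaults to the white/other strata file shipped
#'   with the package.
#' @return a `pce_coeffs` object.
#' @export
read_pce_coeffs <- function(path = system.file("extdata",
                                               "pce_pooled_cohort_white.json",
                                               package = "cvrecal")) {
  raw <- read_json(path, simplifyVector = FALSE)
  if (is.null(raw$equation) || raw$equation != "pce") {
    stop("not a PCE coefficient file: ", path, call. = FALSE)
  }
  strata <- list()
  for (s in raw$strata) {
    terms <- vapply(s$terms, as.numeric, numeric(1))
    unknown <- setdiff(names(terms), .pce_term_names)
    if (length(unknown) > 0L) {
      stop("unknown PCE term(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    full <- stats::setNames(numeric(length(.pce_term_names)), .pce_term_names)
    full[names(terms)] <- terms
    s0 <- as.numeric(s$s0_10)
    if (!(s0 > 0 && s0 < 1)) stop("s0_10 must lie in (0,1)", call. = FALSE)
    strata[[s$sex]] <- list(terms = full, mean_lp = as.numeric(s$mean_lp),
                            s0_10 = s0, race = s$race)
  }
  if (!all(c("male", "female") %in% names(strata))) {
    stop("PCE coefficient file must provide male and female strata",
         call. = FALSE)
  }
  structure(list(version = raw$version,
                 source_citation = raw$source_citation,
                 strata = strata,
                 recalibration = raw$recalibration),
            class = "pce_coeffs")
}

#' Load an ESC SCORE coefficient set
#'
#' Reads a JSON constants file holding, per sex and per cause
#' (`chd`, `non_chd_cvd`), the Weibull baseline parameters `alpha` and `p`
#' and the log-hazard-ratio coefficients `beta_smoker`, `beta_chol`
#' (per mmol/L), `beta_sbp` (per mmHg), plus the reference profile
#' (cholesterol 6 mmol/L, SBP 120 mmHg).
#'
#' @param path JSON file; defaults to the low-risk region file shipped with
#'   the package.
#' @return an `esc_coeffs` object.
#' @export
read_esc_coeffs <- function(path = system.file("extdata",
                                               "esc_score_low_risk.json",
                                               package = "cvrecal")) {
  raw <- read_json(path, simplifyVector = FALSE)
  if (is.null(raw$equation) || raw$equation != "esc_score") {
    stop("not an ESC SCORE coefficient file: ", path, call. = FALSE)
  }
  strata <- list()
  for (s in raw$strata) {
    causes <- lapply(s$causes, function(cc) {
      out <- lapply(cc, as.numeric)
      if (out$p <= 0) stop("Weibull shape p must be > 0", call. = FALSE)
      out
    })
    if (!all(c("chd", "non_chd_cvd") %in% names(causes))) {
      stop("ESC stratum must define causes chd and non_chd_cvd",
           call. = FALSE)
    }
    strata[[s$sex]] <- causes
  }
  if (!all(c("male", "female") %in% names(strata))) {
    stop("ESC coefficient file must provide male and female strata",
         call. = FALSE)
  }
  structure(list(version = raw$version,
                 source_citation = raw$source_citation,
                 reference = list(chol_mmol = as.numeric(raw$reference$chol_mmol),
                                  sbp_mmhg = as.numeric(raw$reference$sbp_mmhg)),
                 strata = strata),
            class = "esc_coeffs")
}

#' @export
print.pce_coeffs <- function(x, ...) {
  cat("<pce_coeffs ", x$version, "> strata: ",
      paste(names(x$strata), collapse = ", "), "\n", sep = "")
  if (!is.null(x$recalibration)) {
    cat("recalibrated: correction =",
        format(x$recalibration$correction, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
print.esc_coeffs <- function(x, ...) {
  cat("<esc_coeffs ", x$version, "> strata: ",
      paste(names(x$strata), collapse = ", "), "\n", sep = "")
  invisible(x)
}
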