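# Cohort data model, delimited-text I/O, unit conversion, exclusion filters
# and administrative censoring at the 10-year horizon.

#' @importFrom utils read.table write.table
NULL

# canonical column order and types of the cohort file format
.cohort_cols <- c(
  subject_id      = "character",
  sex             = "sex",
  age             = "numeric",
  total_chol_mgdl = "numeric",
  hdl_mgdl        = "numeric",
  sbp_mmhg        = "numeric",
  bp_treated      = "logical",
  smoker          = "logical",
  diabetes        = "logical",
  prev_chf        = "logical",
  prev_mi         = "logical",
  prev_stroke     = "logical",
  fu_ascvd_years  = "numeric",
  event_ascvd     = "logical",
  fu_cvdeath_years = "numeric",
  event_cvdeath   = "logical"
)

# fields that must be non-missing for every subject (structural, not an
# exclusion criterion)
.cohort_mandatory <- c("subject_id", "sex")

#' Construct a cohort
#'
#' A cohort is a data frame with one row per subject and a fixed column set
#' (see [read_cohort()] for the file format), plus a name and an exclusion
#' log carried as attributes.
#'
#' @param subjects data frame holding the cohort columns. Missing values
#'   encode "unknown". Logical columns may be given as 0/1.
#' @param name cohort label used in reports.
#' @param exclusion_log named integer vector of per-criterion removal counts
#'   (normally written by [apply_exclusions()]).
#' @return an object of class `cohort` (a data frame).
#' @export
cohort <- function(subjects, name = "cohort", exclusion_log = integer(0)) {
  stopifnot(is.data.frame(subjects))
  missing_cols <- setdiff(names(.cohort_cols), names(subjects))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  subjects <- as.data.frame(subjects)[, names(.cohort_cols)]
  for (col in names(.cohort_cols)) {
    subjects[[col]] <- switch(.cohort_cols[[col]],
      character = as.character(subjects[[col]]),
      numeric   = as.numeric(subjects[[col]]),
      logical   = .as_flag(subjects[[col]], col),
      sex       = .as_sex(subjects[[col]])
    )
  }
  .validate_subjects(subjects)
  structure(subjects,
            class = c("cohort", "data.frame"),
            cohort_name = name,
            exclusion_log = exclusion_log)
}

.as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop("column '", col, "' must be 0/1/empty", call. = FALSE)
    return(x == 1)
  }
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% c("0", "1", "TRUE", "FALSE"))
  if (any(bad)) stop("column '", col, "' must be 0/1/empty", call. = FALSE)
  out <- rep(NA, length(x))
  out[!is.na(x)] <- x[!is.na(x)] %in% c("1", "TRUE")
  out
}

.as_sex <- function(x) {
  x <- toupper(as.character(x))
  bad <- is.na(x) | !(x %in% c("M", "F"))
  if (any(bad)) {
    stop("sex must be 'M' or 'F' (row ", which(bad)[1L], ")", call. = FALSE)
  }
  x
}

.validate_subjects <- function(df) {
  if (anyDuplicated(df$subject_id)) {
    stop("subject_id values must be unique", call. = FALSE)
  }
  for (col in c("age", "total_chol_mgdl", "hdl_mgdl", "sbp_mmhg")) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad)) {
      stop("column '", col, "' must be positive (row ", which(bad)[1L], ")",
           call. = FALSE)
    }
  }
  for (col in c("fu_ascvd_years", "fu_cvdeath_years")) {
    bad <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(bad)) {
      stop("column '", col, "' must be non-negative (row ", which(bad)[1L],
           ")", call. = FALSE)
    }
  }
  # unknown event indicator implies unknown follow-up time for that endpoint
  for (ep in list(c("event_ascvd", "fu_ascvd_years"),
                  c("event_cvdeath", "fu_cvdeath_years"))) {
    bad <- is.na(df[[ep[1L]]]) & !is.na(df[[ep[2L]]])
    if (any(bad)) {
      stop("'", ep[2L], "' present while '", ep[1L], "' is unknown (row ",
           which(bad)[1L], ")", call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort '", cohort_name(x), "'> ", nrow(x), " subjects\n", sep = "")
  log <- exclusion_log(x)
  if (length(log) > 0L) {
    cat("exclusions:",
        paste(names(log), log, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Cohort name and exclusion log accessors
#' @param x a `cohort`.
#' @return `cohort_name()`: the label; `exclusion_log()`: named integer
#'   vector of per-criterion removal counts.
#' @export
cohort_name <- function(x) attr(x, "cohort_name", exact = TRUE)

#' @rdname cohort_name
#' @export
exclusion_log <- function(x) {
  log <- attr(x, "exclusion_log", exact = TRUE)
  if (is.null(log)) integer(0) else log
}

#' Read a cohort from delimited text
#'
#' The file is UTF-8 delimited text (comma by default, tab accepted) with a
#' header row naming exactly these columns: `subject_id`, `sex` (M/F),
#' `age`, `total_chol_mgdl`, `hdl_mgdl`, `sbp_mmhg`, `bp_treated` (0/1),
#' `smoker` (0/1), `diabetes` (0/1), `prev_chf`, `prev_mi`, `prev_stroke`
#' (0/1/empty), `fu_ascvd_years`, `event_ascvd` (0/1/empty),
#' `fu_cvdeath_years`, `event_cvdeath` (0/1/empty). An empty cell encodes
#' "unknown". Units are taken as documented; no conversion is applied.
#'
#' @param path file to read.
#' @param delim field delimiter; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @param name cohort label; defaults to the file name without extension.
#' @return a [cohort()].
#' @export
read_cohort <- function(path, delim = NULL, name = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- read.table(path, sep = delim, header = TRUE, colClasses = "character",
                    na.strings = NULL, check.names = FALSE, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.cohort_cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(.cohort_cols)) {
    x <- raw[[col]]
    x[x == ""] <- NA_character_
    if (.cohort_cols[[col]] == "numeric") {
      num <- suppressWarnings(as.numeric(x))
      bad <- is.na(num) & !is.na(x)
      if (any(bad)) {
        stop("unparseable value '", x[bad][1L], "' in column '", col,
             "' at line ", which(bad)[1L] + 1L, " of ", path, call. = FALSE)
      }
      raw[[col]] <- num
    } else {
      raw[[col]] <- x
    }
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  cohort(raw, name = name)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()] on the documented column set: logical fields
#' are written as 0/1 and unknowns as empty cells.
#'
#' @param x a [cohort()].
#' @param path output file.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, delim = ",") {
  out <- as.data.frame(x)[, names(.cohort_cols)]
  for (col in names(.cohort_cols)) {
    if (.cohort_cols[[col]] == "logical") {
      out[[col]] <- ifelse(is.na(out[[col]]), "", as.integer(out[[col]]))
    }
  }
  write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Convert total cholesterol from mg/dL to mmol/L
#'
#' Uses the fixed constant 38.67 mg/dL per mmol/L.
#'
#' @param x cholesterol in mg/dL; must be positive.
#' @return cholesterol in mmol/L.
#' @export
chol_mgdl_to_mmoll <- function(x) {
  if (any(!is.na(x) & x <= 0)) {
    stop("cholesterol must be positive (mg/dL)", call. = FALSE)
  }
  x / 38.67
}

#' Exclusion configuration
#'
#' Encodes the baseline eligibility filters: an inclusive age window,
#' prevalent-disease exclusions, and completeness requirements. Subjects
#' with an *unknown* prevalent-disease flag are retained (prevalence cannot
#' be asserted).
#'
#' @param age_min,age_max inclusive age bounds in years (defaults 40, 79).
#' @param exclude_prevalent subset of `c("chf", "mi", "stroke")`; a subject
#'   with any listed flag known-true is removed.
#' @param require_complete column names that must be non-missing. Endpoint
#'   columns (`fu_*`/`event_*`) are accounted under the
#'   "missing endpoint" criterion, all others under "missing risk factor".
#' @return an `exclusion_config` object.
#' @export
exclusion_config <- function(age_min = 40, age_max = 79,
                             exclude_prevalent = c("chf", "mi", "stroke"),
                             require_complete = c(
                               "fu_ascvd_years", "event_ascvd",
                               "age", "total_chol_mgdl", "hdl_mgdl",
                               "sbp_mmhg", "bp_treated", "smoker",
                               "diabetes")) {
  if (!(age_min < age_max)) stop("age_min must be < age_max", call. = FALSE)
  exclude_prevalent <- match.arg(exclude_prevalent, c("chf", "mi", "stroke"),
                                 several.ok = TRUE)
  bad <- setdiff(require_complete, names(.cohort_cols))
  if (length(bad) > 0L) {
    stop("unknown require_complete field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(age_min = age_min, age_max = age_max,
                 exclude_prevalent = exclude_prevalent,
                 require_complete = require_complete),
            class = "exclusion_config")
}

#' Exclusion configuration for the cardiovascular-mortality endpoint
#'
#' Same filters as [exclusion_config()] but completeness is required for the
#' mortality endpoint and the risk factors the mortality equation uses.
#' These defaults are the package's own (the source studies' mortality-arm
#' flow chart is not asserted here).
#'
#' @inheritParams exclusion_config
#' @return an `exclusion_config` object.
#' @export
esc_exclusion_config <- function(age_min = 40, age_max = 79,
                                 exclude_prevalent = c("chf", "mi", "stroke")) {
  exclusion_config(age_min = age_min, age_max = age_max,
                   exclude_prevalent = exclude_prevalent,
                   require_complete = c(
                     "fu_cvdeath_years", "event_cvdeath",
                     "age", "total_chol_mgdl", "sbp_mmhg", "smoker"))
}

#' Apply eligibility exclusions to a cohort
#'
#' Removes subjects outside the age window, with a flagged prevalent
#' condition, or with missing required fields. Each removed subject is
#' counted once in the exclusion log, under the first criterion that
#' removes it, in the fixed order: `age`, `prevalent`, `missing_endpoint`,
#' `missing_risk_factor`. Idempotent.
#'
#' @param x a [cohort()]; must be non-empty.
#' @param cfg an [exclusion_config()].
#' @return the filtered `cohort`; its exclusion log holds the per-criterion
#'   counts, which sum to the number of removed subjects.
#' @export
apply_exclusions <- function(x, cfg = exclusion_config()) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "exclusion_config"))
  if (nrow(x) == 0L) stop("cohort is empty", call. = FALSE)

  df <- as.data.frame(x)
  out_age <- is.na(df$age) | df$age < cfg$age_min | df$age > cfg$age_max
  # missing age is an age-window failure only if age is not otherwise required;
  # treat unknown age as failing the window (cannot be confirmed in range)
  prev_cols <- paste0("prev_", cfg$exclude_prevalent)
  out_prev <- rep(FALSE, nrow(df))
  for (col in prev_cols) {
    out_prev <- out_prev | (!is.na(df[[col]]) & df[[col]])
  }
  endpoint_fields <- intersect(cfg$require_complete,
                               c("fu_ascvd_years", "event_ascvd",
                                 "fu_cvdeath_years", "event_cvdeath"))
  risk_fields <- setdiff(cfg$require_complete, endpoint_fields)
  out_ep <- rep(FALSE, nrow(df))
  for (col in endpoint_fields) out_ep <- out_ep | is.na(df[[col]])
  out_rf <- rep(FALSE, nrow(df))
  for (col in risk_fields) out_rf <- out_rf | is.na(df[[col]])

  crit <- rep(NA_character_, nrow(df))
  crit[out_rf] <- "missing_risk_factor"
  crit[out_ep] <- "missing_endpoint"
  crit[out_prev] <- "prevalent"
  crit[out_age] <- "age"

  keep <- is.na(crit)
  log <- c(age = sum(crit == "age", na.rm = TRUE),
           prevalent = sum(crit == "prevalent", na.rm = TRUE),
           missing_endpoint = sum(crit == "missing_endpoint", na.rm = TRUE),
           missing_risk_factor = sum(crit == "missing_risk_factor",
                                     na.rm = TRUE))
  cohort(df[keep, , drop = FALSE], name = cohort_name(x),
         exclusion_log = log)
}

#' Censor follow-up at a fixed horizon
#'
#' Administrative censoring: any follow-up time beyond the horizon is set to
#' the horizon and the corresponding event indicator to `FALSE` (an event
#' after the horizon does not count). Times exactly at the horizon are left
#' unchanged. Applied to both endpoints where known; unknown endpoint data
#' stay unknown.
#'
#' @param x a [cohort()].
#' @param horizon horizon in years (default 10).
#' @return the censored `cohort`.
#' @export
censor_at_horizon <- function(x, horizon = 10) {
  stopifnot(inherits(x, "cohort"), horizon > 0)
  df <- as.data.frame(x)
  for (ep in list(c("fu_ascvd_years", "event_ascvd"),
                  c("fu_cvdeath_years", "event_cvdeath"))) {
    over <- !is.na(df[[ep[1L]]]) & df[[ep[1L]]] > horizon
    df[[ep[2L]]][over] <- FALSE
    df[[ep[1L]]][over] <- horizon
  }
  cohort(df, name = cohort_name(x), exclusion_log = exclusion_log(x))
}
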