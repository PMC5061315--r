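# Fixtures built in code and independent brute-force oracles. The oracles
# deliberately re-state the definitions from scratch (double loops, literal
# formulas) and never call the implementation they check.

# small cohort data frame with complete fields
make_subjects <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(runif(n, 42, 75), 1),
    total_chol_mgdl = round(runif(n, 150, 300)),
    hdl_mgdl = round(runif(n, 30, 90)),
    sbp_mmhg = round(runif(n, 100, 180)),
    bp_treated = runif(n) < 0.25,
    smoker = runif(n) < 0.2,
    diabetes = runif(n) < 0.07,
    prev_chf = FALSE, prev_mi = FALSE, prev_stroke = FALSE,
    fu_ascvd_years = round(runif(n, 1, 12), 2),
    event_ascvd = runif(n) < 0.15,
    fu_cvdeath_years = round(runif(n, 1, 12), 2),
    event_cvdeath = runif(n) < 0.05,
    stringsAsFactors = FALSE)
}

make_cohort <- function(n, seed = 1, name = "toy") {
  cohort(make_subjects(n, seed), name = name)
}

# cohort with an exact event count and fixed follow-up
make_count_cohort <- function(n, events, fu = 8.6, seed = 1) {
  df <- make_subjects(n, seed = seed)
  df$fu_ascvd_years <- fu
  df$event_ascvd <- c(rep(TRUE, events), rep(FALSE, n - events))
  df$fu_cvdeath_years <- fu
  df$event_cvdeath <- FALSE
  cohort(df, name = "count")
}

# Harrell's C by a literal double loop over all unordered pairs, applying
# the normative rules: pair usable iff the smaller time belongs to an event
# (time ties: usable only if both are events, contributing 0.5); concordant
# iff the earlier event has the higher prediction; prediction ties 0.5.
bf_harrells_c <- function(p, t, e) {
  num <- 0; den <- 0
  n <- length(p)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (t[i] == t[j]) {
        if (e[i] && e[j]) { den <- den + 1; num <- num + 0.5 }
        next
      }
      a <- if (t[i] < t[j]) i else j   # earlier subject
      b <- if (t[i] < t[j]) j else i
      if (!e[a]) next
      den <- den + 1
      if (p[a] > p[b]) num <- num + 1
      else if (p[a] == p[b]) num <- num + 0.5
    }
  }
  list(c = num / den, usable = den)
}

# AUC as the Mann-Whitney U statistic over all case/control pairs
bf_auc <- function(p, e) {
  cases <- p[e]; controls <- p[!e]
  u <- 0
  for (a in cases) for (b in controls) {
    u <- u + (a > b) + 0.5 * (a == b)
  }
  u / (length(cases) * length(controls))
}

# literal transcription of the PCE formula chain for one profile,
# independent of the package's term-matrix code
bf_pce <- function(sex, age, tc, hdl, sbp, treated, smoker, diabetes) {
  la <- log(age)
  if (sex == "male") {
    lp <- 12.344 * la + 11.853 * log(tc) - 2.664 * la * log(tc) -
      7.990 * log(hdl) + 1.769 * la * log(hdl) +
      (if (treated) 1.797 else 1.764) * log(sbp) +
      7.837 * smoker - 1.795 * la * smoker + 0.658 * diabetes
    list(lp = lp, risk = 1 - 0.9144^exp(lp - 61.18))
  } else {
    lp <- -29.799 * la + 4.884 * la^2 + 13.540 * log(tc) -
      3.114 * la * log(tc) - 13.578 * log(hdl) + 3.149 * la * log(hdl) +
      (if (treated) 2.019 else 1.957) * log(sbp) +
      7.574 * smoker - 1.665 * la * smoker + 0.661 * diabetes
    list(lp = lp, risk = 1 - 0.9665^exp(lp + 29.18))
  }
}

# literal transcription of the ESC SCORE low-risk formula chain
bf_esc <- function(sex, age, chol, sbp, smoker) {
  par <- if (sex == "male") {
    list(chd = c(a = -22.1, p = 4.71), non = c(a = -26.7, p = 5.64))
  } else {
    list(chd = c(a = -29.8, p = 6.36), non = c(a = -31.0, p = 6.62))
  }
  betas <- list(chd = c(sm = 0.71, ch = 0.24, bp = 0.018),
                non = c(sm = 0.63, ch = 0.02, bp = 0.022))
  total <- 0
  for (cause in c("chd", "non")) {
    a <- par[[cause]][["a"]]; pp <- par[[cause]][["p"]]
    b <- betas[[cause]]
    s_now <- exp(-exp(a) * (age - 20)^pp)
    s_then <- exp(-exp(a) * (age + 10 - 20)^pp)
    w <- exp(b[["ch"]] * (chol - 6) + b[["bp"]] * (sbp - 120) +
             b[["sm"]] * smoker)
    total <- total + (1 - (s_then / s_now)^w)
  }
  min(1, total)
}
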