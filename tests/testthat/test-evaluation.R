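test_that("observed event frequency reproduces crude proportions", {
  expect_equal(round(100 * observed_event_frequency(
    make_count_cohort(5238, 383)), 1), 7.3)
  expect_equal(round(100 * observed_event_frequency(
    make_count_cohort(4208, 271)), 1), 6.4)
  expect_equal(observed_event_frequency(make_count_cohort(50, 0)), 0)
  expect_error(observed_event_frequency(make_cohort(5)[0, ]))

  # with no censoring before the horizon the KM estimate equals the crude
  # proportion (events all at fu < 10, censored exactly at 10)
  df <- make_subjects(200, seed = 41)
  df$fu_ascvd_years <- ifelse(df$event_ascvd, 5, 10)
  x <- cohort(df)
  expect_equal(observed_event_frequency(x, method = "km"),
               observed_event_frequency(x, method = "crude"),
               tolerance = 1e-12)
})

test_that("incidence rate is events per 1,000 person-years", {
  # 383 events over 5,238 x 8.6 person-years ~ 8.5 / 1,000 PY
  x <- make_count_cohort(5238, 383, fu = 8.6)
  expect_equal(incidence_rate(x), 1000 * 383 / (5238 * 8.6),
               tolerance = 1e-12)
  expect_equal(round(incidence_rate(x), 1), 8.5)

  df <- make_subjects(10, seed = 42)
  df$fu_ascvd_years <- 10
  df$event_ascvd <- c(TRUE, rep(FALSE, 9))
  expect_equal(incidence_rate(cohort(df)), 10)
  df$event_ascvd <- FALSE
  expect_equal(incidence_rate(cohort(df)), 0)
})

test_that("overestimation percentage follows its formula exactly", {
  expect_equal(overestimation_pct(10.0, 7.3), (10 / 7.3 - 1) * 100)
  expect_equal(round(overestimation_pct(10.0, 7.3), 2), 36.99)
  expect_equal(overestimation_pct(4.2, 4.2), 0)
  expect_equal(overestimation_pct(5, 10), -50)
  expect_error(overestimation_pct(5, 0), "positive")
  # sign convention: symmetric around equality
  expect_gt(overestimation_pct(8, 7), 0)
  expect_lt(overestimation_pct(6, 7), 0)
})

test_that("decile calibration groups by rank with ties collapsed", {
  # n = 10 distinct predictions: one subject per decile
  p <- seq(0.05, 0.5, by = 0.05)
  ev <- rep(c(TRUE, FALSE), 5)
  tab <- calibration_deciles(p, ev)
  body <- tab[tab$decile != "total", ]
  expect_equal(nrow(body), 10L)
  expect_equal(body$n, rep(1L, 10))
  expect_equal(body$mean_pred, sort(p))
  expect_false(attr(tab, "ties"))

  # totals row reproduces the whole-stratum quantities
  total <- tab[tab$decile == "total", ]
  expect_equal(total$mean_pred, mean(p))
  expect_equal(total$observed_freq, mean(ev))
  expect_equal(sum(body$n), length(p))

  # constant predictions collapse to a single flagged group
  tab2 <- calibration_deciles(rep(0.1, 50), rep(c(TRUE, FALSE), 25))
  expect_true(attr(tab2, "ties"))
  expect_equal(attr(tab2, "groups_effective"), 1L)
  expect_error(calibration_deciles(runif(5), rep(TRUE, 5)), "at least")
})

test_that("calibrated simulations land on the diagonal per decile", {
  set.seed(43)
  n <- 20000
  p <- plogis(rnorm(n, -2.5, 0.8))
  ev <- runif(n) < p
  tab <- calibration_deciles(p, ev)
  body <- tab[tab$decile != "total", ]
  within3 <- abs(body$mean_pred - body$observed_freq) <= 3 * body$se_pred
  expect_gte(sum(within3), 9L)
})

test_that("Harrell's C equals the brute-force pair count exactly", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    p <- round(runif(n), 2)              # forces prediction ties
    t <- round(rexp(n, 0.1), 1)          # forces time ties
    e <- runif(n) < 0.5
    if (sum(e) == 0) e[1] <- TRUE
    got <- harrells_c(p, t, e)
    want <- bf_harrells_c(p, t, e)
    expect_identical(got$usable, want$usable)
    expect_equal(got$c, want$c, tolerance = 1e-15)
  }
})

test_that("Harrell's C endpoints behave canonically", {
  # perfect ranking, no censoring: higher risk -> earlier event
  t <- c(1, 2, 3, 4, 5)
  p <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  e <- rep(TRUE, 5)
  expect_equal(harrells_c(p, t, e)$c, 1)
  # independent predictions at large n: C ~ 0.5
  set.seed(45)
  n <- 2000
  expect_equal(harrells_c(runif(n), rexp(n), rep(TRUE, n))$c, 0.5,
               tolerance = 0.05)
  # equal times with one censored are unusable
  expect_error(harrells_c(c(0.2, 0.8), c(5, 5), c(TRUE, FALSE)),
               "usable")
  # invariance under strictly increasing transforms
  x <- make_cohort(150, seed = 46)
  p0 <- predict_risk(pce_equation(), x)$risk10
  c0 <- harrells_c(p0, x$fu_ascvd_years, x$event_ascvd)$c
  expect_equal(harrells_c(plogis(qlogis(p0) + 2), x$fu_ascvd_years,
                          x$event_ascvd)$c, c0, tolerance = 1e-15)
  expect_equal(harrells_c(10 + 3 * p0, x$fu_ascvd_years,
                          x$event_ascvd)$c, c0, tolerance = 1e-15)
})

test_that("bootstrap CI is seeded and ordered", {
  x <- make_cohort(120, seed = 47)
  p <- predict_risk(pce_equation(), x)$risk10
  c1 <- harrells_c(p, x$fu_ascvd_years, x$event_ascvd, B = 100, seed = 5)
  c2 <- harrells_c(p, x$fu_ascvd_years, x$event_ascvd, B = 100, seed = 5)
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$c)
  expect_gte(c1$ci_high, c1$c)
  expect_error(harrells_c(p, x$fu_ascvd_years, x$event_ascvd, B = 10),
               "seed")
})

test_that("ROC export matches the Mann-Whitney U oracle", {
  set.seed(48)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    p <- round(runif(n), 2)
    e <- runif(n) < 0.4
    if (sum(e) == 0) e[1] <- TRUE
    if (sum(!e) == 0) e[1] <- FALSE
    r <- roc_export(p, e)
    expect_equal(r$auc, bf_auc(p, e), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(r$points$tpr >= 0 & r$points$tpr <= 1))
  }
  # canonical endpoints
  expect_equal(roc_export(c(0.9, 0.8, 0.2, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_export(rep(0.3, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_export(runif(5), rep(TRUE, 5)), "classes")

  # when the only event precedes all censoring times, C reduces exactly
  # to the one-case AUC (no event-event pairs exist); with several events
  # C and AUC differ only through the within-event pairs, so they stay
  # close when events are few
  p <- runif(40); e <- c(TRUE, rep(FALSE, 39))
  t <- c(2, runif(39, 5, 10))
  expect_equal(harrells_c(p, t, e)$c, roc_export(p, e)$auc,
               tolerance = 1e-12)
  p2 <- runif(60); e2 <- c(rep(TRUE, 5), rep(FALSE, 55))
  t2 <- c(runif(5, 0, 4), runif(55, 5, 10))
  expect_equal(harrells_c(p2, t2, e2)$c, roc_export(p2, e2)$auc,
               tolerance = 0.05)

  # file export round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  roc_export(p, e, path = path)
  back <- read.csv(path)
  expect_equal(names(back), c("threshold", "fpr", "tpr"))
})

test_that("evaluation reports are internally consistent", {
  x <- censor_at_horizon(make_cohort(400, seed = 49))
  r <- evaluation_report(x, pce_equation(), B = 50, seed = 3)
  expect_equal(r$overestimation_pct,
               overestimation_pct(r$mean_estimated_pct,
                                  r$observed_freq_pct))
  expect_s3_class(r$calibration, "calibration_table")
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_report_table(list(r), path)
  expect_true(file.exists(path))
  expect_equal(tab$overestimation_pct,
               overestimation_pct(tab$estimated_pct, tab$observed_pct))
})
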