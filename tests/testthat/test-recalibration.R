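test_that("correction factor follows the log odds-ratio definition", {
  # identical odds -> zero correction
  p <- rep(0.2, 10)
  ev <- c(rep(TRUE, 2), rep(FALSE, 8))
  f <- compute_correction(p, ev)
  expect_equal(f$correction, 0)
  expect_equal(f$observed_freq, 0.2)
  expect_equal(f$mean_pred, 0.2)
  expect_equal(f$n, 10L)

  # hand-arithmetic oracle: O = 0.0692, mean pred = 0.103
  p2 <- rep(0.103, 10000)
  ev2 <- rep(FALSE, 10000); ev2[seq_len(692)] <- TRUE
  f2 <- compute_correction(p2, ev2)
  expect_equal(f2$correction, -0.4347, tolerance = 1e-4 / 0.4347)
  expect_equal(f2$correction,
               log((0.0692 / (1 - 0.0692)) / (0.103 / (1 - 0.103))),
               tolerance = 1e-12)

  # degenerate inputs
  expect_error(compute_correction(rep(0.1, 5), rep(TRUE, 5)), "degenerate")
  expect_error(compute_correction(rep(0.1, 5), rep(FALSE, 5)), "degenerate")
})

test_that("apply_correction is an exact, invertible logit shift", {
  p <- c(0.01, 0.2, 0.5, 0.77, 0.99)
  expect_equal(apply_correction(p, 0), p)
  expect_equal(apply_correction(0.5, log(2)), 2 / 3, tolerance = 1e-12)
  # invertibility
  cc <- -0.73
  expect_equal(apply_correction(apply_correction(p, cc), -cc), p,
               tolerance = 1e-12)
  # strict monotonicity preserves rank order exactly
  set.seed(31)
  q <- runif(200, 0.01, 0.6)
  expect_equal(order(apply_correction(q, -1.2)), order(q))
  expect_error(apply_correction(c(0.2, 1), 0.5), "degenerate")
  expect_error(apply_correction(0, 0.5), "degenerate")
})

test_that("recalibrate_equation wraps the correction without touching the original", {
  x <- censor_at_horizon(make_cohort(400, seed = 32))
  eq <- pce_equation()
  req <- recalibrate_equation(eq, x, endpoint = "ascvd")
  p0 <- predict_risk(eq, x)
  p1 <- predict_risk(req, x)
  expect_equal(p1$risk10,
               apply_correction(p0$risk10, req$recalibration$correction),
               tolerance = 1e-15)
  expect_equal(p1$equation, rep("pce_original_recalibrated", 400))
  # original equation untouched
  expect_equal(predict_risk(eq, x)$risk10, p0$risk10)
  # recalibration moves the mean prediction onto the observed frequency
  # at least as closely as before
  obs <- mean(x$event_ascvd)
  expect_lte(abs(mean(p1$risk10) - obs), abs(mean(p0$risk10) - obs))

  # two disjoint training cohorts: different c, same ranking
  xa <- censor_at_horizon(make_cohort(300, seed = 33, name = "a"))
  xb <- censor_at_horizon(make_cohort(300, seed = 34, name = "b"))
  ra <- recalibrate_equation(eq, xa)
  rb <- recalibrate_equation(eq, xb)
  expect_false(isTRUE(all.equal(ra$recalibration$correction,
                                rb$recalibration$correction)))
  expect_equal(order(predict_risk(ra, x)$risk10),
               order(predict_risk(rb, x)$risk10))
})

test_that("Harrell's C is invariant under recalibration", {
  x <- censor_at_horizon(make_cohort(500, seed = 35))
  eq <- pce_equation()
  req <- recalibrate_equation(eq, x)
  p0 <- predict_risk(eq, x)$risk10
  p1 <- predict_risk(req, x)$risk10
  c0 <- harrells_c(p0, x$fu_ascvd_years, x$event_ascvd)
  c1 <- harrells_c(p1, x$fu_ascvd_years, x$event_ascvd)
  expect_identical(c0$usable, c1$usable)
  expect_equal(c0$c, c1$c, tolerance = 1e-15)
})

test_that("exponent-mode recalibration shifts the survival exponent", {
  x <- censor_at_horizon(make_cohort(300, seed = 36))
  eq <- pce_equation()
  req <- recalibrate_equation(eq, x, mode = "exponent")
  p0 <- predict_risk(eq, x)
  p1 <- predict_risk(req, x)
  cc <- req$recalibration$correction
  cf <- eq$coeffs
  expected <- p0$risk10
  for (sx in c("male", "female")) {
    idx <- x$sex == if (sx == "male") "M" else "F"
    st <- cf$strata[[sx]]
    expected[idx] <- 1 - st$s0_10 ^
      (exp(p0$linear_predictor[idx] - st$mean_lp) * exp(cc))
  }
  expect_equal(p1$risk10, expected, tolerance = 1e-15)
  expect_error(recalibrate_equation(esc_equation(), x, mode = "exponent"),
               "PCE")
})

test_that("recalibrated equations serialize and reload identically", {
  x <- censor_at_horizon(make_cohort(300, seed = 37))
  req <- recalibrate_equation(pce_equation(), x, id = "pce_recalibrated")
  path <- withr::local_tempfile(fileext = ".json")
  write_equation(req, path)
  back <- read_equation(path)
  expect_s3_class(back, "recal_equation")
  expect_equal(predict_risk(back, x)$risk10, predict_risk(req, x)$risk10,
               tolerance = 1e-12)
  # a plain equation round-trips too
  path2 <- withr::local_tempfile(fileext = ".json")
  write_equation(pce_equation(), path2)
  plain <- read_equation(path2)
  expect_equal(predict_risk(plain, x)$risk10,
               predict_risk(pce_equation(), x)$risk10, tolerance = 1e-12)
})

test_that("k-fold cross-validation is seeded, stratified and tolerant at k = n", {
  x <- censor_at_horizon(make_cohort(200, seed = 38))
  cv1 <- kfold_cross_validate(x, pce_equation(), k = 5, seed = 99)
  cv2 <- kfold_cross_validate(x, pce_equation(), k = 5, seed = 99)
  expect_identical(cv1, cv2)   # bit-for-bit determinism
  cv3 <- kfold_cross_validate(x, pce_equation(), k = 5, seed = 100)
  expect_false(identical(cv1$folds, cv3$folds))
  expect_equal(nrow(cv1$folds), 5L)
  expect_equal(sum(cv1$folds$n), 200L)
  # event stratification keeps fold event counts within 1 of each other
  expect_lte(diff(range(cv1$folds$events)), 1L)

  # leave-one-out on a 20-subject toy cohort runs and returns 20 entries
  toy <- censor_at_horizon(make_cohort(20, seed = 39))
  loo <- kfold_cross_validate(toy, pce_equation(), k = 20, seed = 7)
  expect_equal(nrow(loo$folds), 20L)

  expect_error(kfold_cross_validate(x, pce_equation(), k = 1, seed = 1),
               "k")
  expect_error(kfold_cross_validate(x, pce_equation(), k = 5), "seed")
})
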