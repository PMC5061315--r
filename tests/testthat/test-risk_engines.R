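# hand-specified profiles: sex, age, TC, HDL, SBP, treated, smoker, diabetes
pce_profiles <- list(
  list("male",   55, 213,  50, 120, FALSE, FALSE, FALSE),
  list("female", 55, 213,  50, 120, FALSE, FALSE, FALSE),
  list("male",   62, 260,  42, 150, TRUE,  TRUE,  FALSE),
  list("female", 48, 190,  70, 110, FALSE, FALSE, TRUE),
  list("male",   71, 230,  55, 165, TRUE,  FALSE, TRUE),
  list("female", 66, 280,  38, 140, FALSE, TRUE,  FALSE))

test_that("PCE linear predictor matches a literal hand computation", {
  for (pr in pce_profiles) {
    oracle <- do.call(bf_pce, pr)
    lp <- pce_linear_predictor(pr[[1]], pr[[2]], pr[[3]], pr[[4]], pr[[5]],
                               pr[[6]], pr[[7]], pr[[8]])
    expect_equal(lp, oracle$lp, tolerance = 1e-12)
    risk <- pce_risk10(pr[[1]], pr[[2]], pr[[3]], pr[[4]], pr[[5]],
                       pr[[6]], pr[[7]], pr[[8]])
    expect_equal(risk, oracle$risk, tolerance = 1e-9)
  }
})

test_that("PCE reference profiles agree with the published worked example", {
  # 55-year-old, TC 213 mg/dL, HDL 50, SBP 120 untreated, nonsmoker,
  # nondiabetic: displayed 10-year risks ~5.4% (men) and 2.1% (women)
  m <- pce_risk10("male", 55, 213, 50, 120, FALSE, FALSE, FALSE)
  f <- pce_risk10("female", 55, 213, 50, 120, FALSE, FALSE, FALSE)
  expect_equal(100 * m, 5.4, tolerance = 0.1 / 5.4)
  expect_equal(100 * f, 2.1, tolerance = 0.1 / 2.1)
})

test_that("PCE structural identities hold", {
  # zero coefficients -> LP 0 regardless of inputs
  zero <- read_pce_coeffs()
  for (sx in c("male", "female")) zero$strata[[sx]]$terms[] <- 0
  expect_equal(pce_linear_predictor("male", 60, 200, 50, 130, TRUE, TRUE,
                                    TRUE, coeffs = zero), 0)

  # doubling untreated SBP shifts the male LP by coef_ln_sbp_untreated*ln 2
  cf <- read_pce_coeffs()
  lp1 <- pce_linear_predictor("male", 60, 200, 50, 110, FALSE, FALSE, FALSE)
  lp2 <- pce_linear_predictor("male", 60, 200, 50, 220, FALSE, FALSE, FALSE)
  expect_equal(lp2 - lp1,
               cf$strata$male$terms[["ln_sbp_untreated"]] * log(2),
               tolerance = 1e-12)

  # LP equal to mean_lp gives risk 1 - s0_10
  cf2 <- read_pce_coeffs()
  lp <- pce_linear_predictor("female", 60, 200, 50, 130, FALSE, FALSE, FALSE)
  cf2$strata$female$mean_lp <- lp
  expect_equal(pce_risk10("female", 60, 200, 50, 130, FALSE, FALSE, FALSE,
                          coeffs = cf2), 1 - cf2$strata$female$s0_10)
})

test_that("PCE risk is monotone in each risk factor", {
  base <- list(60, 200, 50, 130, FALSE, FALSE, FALSE)
  for (sx in c("male", "female")) {
    r0 <- do.call(pce_risk10, c(sx, base))
    expect_gt(do.call(pce_risk10, c(sx, list(60, 260, 50, 130, FALSE,
                                             FALSE, FALSE))), r0)  # TC up
    expect_lt(do.call(pce_risk10, c(sx, list(60, 200, 80, 130, FALSE,
                                             FALSE, FALSE))), r0)  # HDL up
    expect_gt(do.call(pce_risk10, c(sx, list(60, 200, 50, 170, FALSE,
                                             FALSE, FALSE))), r0)  # SBP up
    expect_gt(do.call(pce_risk10, c(sx, list(60, 200, 50, 130, FALSE,
                                             TRUE, FALSE))), r0)   # smoker
    expect_gt(do.call(pce_risk10, c(sx, list(60, 200, 50, 130, FALSE,
                                             FALSE, TRUE))), r0)   # diabetes
  }
})

test_that("PCE input contracts are enforced", {
  expect_error(pce_risk10("male", -1, 200, 50, 130, FALSE, FALSE, FALSE),
               "positive")
  expect_error(pce_risk10("male", 60, 0, 50, 130, FALSE, FALSE, FALSE),
               "positive")
  expect_error(pce_linear_predictor("neither", 60, 200, 50, 130, FALSE,
                                    FALSE, FALSE))
})

test_that("ESC SCORE matches a literal evaluation of the formula chain", {
  cases <- list(list("male", 55, 6.0, 140, TRUE),
                list("male", 55, 6.0, 120, FALSE),
                list("female", 62, 7.2, 160, TRUE),
                list("male", 45, 5.0, 120, FALSE),
                list("female", 70, 6.5, 135, FALSE))
  for (cs in cases) {
    expect_equal(esc_risk10(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]]),
                 do.call(bf_esc, cs), tolerance = 1e-12)
  }
})

test_that("ESC reference profile reduces to the baseline identity", {
  # at chol 6 mmol/L, SBP 120, nonsmoker all w_c = 1 and the risk is the
  # sum of baseline cause risks
  cf <- read_esc_coeffs()
  for (sx in c("male", "female")) {
    age <- 58
    expected <- sum(vapply(cf$strata[[sx]], function(cc) {
      1 - exp(-exp(cc$alpha) * (age + 10 - 20)^cc$p) /
        exp(-exp(cc$alpha) * (age - 20)^cc$p)
    }, numeric(1)))
    expect_equal(esc_risk10(sx, age, 6, 120, FALSE), expected,
                 tolerance = 1e-12)
  }
})

test_that("ESC risk increases with age and rejects age <= 20", {
  ages <- seq(40, 70, by = 5)
  risks <- esc_risk10("male", ages, 6, 140, TRUE)
  expect_true(all(diff(risks) > 0))
  expect_error(esc_risk10("male", 20, 6, 140, TRUE), "age")
  # combine modes: complement is bounded by the sum
  s <- esc_risk10("female", 65, 7, 150, TRUE, combine = "sum")
  p <- esc_risk10("female", 65, 7, 150, TRUE, combine = "complement")
  expect_lte(p, s)
})

test_that("predictions stay in [0,1] with no NaN across the input domain", {
  grid <- expand.grid(age = c(40, 55, 79), tc = c(100, 250, 400),
                      hdl = c(20, 60, 120), sbp = c(80, 150, 220),
                      treated = c(FALSE, TRUE), smoker = c(FALSE, TRUE),
                      diabetes = c(FALSE, TRUE))
  for (sx in c("male", "female")) {
    r <- pce_risk10(sx, grid$age, grid$tc, grid$hdl, grid$sbp,
                    grid$treated, grid$smoker, grid$diabetes)
    expect_true(all(is.finite(r) & r >= 0 & r <= 1))
    e <- esc_risk10(sx, grid$age, chol_mgdl_to_mmoll(grid$tc), grid$sbp,
                    grid$smoker)
    expect_true(all(is.finite(e) & e >= 0 & e <= 1))
  }
})

test_that("cohort prediction is a pure function of rows", {
  x <- make_cohort(50, seed = 21)
  eq <- pce_equation()
  p1 <- predict_risk(eq, x)
  perm <- sample(seq_len(50))
  x2 <- cohort(as.data.frame(x)[perm, ], name = "perm")
  p2 <- predict_risk(eq, x2)
  expect_equal(p2$risk10, p1$risk10[perm], tolerance = 1e-15)
  expect_equal(p2$subject_id, p1$subject_id[perm])

  # missing required field names the offending subjects
  df <- make_subjects(4, seed = 22)
  df$total_chol_mgdl[c(2, 4)] <- NA
  expect_error(predict_risk(esc_equation(), cohort(df)), "s002")
})
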