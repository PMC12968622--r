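test_that("allometric scaling follows the power law", {
  p70 <- pk_params(10, 60, 30, 6, 2, 1.5, 0.3)
  expect_equal(unclass(scale_parameters(p70, 70)), unclass(p70))
  p35 <- scale_parameters(p70, 35)
  expect_equal(p35[["cl_f"]], 10 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(p35[["q_f"]], 6 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(p35[["vc_f"]], 30, tolerance = 1e-12)
  expect_equal(p35[["vp_f"]], 15, tolerance = 1e-12)
  expect_equal(p35[["ka"]], 2)
  expect_equal(p35[["d1"]], 1.5)
  # zero exponents: identity for any weight
  s0 <- allometric_spec(exp_flow = 0, exp_volume = 0)
  expect_equal(unclass(scale_parameters(p70, 23.7, s0)), unclass(p70))
  expect_error(scale_parameters(p70, -5), "positive")
})

test_that("weight sampling is truncated, seeded and matches analytic moments", {
  w <- sample_weights(1e5, 38.1, 16.8, c(15, 90), seed = 11)
  expect_gte(min(w), 15)
  expect_lte(max(w), 90)
  # closed-form truncated-normal mean
  a <- (15 - 38.1) / 16.8; b <- (90 - 38.1) / 16.8
  mu_trunc <- 38.1 + 16.8 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(w) - mu_trunc), 0.5)
  expect_identical(w, sample_weights(1e5, 38.1, 16.8, c(15, 90), seed = 11))
  expect_error(sample_weights(10, 38.1, 2, c(80, 90)), "degenerate")
})

test_that("lognormal IIV has the constructed log-scale SD and median", {
  typ <- pk_params(10, 60, 30, 6, 2, 1.5, 0.3)
  om0 <- omega_spec()
  expect_equal(unclass(apply_iiv(typ, om0, seed = 1)), unclass(typ))
  om <- omega_spec(cl_f = 0.0625)
  P <- apply_iiv(typ, om, n = 1e5, seed = 2)
  expect_lt(abs(sd(log(P[, "cl_f"])) - 0.25), 0.005)
  expect_lt(abs(median(P[, "cl_f"]) / 10 - 1), 0.01)
  # vc_f carries no random effect
  expect_equal(unname(P[, "vc_f"]), rep(60, 1e5))
})

test_that("scaling and IIV commute exactly", {
  typ <- pk_params(10, 60, 30, 6, 2, 1.5, 0.3)
  om <- omega_spec(cl_f = 0.05, vp_f = 0.09, q_f = 0.09, d1 = 0.09,
                   ka = 0.09, alag1 = 0.09)
  a <- apply_iiv(scale_parameters(typ, 20), om, n = 500, seed = 5)
  set.seed(5)
  b <- apply_iiv(typ, om, n = 500, seed = 5)
  b[, c("cl_f", "q_f")] <- b[, c("cl_f", "q_f")] * (20 / 70)^0.75
  b[, c("vc_f", "vp_f")] <- b[, c("vc_f", "vp_f")] * (20 / 70)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("typical AUC ratio between weights is parameter-free", {
  for (p in random_params(10, seed = 13)) {
    a1 <- exposure_metrics(
      steady_state_profile(scale_parameters(p, 20), dosing_regimen(10)),
      24)$auc_0_24
    a2 <- exposure_metrics(
      steady_state_profile(scale_parameters(p, 60), dosing_regimen(10)),
      24)$auc_0_24
    expect_equal(a1 / a2, (60 / 20)^0.75, tolerance = 0.005)
  }
})

test_that("survey resampling matches the printed weight quantiles", {
  s <- resample_survey(1e5, seed = 21)
  expect_lt(abs(median(s$weight_kg) / 42 - 1), 0.02)
  q <- quantile(s$weight_kg, c(0.25, 0.75))
  # quantile-matched lognormal: symmetric log-scale fit to [27, 44]
  expect_lt(abs(log(unname(q[2] / q[1])) - log(44 / 27)), 0.05)
  expect_identical(resample_survey(5, seed = 3), resample_survey(5, seed = 3))
  one <- resample_survey(1, seed = 8)
  expect_gt(one$weight_kg, 5)
  expect_lt(one$weight_kg, 120)
})

test_that("cohorts are reproducible and export to CSV", {
  fx <- ref_fixture()
  ch <- make_cohort(25, fx$params, fx$omega, fx$allometry, seed = 31)
  ch2 <- make_cohort(25, fx$params, fx$omega, fx$allometry, seed = 31)
  expect_identical(ch, ch2)
  expect_true(all(ch$weight_kg >= 15 & ch$weight_kg <= 90))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(ch, f)
  expect_identical(names(read.csv(f)),
                   c("id", "weight_kg", "cl_f", "vc_f", "vp_f", "q_f",
                     "ka", "d1", "alag1"))
})
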