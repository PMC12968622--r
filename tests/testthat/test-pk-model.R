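test_that("no drug appears before the absorption lag", {
  p <- pk_params(10, 50, 30, 6, 2, 1.5, alag1 = 0.5)
  pr <- predict_concentration(p, dosing_regimen(25), c(0, 0.1, 0.25, 0.49))
  expect_equal(pr$conc, rep(0, 4))
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(pk_params(-1, 50, 30, 6, 2), "strictly positive")
  expect_error(pk_params(10, 50, 30, 6, 2, d1 = -0.1), "non-negative")
  expect_error(pk_params(Inf, 50, 30, 6, 2), "non-finite")
  p <- pk_params(10, 50, 30, 6, 2)
  expect_error(predict_concentration(p, dosing_regimen(25), c(2, 1)),
               "sorted")
})

test_that("total AUC equals dose over clearance (analytic identity)", {
  p <- pk_params(10.083, 45, 30, 6, 2, 1.5, 0.3)
  pr <- predict_concentration(p, dosing_regimen(25), seq(0, 400, 0.05))
  auc <- sum(diff(pr$times) * (pr$conc[-1] + pr$conc[-length(pr$conc)])) / 2
  expect_equal(auc, dose_mg_to_nmol(25) / 10.083, tolerance = 0.005)
})

test_that("the model is exactly linear in dose", {
  p <- pk_params(10, 50, 30, 6, 2, 1.5, 0.3)
  tt <- seq(0, 48, 0.5)
  c25 <- predict_concentration(p, dosing_regimen(25, n_doses = 2L), tt)$conc
  c50 <- predict_concentration(p, dosing_regimen(50, n_doses = 2L), tt)$conc
  expect_equal(c50, 2 * c25, tolerance = 1e-10)
})

test_that("closed-form solver agrees with a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  tt <- seq(0.25, 48, 0.25)
  for (p in random_params(20)) {
    prod <- predict_concentration(p, dosing_regimen(25), tt)$conc
    orac <- ode_oracle(p, dose_mg_to_nmol(25), tt)[, 3] / p[["vc_f"]]
    scale <- max(orac)
    expect_lt(max(abs(prod - orac) / (abs(orac) + 1e-4 * scale)), 1e-3)
  }
})

test_that("amounts balance: depot + central + peripheral + eliminated = dose", {
  skip_if_not_installed("deSolve")
  for (p in random_params(5, seed = 7)) {
    dose <- dose_mg_to_nmol(25)
    tt <- c(0.5, 1, 2, 6, 12, 24, 48)
    sol <- ode_oracle(p, dose, tt)
    central_prod <- predict_concentration(p, dosing_regimen(25), tt)$conc *
      p[["vc_f"]]
    input_so_far <- dose / p[["d1"]] *
      pmin(pmax(tt - p[["alag1"]], 0), p[["d1"]])
    remaining <- dose - input_so_far
    total <- remaining + sol[, 2] + central_prod + sol[, 4] + sol[, 5]
    expect_lt(max(abs(total - dose)) / dose, 1e-3)
  }
})

test_that("one-compartment accumulation matches the geometric-series factor", {
  # half-life 8 h once daily: accumulation 1 / (1 - 2^(-24/8))
  vc <- 57.7
  cl <- log(2) / 8 * vc
  p <- pk_params(cl, vc, 1e-4, 1e-9, ka = 2, d1 = 0.5, alag1 = 0)
  single <- predict_concentration(p, dosing_regimen(25), 24)$conc
  ss <- steady_state_profile(p, dosing_regimen(25))
  trough_ss <- ss$conc[length(ss$conc)]
  expect_equal(trough_ss / single, 1 / (1 - 2^(-3)), tolerance = 1e-3)
})

test_that("steady state: trough at 24 h equals trough at 0 h", {
  for (p in random_params(5, seed = 3)) {
    ss <- steady_state_profile(p, dosing_regimen(10))
    expect_equal(ss$conc[length(ss$conc)], ss$conc[1L], tolerance = 1e-6)
  }
})

test_that("steady-state profile of a slowly accumulating drug converges", {
  p <- pk_params(10, 50, 30, 6, 2, 1.5, 0.3)
  ss <- steady_state_profile(p, dosing_regimen(25))
  one <- predict_concentration(p, dosing_regimen(25, n_doses = 1L),
                               ss$times)
  # accumulation: steady state dominates the single dose everywhere past tmax
  expect_true(all(ss$conc >= one$conc - 1e-9))
})

test_that("exposure metrics: rectangle profile and interval checks", {
  prof <- empbridge:::new_conc_profile(seq(0, 24, 0.05), rep(100, 481))
  m <- exposure_metrics(prof, tau = 24)
  expect_equal(m$auc_0_24, 2400)
  expect_equal(m$cmax, 100)
  expect_equal(m$css, 100)
  expect_equal(m$css, m$auc_0_24 / 24)
  short <- empbridge:::new_conc_profile(seq(0, 12, 0.05), rep(1, 241))
  expect_error(exposure_metrics(short, 24), "span")
  coarse <- empbridge:::new_conc_profile(seq(0, 24, 0.5), rep(1, 49))
  expect_error(exposure_metrics(coarse, 24), "step")
})

test_that("steady-state AUC identity holds across random parameter sets", {
  set.seed(9)
  ps <- random_params(100, seed = 9)
  P <- do.call(rbind, lapply(ps, empbridge:::as_par_vec))
  M <- empbridge:::ss_metrics_cpp(P, dose_mg_to_nmol(10), 24, 0.05)
  rel <- abs(M[, 1] - M[, 4]) / M[, 4]
  expect_lt(max(rel), 0.005)
})

test_that("fixture exposure profile has the expected shape at 70 kg / 25 mg", {
  fx <- ref_fixture()
  m <- exposure_metrics(steady_state_profile(fx$params, dosing_regimen(25)),
                        24)
  expect_gte(m$tmax, 1.0)
  expect_lte(m$tmax, 2.0)
  expect_gte(m$cmax, m$css)
})

test_that("terminal half-life matches micro-constant limits", {
  # one-compartment limit: q -> 0
  p1 <- pk_params(5, 57.7, 30, 1e-12, 2, 1, 0.2)
  expect_equal(terminal_half_life(p1), log(2) / (5 / 57.7),
               tolerance = 1e-9)
  # degenerate peripheral volume with q fixed
  p2 <- pk_params(5, 57.7, 1e-12, 6, 2, 1, 0.2)
  expect_equal(terminal_half_life(p2), log(2) / (5 / 57.7),
               tolerance = 0.01)
  expect_gte(terminal_half_life(ref_fixture()$params), 7)
  expect_lte(terminal_half_life(ref_fixture()$params), 12)
})

test_that("profiles export as two-column CSV", {
  p <- pk_params(10, 50, 30, 6, 2, 1.5, 0.3)
  pr <- predict_concentration(p, dosing_regimen(25), seq(0, 24, 1))
  f <- tempfile(fileext = ".csv")
  write_profile_csv(pr, f)
  back <- read.csv(f)
  expect_identical(names(back), c("time_h", "conc_nmol_per_L"))
  expect_equal(back$conc_nmol_per_L, pr$conc, tolerance = 1e-6)
})
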