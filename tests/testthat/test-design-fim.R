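test_that("linearised moments reduce correctly in degenerate cases", {
  fx <- ref_fixture()
  m0 <- fim_model(fx)
  m0$omega <- omega_spec()
  m0$sigma <- residual_spec(0)
  lm0 <- linearised_moments(m0, c(1, 2, 8))
  expect_equal(unname(lm0$cov), matrix(0, 3, 3))
  # duplicated time point with no residual error: rank deficiency flagged
  mdup <- fim_model(fx)
  mdup$sigma <- residual_spec(0)
  lmd <- linearised_moments(mdup, c(1, 1, 2, 4, 6, 8, 12, 24))
  expect_identical(lmd$flag, "rank-deficient")
  expect_error(linearised_moments(fim_model(fx), numeric(0)), "non-empty")
})

test_that("single-observation FO variance matches a Monte-Carlo oracle", {
  fx <- ref_fixture()
  m <- fim_model(fx)
  m$omega <- omega_spec(cl_f = 0.04)
  lm1 <- linearised_moments(m, 6)
  set.seed(8)
  eta <- rnorm(1e5, 0, 0.2)
  pv <- empbridge:::as_par_vec(scale_parameters(fx$params, 38.1))
  dh <- empbridge:::dose_history(6, 10)
  f_eta <- vapply(eta, function(e) {
    pvi <- pv
    pvi[1] <- pvi[1] * exp(e)
    empbridge:::conc_profile_cpp(6, dh$times, dh$amts, pvi)
  }, 0)
  mc_var <- var(f_eta) + fx$sigma$sigma_prop^2 * mean(f_eta^2)
  expect_equal(unname(lm1$cov[1, 1]), mc_var, tolerance = 0.05)
})

test_that("the FIM is additive over subjects and monotone in sampling times", {
  fx <- ref_fixture()
  model <- fim_model(fx)
  s3 <- load_scenario("3")
  f1 <- compute_fim(s3, model)
  doubled <- design_scenario("3x2", rep(s3$groups, 2))
  f2 <- compute_fim(doubled, model)
  expect_equal(f2$fim, 2 * f1$fim, tolerance = 1e-9)
  expect_equal(f2$log_det, f1$log_det + f1$p * log(2), tolerance = 1e-6)
  # subject-order invariance: group split does not change the FIM
  split <- design_scenario("3split",
                           list(list(n = 5, times = s3$groups[[1]]$times),
                                list(n = 7, times = s3$groups[[1]]$times)))
  expect_equal(compute_fim(split, model)$fim, f1$fim, tolerance = 1e-9)
  # adding a sampling time never loses information
  richer <- design_scenario("3plus",
                            list(list(n = 12,
                                      times = c(s3$groups[[1]]$times, 12))))
  expect_gte(compute_fim(richer, model)$log_det, f1$log_det)
})

test_that("%RSE is invariant to rescaling the parameter units", {
  fx <- ref_fixture()
  model <- fim_model(fx)
  f70 <- compute_fim(load_scenario("3"), model)
  # reparameterise the same model at a 35 kg reference: every theta is
  # rescaled but all predictions are unchanged
  model35 <- model
  model35$params <- scale_parameters(fx$params, 35, fx$allometry)
  model35$allometry <- allometric_spec(ref_weight = 35)
  f35 <- compute_fim(load_scenario("3"), model35)
  expect_equal(f35$rse, f70$rse, tolerance = 1e-6)
  expect_equal(f35$log_det, f70$log_det, tolerance = 1e-6)
})

test_that("design comparison ranks by D-efficiency with self-efficiency 1", {
  fx <- ref_fixture()
  model <- fim_model(fx)
  s3 <- load_scenario("3")
  cmp_self <- compare_designs(list(s3, s3), model)
  expect_equal(cmp_self$efficiency, c(1, 1), tolerance = 1e-9)
  cmp <- compare_designs(list(s3, load_scenario("2"), load_scenario("6")),
                         model)
  expect_gt(cmp$efficiency[cmp$design_id == "2"], 1)
  expect_identical(cmp$design_id[1L], "2") # rich design ranks first
})

test_that("optimised schedules satisfy the clinical constraints", {
  fx <- ref_fixture()
  model <- fim_model(fx)
  w <- sampling_windows(granularity = 0.5)
  opt <- optimise_schedule(w, n_groups = 2L, n_subjects = 12L,
                           model = model, n_starts = 1L, seed = 2,
                           max_sweeps = 1L)
  for (g in opt$design$groups) {
    v1 <- g$times[g$times <= 8]
    expect_lte(length(v1), w$visit1_cap)
    expect_true(all(v1 >= 0 & v1 <= 8))
    v2 <- g$times[g$times > 8 & g$times < 400]
    expect_true(all(v2 >= 165 & v2 <= 171))
    v3 <- g$times[g$times >= 400]
    expect_true(all(v3 >= 501 & v3 <= 507))
    # rounded to the grid
    expect_equal(g$times, round(g$times / 0.5) * 0.5, tolerance = 1e-9)
  }
  expect_gte(opt$improvement_over_empirical, 0)
  expect_error(optimise_schedule(w, n_groups = 4L, n_subjects = 2L,
                                 model = model),
               "infeasible")
})

test_that("multistart optimisation is stable across seeds", {
  fx <- ref_fixture()
  model <- fim_model(fx)
  w <- sampling_windows(visit1_cap = 3L, granularity = 1)
  best <- vapply(1:4, function(s) {
    optimise_schedule(w, n_groups = 1L, n_subjects = 12L, model = model,
                      n_starts = 2L, seed = s, max_sweeps = 2L)$log_det
  }, 0)
  expect_lt(diff(range(best)) / abs(mean(best)), 0.01)
})
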