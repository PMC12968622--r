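test_that("trial simulation is deterministic and structurally correct", {
  fx <- ref_fixture()
  d1 <- simulate_trial(load_scenario("6"), fx, cohort_seed = 3,
                       residual_seed = 4)
  d2 <- simulate_trial(load_scenario("6"), fx, cohort_seed = 3,
                       residual_seed = 4)
  expect_identical(d1, d2)
  obs <- d1[d1$EVID == 0, ]
  # 12 subjects; groups 2 and 4 carry the week-3 sample
  expect_identical(as.integer(table(obs$ID)),
                   as.integer(c(7, 7, 7, 8, 8, 8, 7, 7, 7, 8, 8, 8)))
  expect_identical(sum(obs$TIME > 400), 6L) # half the subjects
  expect_true(all(obs$DV >= 0))
  # visit-1 samples: 6 per subject within the 8 h stay
  expect_true(all(table(obs$ID[obs$TIME <= 8]) == 6))
})

test_that("without any variability, observations equal typical predictions", {
  fx <- ref_fixture()
  fx$omega <- omega_spec()
  fx$sigma <- residual_spec(0)
  d <- simulate_trial(load_scenario("3"), fx, cohort_seed = 5,
                      residual_seed = 6)
  obs <- d[d$EVID == 0 & d$ID == 1, ]
  w <- obs$WT[1]
  p <- scale_parameters(fx$params, w, fx$allometry)
  dh <- empbridge:::dose_history(obs$TIME, 10)
  f <- empbridge:::conc_profile_cpp(obs$TIME, dh$times, dh$amts,
                                    empbridge:::as_par_vec(p))
  expect_equal(obs$DV, f, tolerance = 1e-12)
})

test_that("NONMEM-style CSV round trip is bit-exact", {
  fx <- ref_fixture()
  d <- simulate_trial(load_scenario("4"), fx, cohort_seed = 9,
                      residual_seed = 10)
  f <- tempfile(fileext = ".csv")
  write_nonmem_csv(d, f)
  back <- read_nonmem_csv(f)
  for (cn in c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "WT")) {
    expect_identical(back[[cn]], unclass(d)[[cn]], label = cn)
  }
  # dose rows carry AMT in mg and MDV 1
  expect_true(all(back$AMT[back$EVID == 1] == 10))
  expect_true(all(back$MDV[back$EVID == 1] == 1L))
})

test_that("datasets without a leading dose record are rejected", {
  bad <- data.frame(ID = 1L, TIME = c(1, 24), EVID = c(0L, 1L),
                    AMT = c(NA, 10), DV = c(5, NA), MDV = c(0L, 1L),
                    WT = 40)
  expect_error(empbridge:::split_subjects(bad), "dose record")
})

test_that("noise-free rich data identifies all fixed effects within 1%", {
  fx <- ref_fixture()
  truth0 <- fx
  truth0$omega <- omega_spec()
  truth0$sigma <- residual_spec(1e-4)
  sc <- design_scenario("rich8",
                        list(list(n = 8,
                                  times = load_scenario("1")$groups[[1]]$times)))
  d <- simulate_trial(sc, truth0, cohort_seed = 11, residual_seed = 12)
  ft <- fit_model(d, init = list(params = fx$params, omega = omega_spec(),
                                 sigma = residual_spec(1e-3)),
                  estimate = list(theta = empbridge:::PAR_NAMES,
                                  omega = character(0), sigma = TRUE))
  ratios <- coef(ft) / unclass(fx$params)[empbridge:::PAR_NAMES]
  expect_true(all(abs(ratios - 1) < 0.01))
})

test_that("a dominant informative prior pins the estimates to its centre", {
  fx <- ref_fixture()
  centre <- pk_params(12, 55, 40, 9, 2.5, 0.9, 0.35)
  pr <- prior_spec("informative", mean = centre, sd = 1e-3)
  d <- simulate_trial(load_scenario("6"), fx, cohort_seed = 13,
                      residual_seed = 14)
  ft <- fit_model(d, init = list(params = centre, omega = fx$omega,
                                 sigma = fx$sigma), prior = pr)
  expect_true(all(abs(coef(ft) / unclass(centre)[empbridge:::PAR_NAMES] - 1)
                  < 0.01))
})

test_that("a vague informative prior converges to the non-informative fit", {
  fx <- ref_fixture()
  d <- simulate_trial(load_scenario("6"), fx, cohort_seed = 15,
                      residual_seed = 16)
  init <- list(params = fx$params, omega = fx$omega, sigma = fx$sigma)
  f_non <- fit_model(d, init, prior = prior_spec())
  f_vag <- fit_model(d, init,
                     prior = prior_spec("informative", mean = fx$params,
                                        sd = 1e6))
  expect_lt(abs(f_non$ofv - f_vag$ofv), 0.1)
})

test_that("Laplace marginal likelihood matches Gauss-Hermite quadrature", {
  skip_if_not_installed("deSolve") # suite parity; oracle itself is pure R
  p1 <- pk_params(10, 50, 1e-6, 1e-9, 2, 1.0, 0.3)
  om <- omega_spec(cl_f = 0.05)
  sg <- 0.15
  tt <- c(1, 2, 6, 12)
  dh <- list(times = 0, amts = dose_mg_to_nmol(10))
  set.seed(77)
  for (rep in 1:4) { # 2 subjects x 2 data sets
    eta_true <- rnorm(1, 0, sqrt(0.05))
    pv <- empbridge:::as_par_vec(p1)
    pv[1] <- pv[1] * exp(eta_true)
    f <- empbridge:::conc_profile_cpp(tt, dh$times, dh$amts, pv)
    y <- f * (1 + rnorm(length(f), 0, sg))
    lap <- empbridge:::subject_ofv_cpp(y, tt, dh$times, dh$amts,
                                       empbridge:::as_par_vec(p1),
                                       unclass(om), sg^2, numeric(6))
    gh <- gh_ofv_cl(y, tt, dh$times, dh$amts, p1, 0.05, sg)
    expect_lt(abs(lap$ofv - gh), 0.5)
  }
})

test_that("SSE runs are bitwise reproducible under the base seed", {
  fx <- ref_fixture()
  r1 <- run_sse(load_scenario("6.a"), fx, n_replicates = 2, base_seed = 19)
  r2 <- run_sse(load_scenario("6.a"), fx, n_replicates = 2, base_seed = 19)
  expect_identical(r1$ratios, r2$ratios)
  expect_identical(r1$summary, r2$summary)
})

test_that("summarising SSE results ranks deterministically", {
  fx <- ref_fixture()
  r1 <- run_sse(load_scenario("6.a"), fx, n_replicates = 2, base_seed = 19)
  tab1 <- summarise_sse(list(r1))
  expect_identical(nrow(tab1), nrow(r1$summary))
  expect_equal(tab1$median, r1$summary$median)
  # identical results twice: deterministic tie-break by scenario id
  r1b <- r1
  r1b$scenario_id <- "zz"
  tab2 <- summarise_sse(list(r1b, r1))
  expect_identical(unique(tab2$rank[tab2$scenario == "6.a"]), 1L)
  expect_identical(unique(tab2$rank[tab2$scenario == "zz"]), 2L)
})
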