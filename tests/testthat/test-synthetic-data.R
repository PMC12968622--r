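test_that("the calibrated fixture satisfies its exposure anchors", {
  fx <- ref_fixture()
  expect_equal(fx$params[["cl_f"]], 10.08, tolerance = 0.001)
  m <- exposure_metrics(steady_state_profile(fx$params, dosing_regimen(25)),
                        24)
  expect_equal(m$auc_0_24, 5499, tolerance = 0.005)
  expect_gte(m$cmax, 641.3)
  expect_lte(m$cmax, 898.3)
  expect_gte(m$tmax, 1.2)
  expect_lte(m$tmax, 1.8)
  th <- terminal_half_life(fx$params)
  expect_gte(th, 7)
  expect_lte(th, 12)
  # clearance IIV derived from the AUC interquartile anchor
  expect_equal(unname(unclass(fx$omega)["cl_f"]),
               (log(6398 / 4696) / (2 * qnorm(0.75)))^2, tolerance = 1e-9)
})

test_that("simulated AUC interquartile spread matches the anchor width", {
  fx <- ref_fixture()
  M <- empbridge:::ss_population_metrics(fx, 70, 25, 20000)
  q <- quantile(M[, "auc"], c(0.25, 0.75))
  width <- unname(q[2] - q[1])
  expect_lt(abs(width - (6398 - 4696)) / (6398 - 4696), 0.2)
})

test_that("fixture calibration is idempotent and serialises losslessly", {
  a <- make_reference_parameters()
  b <- make_reference_parameters()
  expect_identical(unclass(a$params), unclass(b$params))
  f <- tempfile(fileext = ".json")
  write_fixture_json(a, f)
  back <- read_fixture_json(f)
  expect_equal(unclass(back$params), unclass(a$params), tolerance = 1e-12)
  expect_equal(unclass(back$omega), unclass(a$omega), tolerance = 1e-12)
  expect_identical(back$schema_version, a$schema_version)
})

test_that("infeasible anchors are rejected with the violated anchor named", {
  bad <- default_anchors()
  # Cmax below Css = AUC/24 is impossible for any parameter set
  bad$cmax <- 100
  bad$cmax_range <- c(90, 110)
  expect_error(make_reference_parameters(bad), "cmax")
})

test_that("the scenario library stores the protocol table verbatim", {
  s4 <- load_scenario(4)
  expect_identical(length(s4$groups), 1L)
  expect_equal(s4$groups[[1]]$times, c(1.0, 2.2, 2.5, 4.4, 7.7, 8.0, 168))
  s3 <- load_scenario("3")
  expect_equal(s3$groups[[1]]$times, c(0.5, 1, 2, 4, 6, 8, 168))
  s6 <- load_scenario("6")
  expect_identical(vapply(s6$groups, `[[`, 0, "n"), rep(3, 4))
  expect_true(507 %in% s6$groups[[2]]$times)
  expect_true(507 %in% s6$groups[[4]]$times)
  expect_false(507 %in% s6$groups[[1]]$times)
  s6a <- load_scenario("6.a")
  expect_identical(s6a$n_total, 8)
  s7 <- load_scenario("7")
  expect_identical(length(s7$groups), 12L)
  expect_match(s7$description, "synthetic")
  expect_error(load_scenario("99"), "valid ids")
})

test_that("the example bundle is byte-identical across runs", {
  d1 <- file.path(tempdir(), "bundleA")
  d2 <- file.path(tempdir(), "bundleB")
  p1 <- generate_example_bundle(d1, seed = 6)
  p2 <- generate_example_bundle(d2, seed = 6)
  expect_identical(basename(p1), basename(p2))
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]),
                     label = basename(p1[i]))
  }
  ch <- read.csv(file.path(d1, "cohort.csv"))
  expect_true(all(ch$weight_kg >= 15 & ch$weight_kg <= 90))
  tr <- read_nonmem_csv(file.path(d1, "trial_scenario6.csv"))
  expect_identical(length(unique(tr$ID)), 12L)
  unlink(c(d1, d2), recursive = TRUE)
})
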