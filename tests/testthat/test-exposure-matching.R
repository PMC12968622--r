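no_iiv_fixture <- function() {
  fx <- ref_fixture()
  fx$omega <- omega_spec()
  fx
}

test_that("without variability the ratios collapse to the closed form", {
  fx0 <- no_iiv_fixture()
  rs <- ratio_distribution(15, 10, 50, 25, fx0, n_pairs = 50, seed = 1)
  closed <- (10 / 25) * (50 / 15)^0.75
  auc_row <- rs[rs$metric == "AUC", ]
  expect_equal(auc_row$median, closed, tolerance = 1e-9)
  # all quantiles collapse
  expect_equal(auc_row$q05, auc_row$q95, tolerance = 1e-12)
  # identical subjects: every ratio exactly 1
  rs1 <- ratio_distribution(50, 25, 50, 25, fx0, n_pairs = 20, seed = 2)
  expect_equal(rs1$median, rep(1, 3), tolerance = 1e-12)
  # Css ratio equals AUC ratio by construction
  expect_equal(rs[rs$metric == "Css", ]$median, auc_row$median)
})

test_that("median AUC ratio decreases strictly with child weight", {
  tab <- evaluate_weight_bands(c(10, 15, 20, 30, 40, 50, 60, 70, 80, 90),
                               doses = 10, fixture = ref_fixture(),
                               n = 2000, seed = 4)
  auc_saf <- tab[tab$metric == "AUC" & tab$reference == "safety", ]
  expect_true(all(diff(auc_saf$median) < 0))
  expect_true(all(auc_saf$q05 <= auc_saf$q25 &
                    auc_saf$q25 <= auc_saf$median &
                    auc_saf$median <= auc_saf$q75 &
                    auc_saf$q75 <= auc_saf$q95))
  expect_true(is.numeric(attr(tab, "ref_q95")["auc_safety"]))
})

test_that("a 10 kg child on 10 mg exceeds the safety cap (closed form)", {
  fx0 <- no_iiv_fixture()
  tab <- evaluate_weight_bands(c(10, 15), doses = 10, fixture = fx0,
                               n = 10, seed = 1)
  r10 <- tab[tab$weight_kg == 10 & tab$metric == "AUC" &
               tab$reference == "safety", ]
  expect_equal(r10$median, 0.4 * 5^0.75, tolerance = 1e-9)
  expect_gt(r10$median, 1.30)
  expect_false(unique(tab$pass_safety[tab$weight_kg == 10]))
  expect_true(unique(tab$pass_safety[tab$weight_kg == 15]))
})

test_that("minimum admissible weight behaves at the grid edges", {
  fx0 <- no_iiv_fixture()
  # a 50 kg adult-like subject passes both criteria
  expect_equal(min_admissible_weight(50, 10, fixture = fx0, n = 10,
                                     seed = 1), 50)
  # with the safety cap disabled, the efficacy floor alone decides
  crit_nocap <- matching_criteria(safety_cap = Inf)
  expect_equal(min_admissible_weight(c(10, 15, 20), 10,
                                     criteria = crit_nocap, fixture = fx0,
                                     n = 10, seed = 1), 10)
  # no admissible weight: explicit token, not an exception
  strict <- matching_criteria(safety_cap = 1.01)
  res <- min_admissible_weight(10, 10, criteria = strict, fixture = fx0,
                               n = 10, seed = 1)
  expect_true(is.na(res))
  expect_identical(attr(res, "reason"), "no admissible weight")
  expect_error(min_admissible_weight(c(20, 10), 10), "ascending")
})

test_that("criteria validation enforces floor < 1 < cap", {
  expect_error(matching_criteria(efficacy_floor = 1.2), "0, 1")
  expect_error(matching_criteria(safety_cap = 0.9), "exceed 1")
})

test_that("weight-band tables export as tidy CSV", {
  tab <- evaluate_weight_bands(c(15, 50), doses = 10,
                               fixture = no_iiv_fixture(), n = 10,
                               seed = 1)
  f <- tempfile(fileext = ".csv")
  write_weight_bands_csv(tab, f)
  got <- read.csv(f)
  expect_true(all(c("weight_kg", "dose_mg", "metric", "median", "q25",
                    "q75", "q05", "q95", "reference", "pass_efficacy",
                    "pass_safety") %in% names(got)))
})
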