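# Dose-rationale engine: exposure-ratio distributions of virtual children
# against adult reference exposures, and the minimum-admissible-weight rule.

#' Exposure-matching criteria
#'
#' Efficacy: the child's median AUC must reach at least `efficacy_floor`
#' (default 70%) of the exposure of a normal-weight adult on the 10 mg
#' heart-failure dose. Safety: the child's median AUC and Cmax must not
#' exceed `safety_cap` (default 130%) of the exposure of an adult on the
#' maximum recommended 25 mg dose; the default safety comparator is a 50 kg
#' adult (configurable to 70 kg).
#'
#' @param efficacy_floor minimum acceptable child/adult AUC ratio (0-1)
#' @param safety_cap maximum acceptable child/adult AUC and Cmax ratio (> 1)
#' @param efficacy_ref_weight,efficacy_ref_dose efficacy reference subject
#' @param safety_ref_weight,safety_ref_dose safety reference subject
#' @return object of class `matching_criteria`
#' @export
matching_criteria <- function(efficacy_floor = 0.70, safety_cap = 1.30,
                              efficacy_ref_weight = 70,
                              efficacy_ref_dose = 10,
                              safety_ref_weight = 50,
                              safety_ref_dose = 25) {
  if (!(efficacy_floor > 0 && efficacy_floor < 1)) {
    stop("efficacy_floor must lie in (0, 1)", call. = FALSE)
  }
  if (!(safety_cap > 1)) stop("safety_cap must exceed 1", call. = FALSE)
  structure(list(efficacy_floor = efficacy_floor, safety_cap = safety_cap,
                 efficacy_ref_weight = efficacy_ref_weight,
                 efficacy_ref_dose = efficacy_ref_dose,
                 safety_ref_weight = safety_ref_weight,
                 safety_ref_dose = safety_ref_dose),
            class = "matching_criteria")
}

# internal: steady-state AUC / Cmax / Tmax for n IIV draws at a fixed weight
ss_population_metrics <- function(fixture, weight, dose_mg, n,
                                  tau = 24, dt = 0.05) {
  P <- individual_parameters(fixture$params, rep(weight, n), fixture$omega,
                             fixture$allometry)
  M <- ss_metrics_cpp(P, dose_mg_to_nmol(dose_mg), tau, dt)
  colnames(M) <- c("auc_trapz", "cmax", "tmax", "auc")
  M
}

ratio_quantiles <- function(r, metric) {
  qs <- quantile(r, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                 type = 7)
  data.frame(metric = metric, median = qs[3L], q25 = qs[2L], q75 = qs[4L],
             q05 = qs[1L], q95 = qs[5L])
}

#' Exposure-ratio distribution between a child and an adult reference
#'
#' Simulates `n_pairs` independent virtual children and adults (allometric
#' scaling to the stated weights, lognormal inter-individual variability on
#' both), computes per-pair ratios of the steady-state metrics (AUC over one
#' interval, Cmax, Css) and returns quantile summaries. Pairs are
#' independent draws rather than common-random-number pairs, so the ratio
#' spread is wider than either marginal, as for empirically sampled
#' populations.
#'
#' @param child_weight,adult_weight body weights, kg
#' @param child_dose,adult_dose once-daily doses, mg
#' @param fixture a [make_reference_parameters()] fixture (or any list with
#'   `params`, `omega`, `allometry`)
#' @param n_pairs number of child/adult pairs (>= 1000 recommended for
#'   stable summaries)
#' @param seed integer RNG seed
#' @param dt Cmax search grid step, h
#' @return data.frame of class `ratio_summary`: one row per metric with
#'   columns metric, median, q25, q75, q05, q95
#' @export
#' @examples
#' fx <- make_reference_parameters()
#' ratio_distribution(15, 10, 50, 25, fx, n_pairs = 2000, seed = 1)
ratio_distribution <- function(child_weight, child_dose, adult_weight,
                               adult_dose, fixture, n_pairs = 10000L,
                               seed = NULL, dt = 0.05) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  child <- ss_population_metrics(fixture, child_weight, child_dose, n_pairs,
                                 dt = dt)
  adult <- ss_population_metrics(fixture, adult_weight, adult_dose, n_pairs,
                                 dt = dt)
  out <- rbind(ratio_quantiles(child[, "auc"] / adult[, "auc"], "AUC"),
               ratio_quantiles(child[, "cmax"] / adult[, "cmax"], "Cmax"),
               ratio_quantiles((child[, "auc"] / 24) / (adult[, "auc"] / 24),
                               "Css"))
  class(out) <- c("ratio_summary", "data.frame")
  out
}

#' Evaluate exposure matching over a weight grid
#'
#' For each (weight, dose) cell, simulates `n` virtual children and compares
#' their steady-state exposure against the efficacy reference (adult at
#' `criteria$efficacy_ref_weight` on `criteria$efficacy_ref_dose`) and the
#' safety reference (adult on the maximum 25 mg dose). A cell passes
#' efficacy if the median AUC ratio against the efficacy reference is at or
#' above the floor, and passes safety if the median AUC *and* Cmax ratios
#' against the safety reference are at or below the cap. The 95th percentile
#' of the safety reference's own exposure is also reported (the red
#' reference line of the exposure figures).
#'
#' @param weights weight grid, kg
#' @param doses dose levels, mg (default the two tablet strengths)
#' @param criteria a [matching_criteria()]
#' @param fixture a [make_reference_parameters()] fixture
#' @param n virtual subjects per cell
#' @param seed integer RNG seed
#' @param dt Cmax grid step, h
#' @return data.frame of class `weight_band_table`: one row per
#'   (weight, dose, metric, reference) with quantile columns, pass flags
#'   and the reference 95th percentiles as attributes `ref_q95`
#' @export
evaluate_weight_bands <- function(weights, doses = c(10, 25),
                                  criteria = matching_criteria(),
                                  fixture = make_reference_parameters(),
                                  n = 10000L, seed = NULL, dt = 0.05) {
  if (length(weights) < 1) stop("weight grid must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eff_ref <- ss_population_metrics(fixture, criteria$efficacy_ref_weight,
                                   criteria$efficacy_ref_dose, n, dt = dt)
  saf_ref <- ss_population_metrics(fixture, criteria$safety_ref_weight,
                                   criteria$safety_ref_dose, n, dt = dt)
  rows <- list()
  for (dose in doses) {
    for (w in weights) {
      child <- ss_population_metrics(fixture, w, dose, n, dt = dt)
      auc_eff <- child[, "auc"] / eff_ref[, "auc"]
      auc_saf <- child[, "auc"] / saf_ref[, "auc"]
      cmax_saf <- child[, "cmax"] / saf_ref[, "cmax"]
      pass_eff <- median(auc_eff) >= criteria$efficacy_floor
      pass_saf <- median(auc_saf) <= criteria$safety_cap &&
        median(cmax_saf) <= criteria$safety_cap
      blk <- rbind(
        cbind(ratio_quantiles(auc_eff, "AUC"), reference = "efficacy"),
        cbind(ratio_quantiles(auc_saf, "AUC"), reference = "safety"),
        cbind(ratio_quantiles(cmax_saf, "Cmax"), reference = "safety"))
      blk <- data.frame(weight_kg = w, dose_mg = dose, blk,
                        pass_efficacy = pass_eff, pass_safety = pass_saf)
      rows[[length(rows) + 1L]] <- blk
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ref_q95") <- c(
    auc_safety = unname(quantile(saf_ref[, "auc"], 0.95)),
    cmax_safety = unname(quantile(saf_ref[, "cmax"], 0.95)))
  class(out) <- c("weight_band_table", "data.frame")
  out
}

#' Minimum admissible body weight for a fixed tablet strength
#'
#' The smallest weight on the (ascending) grid whose simulated exposure
#' passes both the efficacy floor and the safety cap of the matching
#' criteria at the given dose. If no grid weight passes, `NA` is returned
#' with attribute `reason = "no admissible weight"` rather than an error.
#'
#' @inheritParams evaluate_weight_bands
#' @param grid ascending weight grid, kg
#' @param dose dose, mg
#' @return admissible weight (kg), or `NA`
#' @export
min_admissible_weight <- function(grid, dose = 10,
                                  criteria = matching_criteria(),
                                  fixture = make_reference_parameters(),
                                  n = 10000L, seed = NULL, dt = 0.05) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending", call. = FALSE)
  tab <- evaluate_weight_bands(grid, doses = dose, criteria = criteria,
                               fixture = fixture, n = n, seed = seed,
                               dt = dt)
  per_w <- unique(tab[, c("weight_kg", "pass_efficacy", "pass_safety")])
  ok <- per_w$weight_kg[per_w$pass_efficacy & per_w$pass_safety]
  if (!length(ok)) {
    return(structure(NA_real_, reason = "no admissible weight"))
  }
  min(ok)
}

#' Tidy export of a weight-band table
#'
#' @param table a `weight_band_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_weight_bands_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
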