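# Pipeline driver: validated run configuration, staged execution in the
# method's order (scaling -> exposure extrapolation -> design optimisation
# -> simulation-re-estimation), CSV/JSON reports and a reproducibility
# manifest.

config_defaults <- function() {
  list(
    stages = c("exposure", "weight_bands"),
    out_dir = "empbridge-run",
    seed = 1L,
    n_pairs = 10000L,
    n_per_band = 10000L,
    weight_grid = c(10, 15, 20, 30, 40, 50, 60, 70, 80, 90),
    doses = c(10, 25),
    efficacy_floor = 0.70,
    safety_cap = 1.30,
    safety_ref_weight = 50,
    child_weight = 15,
    allometric_exp_flow = 0.75,
    allometric_exp_volume = 1.0,
    design_groups = 4L,
    design_subjects = 12L,
    design_starts = 1L,
    sse_scenarios = c("3", "6"),
    sse_replicates = 100L,
    sse_prior = "noninformative",
    sse_dose_mg = 10
  )
}

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected before any computation. Every randomised stage
#' derives its seed from `seed` and the manifest records it.
#'
#' @param ... configuration overrides; see Details
#' @details Recognised keys and defaults: stages (exposure, weight_bands;
#'   also design, sse), out_dir, seed, n_pairs, n_per_band, weight_grid,
#'   doses, efficacy_floor, safety_cap, safety_ref_weight, child_weight,
#'   allometric_exp_flow, allometric_exp_volume, design_groups,
#'   design_subjects, design_starts, sse_scenarios, sse_replicates,
#'   sse_prior, sse_dose_mg.
#' @return object of class `run_config` (named list)
#' @export
run_config <- function(...) {
  overrides <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, overrides)
  valid_stages <- c("exposure", "weight_bands", "design", "sse")
  if (!length(cfg$stages) || !all(cfg$stages %in% valid_stages)) {
    stop("stages must be a subset of: ",
         paste(valid_stages, collapse = ", "), call. = FALSE)
  }
  if ("sse" %in% cfg$stages) {
    known <- c(as.character(1:7), paste0("6.", letters[1:5]))
    bad <- setdiff(as.character(cfg$sse_scenarios), known)
    if (length(bad)) {
      stop("unknown scenario id(s) in sse_scenarios: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' The file holds the same keys accepted by [run_config()]; unknown keys
#' are rejected before any computation.
#'
#' @param path JSON configuration file
#' @return a validated [run_config()]
#' @export
run_config_file <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, as.list(obj))
}

config_hash <- function(cfg) {
  canon <- jsonlite::toJSON(unclass(cfg)[order(names(cfg))],
                            auto_unbox = TRUE, digits = NA)
  digest_text(as.character(canon))
}

#' Execute the bridging pipeline
#'
#' Runs the requested stages in the method's order and writes tidy CSV
#' reports plus a JSON manifest (config hash, per-stage seeds, file list)
#' into `config$out_dir`. Identical configurations produce identical
#' manifests apart from the timestamp.
#'
#' @param config a [run_config()]
#' @return the manifest (list), invisibly; files on disk as a side effect
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_reference_parameters()
  fx$allometry <- allometric_spec(exp_flow = config$allometric_exp_flow,
                                  exp_volume = config$allometric_exp_volume)
  criteria <- matching_criteria(efficacy_floor = config$efficacy_floor,
                                safety_cap = config$safety_cap,
                                safety_ref_weight = config$safety_ref_weight)
  stage_order <- c("exposure", "weight_bands", "design", "sse")
  stages <- stage_order[stage_order %in% config$stages]
  manifest <- list(package = "empbridge",
                   config = unclass(config),
                   config_hash = config_hash(config),
                   completed = character(0),
                   outputs = character(0),
                   seeds = list(),
                   generated_at = format(Sys.time(), tz = "UTC"))
  note <- function(stage, files, seed) {
    manifest$completed <<- c(manifest$completed, stage)
    manifest$outputs <<- c(manifest$outputs, files)
    manifest$seeds[[stage]] <<- seed
    message(sprintf("[empbridge] stage=%s files=%d seed=%d", stage,
                    length(files), seed))
  }

  for (stage in stages) {
    ok <- tryCatch({
      if (stage == "exposure") {
        seed <- config$seed + 11L
        rs50 <- ratio_distribution(config$child_weight, 10,
                                   config$safety_ref_weight, 25, fx,
                                   n_pairs = config$n_pairs, seed = seed)
        rs70 <- ratio_distribution(config$child_weight, 10, 70, 25, fx,
                                   n_pairs = config$n_pairs,
                                   seed = seed + 1L)
        out <- rbind(cbind(comparison = sprintf("%gkg_10mg_vs_50kg_25mg",
                                                config$child_weight), rs50),
                     cbind(comparison = sprintf("%gkg_10mg_vs_70kg_25mg",
                                                config$child_weight), rs70))
        f <- file.path(config$out_dir, "exposure_ratios.csv")
        write.csv(out, f, row.names = FALSE)
        note(stage, f, seed)
      } else if (stage == "weight_bands") {
        seed <- config$seed + 23L
        tab <- evaluate_weight_bands(config$weight_grid, config$doses,
                                     criteria, fx, n = config$n_per_band,
                                     seed = seed)
        f <- file.path(config$out_dir, "weight_bands.csv")
        write_weight_bands_csv(tab, f)
        per_w <- unique(tab[tab$dose_mg == 10,
                            c("weight_kg", "pass_efficacy", "pass_safety")])
        ok_w <- per_w$weight_kg[per_w$pass_efficacy & per_w$pass_safety]
        minw <- if (length(ok_w)) min(ok_w) else NA_real_
        f2 <- file.path(config$out_dir, "min_admissible_weight.json")
        jsonlite::write_json(list(dose_mg = 10,
                                  min_admissible_weight_kg = minw),
                             f2, auto_unbox = TRUE, digits = NA)
        note(stage, c(f, f2), seed)
      } else if (stage == "design") {
        seed <- config$seed + 37L
        model <- list(params = fx$params, omega = fx$omega,
                      sigma = fx$sigma, allometry = fx$allometry)
        opt <- optimise_schedule(n_groups = config$design_groups,
                                 n_subjects = config$design_subjects,
                                 model = model,
                                 n_starts = config$design_starts,
                                 seed = seed)
        cmp <- compare_designs(list(load_scenario("3"), opt$design), model)
        f <- file.path(config$out_dir, "design_comparison.csv")
        write.csv(cmp, f, row.names = FALSE)
        rse_tab <- do.call(rbind, lapply(list(load_scenario("3"),
                                              opt$design), function(d) {
          fim <- compute_fim(d, model)
          data.frame(design_id = d$id, parameter = names(fim$rse),
                     rse_pct = unname(fim$rse), log_det = fim$log_det)
        }))
        f3 <- file.path(config$out_dir, "design_rse.csv")
        write.csv(rse_tab, f3, row.names = FALSE)
        f2 <- file.path(config$out_dir, "optimised_design.json")
        jsonlite::write_json(
          list(id = opt$design$id, log_det = opt$log_det,
               improvement_over_empirical = opt$improvement_over_empirical,
               groups = lapply(opt$design$groups, function(g)
                 list(n = g$n, times = g$times))),
          f2, auto_unbox = TRUE, digits = NA)
        note(stage, c(f, f2, f3), seed)
      } else if (stage == "sse") {
        seed <- config$seed + 53L
        prior <- if (config$sse_prior == "informative") {
          prior_spec("informative", mean = fx$params, sd = 0.5)
        } else prior_spec()
        res <- lapply(as.character(config$sse_scenarios), function(sc) {
          run_sse(load_scenario(sc), fx,
                  n_replicates = config$sse_replicates, prior = prior,
                  base_seed = seed + as.integer(factor(sc,
                    levels = as.character(config$sse_scenarios))),
                  dose_mg = config$sse_dose_mg)
        })
        tab <- summarise_sse(res)
        f <- file.path(config$out_dir, "sse_summary.csv")
        write.csv(as.data.frame(tab), f, row.names = FALSE)
        note(stage, f, seed)
      }
      TRUE
    }, error = function(e) {
      message(sprintf("[empbridge] stage=%s FAILED: %s", stage,
                      conditionMessage(e)))
      FALSE
    })
    if (!ok) break
  }
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
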