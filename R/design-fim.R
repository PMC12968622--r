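# Expected Fisher information under the first-order (FO) approximation of
# the nonlinear mixed-effects model, D-optimality, and constrained
# sampling-time optimisation.
#
# Per subject with design times t: the FO moments are
#   mean  f = model prediction at eta = 0,
#   cov   V = G Omega G' + sigma^2 diag(f^2),
# with G the sensitivity of predictions to the log-scale random effects.
# The FIM is block-diagonal between the fixed effects (computed on the log
# scale, which makes %RSE and the D-criterion invariant to parameter
# units) and the variance parameters (omega^2, sigma^2).

#' Clinical sampling windows and caps
#'
#' Visit 1 is the first-dose day (stay capped at 8 h, at most 6 samples);
#' visit 2 is one week later with the sample falling 21-27 h after the
#' preceding (144 h) dose; visit 3 is the week-3 opportunistic sample.
#' `granularity` is the rounding grid for proposed times (5-15 min in
#' practice; default 6 min).
#'
#' @param visit1 visit-1 window, h
#' @param visit1_cap maximum samples at visit 1
#' @param visit2 visit-2 window, h after first dose
#' @param visit3 visit-3 window, h after first dose
#' @param total_range allowed per-subject total samples
#' @param granularity time rounding step, h
#' @return object of class `sampling_windows`
#' @export
sampling_windows <- function(visit1 = c(0, 8), visit1_cap = 6L,
                             visit2 = c(165, 171), visit3 = c(501, 507),
                             total_range = c(7L, 8L), granularity = 0.1) {
  stopifnot(visit1[1L] < visit1[2L], visit2[1L] < visit2[2L],
            visit3[1L] < visit3[2L], visit1_cap >= 1L)
  if (visit1[2L] >= visit2[1L] || visit2[2L] >= visit3[1L]) {
    stop("visit windows must be disjoint and ordered", call. = FALSE)
  }
  structure(list(visit1 = visit1, visit1_cap = as.integer(visit1_cap),
                 visit2 = visit2, visit3 = visit3,
                 total_range = as.integer(total_range),
                 granularity = granularity),
            class = "sampling_windows")
}

# once-daily dose history covering a set of observation times
dose_history <- function(times, dose_mg, tau = 24) {
  k <- 0:floor(max(times) / tau)
  list(times = k * tau, amts = rep(dose_mg_to_nmol(dose_mg), length(k)))
}

# default population model bundle used by the design machinery
as_fim_model <- function(model) {
  stopifnot(!is.null(model$params), !is.null(model$omega),
            !is.null(model$sigma))
  if (is.null(model$allometry)) model$allometry <- allometric_spec()
  if (is.null(model$weight)) model$weight <- 38.1
  if (is.null(model$dose_mg)) model$dose_mg <- 10
  model
}

#' First-order linearised moments of the observations
#'
#' Mean vector and covariance matrix of the observations of one subject
#' under the first-order approximation: mean is the prediction at the
#' typical individual parameters; covariance is `G Omega G' + diag(sigma^2
#' mean^2)` with `G` the finite-difference sensitivity (relative step 1e-4)
#' of the predictions to the log-scale random effects at eta = 0.
#'
#' @param model list with `params` ([pk_params()] at the reference weight),
#'   `omega` ([omega_spec()]), `sigma` ([residual_spec()]), and optionally
#'   `allometry`, `weight`, `dose_mg`
#' @param times sampling schedule, h after first dose (non-empty)
#' @return list with `mean`, `cov`, `G`, `condition` (condition number of
#'   `cov`) and `flag` ("ok", or "rank-deficient" when the covariance is
#'   numerically singular)
#' @export
linearised_moments <- function(model, times) {
  if (!length(times)) stop("schedule must be non-empty", call. = FALSE)
  model <- as_fim_model(model)
  p_ind <- scale_parameters(model$params, model$weight, model$allometry)
  pv <- as_par_vec(p_ind)
  dh <- dose_history(times, model$dose_mg)
  f <- conc_profile_cpp(times, dh$times, dh$amts, pv)
  h <- 1e-4
  G <- matrix(0, length(times), 6L,
              dimnames = list(NULL, OMEGA_NAMES))
  pidx <- match(OMEGA_NAMES, c("cl_f", "vc_f", "vp_f", "q_f", "ka", "d1",
                               "alag1"))
  for (j in seq_len(6L)) {
    up <- pv; up[pidx[j]] <- up[pidx[j]] * exp(h)
    dn <- pv; dn[pidx[j]] <- dn[pidx[j]] * exp(-h)
    G[, j] <- (conc_profile_cpp(times, dh$times, dh$amts, up) -
                 conc_profile_cpp(times, dh$times, dh$amts, dn)) / (2 * h)
  }
  om <- unclass(model$omega)
  V <- G %*% diag(om, 6L) %*% t(G) +
    diag(model$sigma$sigma_prop^2 * f^2, length(f))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  flag <- if (!is.finite(cond) || cond > 1e12) "rank-deficient" else "ok"
  list(mean = f, cov = V, G = G, condition = cond, flag = flag)
}

fim_par_names <- function(model) {
  om <- unclass(model$omega)
  c(paste0("theta.", c("cl_f", "vc_f", "vp_f", "q_f", "ka", "d1", "alag1")),
    paste0("omega2.", names(om)[om > 0]),
    if (model$sigma$sigma_prop > 0) "sigma2")
}

# per-subject FIM blocks (log-theta block and variance block) for one
# sampling schedule at one weight
subject_fim_blocks <- function(model, times) {
  lm <- linearised_moments(model, times)
  V <- lm$cov
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  p_ind <- scale_parameters(model$params, model$weight, model$allometry)
  pv <- as_par_vec(p_ind)
  dh <- dose_history(times, model$dose_mg)
  h <- 1e-4
  S <- matrix(0, length(times), 7L)
  for (j in seq_len(7L)) {
    up <- pv; up[j] <- up[j] * exp(h)
    dn <- pv; dn[j] <- dn[j] * exp(-h)
    S[, j] <- (conc_profile_cpp(times, dh$times, dh$amts, up) -
                 conc_profile_cpp(times, dh$times, dh$amts, dn)) / (2 * h)
  }
  A <- t(S) %*% Vi %*% S
  om <- unclass(model$omega)
  keep <- which(om > 0)
  dVs <- lapply(keep, function(j) tcrossprod(lm$G[, j]))
  if (model$sigma$sigma_prop > 0) {
    dVs <- c(dVs, list(diag(lm$mean^2, length(lm$mean))))
  }
  nb <- length(dVs)
  B <- matrix(0, nb, nb)
  W <- lapply(dVs, function(D) Vi %*% D)
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      B[i, j] <- B[j, i] <- 0.5 * sum(W[[i]] * t(W[[j]]))
    }
  }
  list(A = A, B = B)
}

#' Expected Fisher information of a population design
#'
#' Sums per-subject FO information blocks over all groups of the design.
#' The fixed-effect block is computed on the log-parameter scale and the
#' variance block covers the non-zero omega^2 entries plus sigma^2; the two
#' blocks are treated as block-diagonal, the standard population-design
#' practice. Predicted precision is returned as %RSE:
#' `sqrt(diag(FIM^-1)) * 100` for log-scale fixed effects (equivalently
#' SE/estimate * 100), and SE/value * 100 for the variance parameters.
#'
#' @param design a [design_scenario()]
#' @param model population model bundle, see [linearised_moments()];
#'   `model$weight` may be a vector giving one weight per subject
#' @return object of class `fim_result`: list with `fim`, `log_det`,
#'   `rse` (named, %), `p` (dimension), `degenerate` (names of
#'   unidentifiable parameters, if any) and `design_id`
#' @export
compute_fim <- function(design, model) {
  stopifnot(inherits(design, "design_scenario"))
  model <- as_fim_model(model)
  nm <- fim_par_names(model)
  p_theta <- 7L
  weights <- model$weight
  if (length(weights) != 1L && length(weights) != design$n_total) {
    stop("model$weight must be scalar or one weight per subject",
         call. = FALSE)
  }
  A <- matrix(0, p_theta, p_theta)
  nb <- length(nm) - p_theta
  B <- matrix(0, nb, nb)
  sub <- 0L
  for (g in design$groups) {
    if (length(weights) == 1L) {
      # identical subjects within the group: one block, scaled by group size
      blk <- subject_fim_blocks(model, g$times)
      sub <- sub + g$n
      if (is.null(blk)) next
      A <- A + g$n * blk$A
      B <- B + g$n * blk$B
    } else {
      for (i in seq_len(g$n)) {
        sub <- sub + 1L
        m <- model
        m$weight <- weights[sub]
        blk <- subject_fim_blocks(m, g$times)
        if (is.null(blk)) next
        A <- A + blk$A
        B <- B + blk$B
      }
    }
  }
  fim <- rbind(cbind(A, matrix(0, p_theta, nb)),
               cbind(matrix(0, nb, p_theta), B))
  dimnames(fim) <- list(nm, nm)
  ldA <- determinant(A, logarithm = TRUE)
  ldB <- if (nb > 0) determinant(B, logarithm = TRUE) else
    list(modulus = 0, sign = 1)
  degenerate <- character(0)
  rse <- setNames(rep(NA_real_, length(nm)), nm)
  if (ldA$sign > 0 && is.finite(ldA$modulus)) {
    Ai <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(Ai) && all(diag(Ai) > 0)) {
      rse[seq_len(p_theta)] <- sqrt(diag(Ai)) * 100
    }
  } else {
    degenerate <- c(degenerate, nm[seq_len(p_theta)][diag(A) < 1e-10])
  }
  if (nb > 0) {
    if (ldB$sign > 0 && is.finite(ldB$modulus)) {
      Bi <- tryCatch(solve(B), error = function(e) NULL)
      if (!is.null(Bi) && all(diag(Bi) > 0)) {
        om <- unclass(model$omega)
        vals <- c(om[om > 0],
                  if (model$sigma$sigma_prop > 0) model$sigma$sigma_prop^2)
        rse[p_theta + seq_len(nb)] <- sqrt(diag(Bi)) / vals * 100
      }
    } else {
      degenerate <- c(degenerate,
                      nm[p_theta + which(diag(B) < 1e-10)])
    }
  }
  singular <- (ldA$sign <= 0) || (nb > 0 && ldB$sign <= 0)
  log_det <- if (singular) -Inf else
    as.numeric(ldA$modulus) + as.numeric(ldB$modulus)
  structure(list(fim = fim, log_det = log_det, rse = rse,
                 p = length(nm), degenerate = degenerate,
                 design_id = design$id),
            class = "fim_result")
}

#' @export
print.fim_result <- function(x, ...) {
  cat(sprintf("FIM for design %s: p = %d, log det = %.4g\n",
              x$design_id, x$p, x$log_det))
  if (length(x$degenerate)) {
    cat("unidentifiable:", paste(x$degenerate, collapse = ", "), "\n")
  }
  cat("predicted %RSE:\n")
  print(round(x$rse, 2))
  invisible(x)
}

#' Rank designs by D-criterion efficiency
#'
#' Efficiency of design A relative to design B is
#' `exp((log det A - log det B) / p)`, the per-parameter information ratio.
#' The first design in the list is the reference.
#'
#' @param designs list of [design_scenario()] objects
#' @param model population model bundle (shared by all designs)
#' @return data.frame sorted by decreasing log det: design_id, log_det, p,
#'   efficiency (vs the first design supplied)
#' @export
compare_designs <- function(designs, model) {
  res <- lapply(designs, compute_fim, model = model)
  ld <- vapply(res, `[[`, 0, "log_det")
  p <- res[[1L]]$p
  eff <- exp((ld - ld[1L]) / p)
  out <- data.frame(design_id = vapply(res, `[[`, "", "design_id"),
                    log_det = ld, p = p, efficiency = eff)
  out[order(-out$log_det), , drop = FALSE]
}

round_to_grid <- function(x, lo, hi, g) {
  pmin(hi, pmax(lo, round(x / g) * g))
}

#' Optimise a grouped sampling schedule by D-optimality
#'
#' Maximises the log-determinant of the expected FIM over the sampling
#' times, constrained to the clinical visit windows, sample caps and the
#' rounding grid. The search is multistart (random feasible starts, plus
#' the empirical 0.5/1/2/4/6/8 h scheme as a deterministic start) followed
#' by coordinate-wise exact search on the rounded grid, which terminates at
#' a grid-local optimum. Because the empirical scheme is always one of the
#' starting points, the optimised criterion can never fall below it.
#'
#' @param windows a [sampling_windows()]
#' @param n_groups number of distinct schedules (1, 2, 4 or one per subject)
#' @param n_subjects total subjects (split as evenly as possible)
#' @param model population model bundle, see [linearised_moments()]
#' @param n_starts random multistarts in addition to the empirical start
#' @param seed integer RNG seed for the random starts
#' @param visit3_fraction fraction of groups carrying the week-3 sample
#' @param max_sweeps coordinate-descent sweeps per start
#' @return list with `design` (the best [design_scenario()]), `log_det`,
#'   `trace` (best criterion after each sweep of the winning start) and
#'   `improvement_over_empirical` (log-det difference vs the empirical
#'   one-group scheme)
#' @export
optimise_schedule <- function(windows = sampling_windows(), n_groups = 4L,
                              n_subjects = 12L,
                              model = list(params =
                                             make_reference_parameters()$params,
                                           omega =
                                             make_reference_parameters()$omega,
                                           sigma =
                                             make_reference_parameters()$sigma),
                              n_starts = 3L, seed = 1L,
                              visit3_fraction = 0.5, max_sweeps = 3L) {
  model <- as_fim_model(model)
  g <- windows$granularity
  n_groups <- as.integer(n_groups)
  if (n_subjects < n_groups) {
    stop("infeasible constraint set: fewer subjects than groups",
         call. = FALSE)
  }
  sizes <- rep(n_subjects %/% n_groups, n_groups)
  extra <- n_subjects %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  v3_groups <- if (n_groups == 1L) integer(0) else
    which(seq_len(n_groups) %% 2 == 0)
  if (visit3_fraction >= 0.999) v3_groups <- seq_len(n_groups)
  if (visit3_fraction <= 0.001) v3_groups <- integer(0)

  nv1 <- windows$visit1_cap
  make_design <- function(tm) {
    groups <- lapply(seq_len(n_groups), function(i) {
      list(n = sizes[i], times = sort(tm[[i]]))
    })
    design_scenario("optimised", groups,
                    sprintf("D-optimised %d-group schedule", n_groups))
  }
  # per-group information blocks are cached so a candidate move in one group
  # only recomputes that group's block
  group_block <- function(times) subject_fim_blocks(model, sort(times))
  ld_from_blocks <- function(blocks) {
    # a singular per-group covariance (e.g. a pre-dose sample at t = 0)
    # yields a NULL block: such a candidate design carries no criterion
    if (any(vapply(blocks, is.null, TRUE))) return(-Inf)
    A <- Reduce(`+`, Map(function(b, n) n * b$A, blocks, sizes))
    B <- Reduce(`+`, Map(function(b, n) n * b$B, blocks, sizes))
    ldA <- determinant(A, logarithm = TRUE)
    ldB <- determinant(B, logarithm = TRUE)
    if (ldA$sign <= 0 || ldB$sign <= 0) return(-Inf)
    as.numeric(ldA$modulus) + as.numeric(ldB$modulus)
  }
  objective <- function(tm) {
    ld_from_blocks(lapply(tm, group_block))
  }

  empirical_v1 <- c(0.5, 1, 2, 4, 6, 8)
  starts <- list()
  emp_tm <- lapply(seq_len(n_groups), function(i) {
    v1 <- round_to_grid(empirical_v1[seq_len(min(nv1, 6L))],
                        windows$visit1[1L], windows$visit1[2L], g)
    if (nv1 > 6L) v1 <- c(v1, round_to_grid(seq(0.5, 7.5, length.out =
                                                  nv1 - 6L),
                                            windows$visit1[1L],
                                            windows$visit1[2L], g))
    tm <- c(v1, 168)
    if (i %in% v3_groups) tm <- c(tm, 507)
    tm
  })
  starts[[1L]] <- emp_tm
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    starts[[s + 1L]] <- lapply(seq_len(n_groups), function(i) {
      v1 <- round_to_grid(runif(nv1, windows$visit1[1L],
                                windows$visit1[2L]),
                          windows$visit1[1L], windows$visit1[2L], g)
      v2 <- round_to_grid(runif(1, windows$visit2[1L], windows$visit2[2L]),
                          windows$visit2[1L], windows$visit2[2L], g)
      tm <- c(v1, v2)
      if (i %in% v3_groups) {
        tm <- c(tm, round_to_grid(runif(1, windows$visit3[1L],
                                        windows$visit3[2L]),
                                  windows$visit3[1L], windows$visit3[2L],
                                  g))
      }
      tm
    })
  }

  window_of <- function(tval) {
    if (tval <= windows$visit1[2L]) windows$visit1
    else if (tval <= windows$visit2[2L]) windows$visit2
    else windows$visit3
  }

  best <- NULL
  for (tm in starts) {
    blocks <- lapply(tm, group_block)
    cur <- ld_from_blocks(blocks)
    trace <- cur
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (gi in seq_len(n_groups)) {
        for (ci in seq_along(tm[[gi]])) {
          win <- window_of(tm[[gi]][ci])
          cand_vals <- seq(round_to_grid(win[1L], win[1L], win[2L], g),
                           win[2L], by = g)
          for (v in cand_vals) {
            if (abs(v - tm[[gi]][ci]) < g / 2) next
            cand_times <- tm[[gi]]
            cand_times[ci] <- v
            cand_blk <- group_block(cand_times)
            if (is.null(cand_blk)) next
            cand_blocks <- blocks
            cand_blocks[[gi]] <- cand_blk
            val <- ld_from_blocks(cand_blocks)
            if (val > cur + 1e-9) {
              tm[[gi]][ci] <- v
              blocks <- cand_blocks
              cur <- val
              improved <- TRUE
            }
          }
        }
      }
      trace <- c(trace, cur)
      if (!improved) break
    }
    if (is.null(best) || cur > best$log_det) {
      best <- list(tm = tm, log_det = cur, trace = trace)
    }
  }

  emp_design <- load_scenario("3")
  emp_ld <- compute_fim(emp_design, model)$log_det
  list(design = make_design(best$tm), log_det = best$log_det,
       trace = best$trace,
       improvement_over_empirical = best$log_det - emp_ld)
}
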