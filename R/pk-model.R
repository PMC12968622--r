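#' Predict the concentration-time profile
#'
#' Evaluates the central-compartment concentration (amount / Vc/F, nmol/L)
#' of the two-compartment model with sequential zero-/first-order absorption,
#' superposing all administrations of the regimen at k * tau,
#' k = 0 .. n_doses - 1. The solution is the closed-form piecewise
#' superposition of the linear system (exact up to floating point), so the
#' model is exactly linear in dose.
#'
#' @param params a [pk_params()] object
#' @param regimen a [dosing_regimen()] object
#' @param times sampling times, h since first dose; non-negative, sorted
#' @return object of class `conc_profile`: list with `times` (h) and
#'   `conc` (nmol/L)
#' @export
#' @examples
#' p <- pk_params(10.083, 50, 30, 6, 2, 1.5, 0.3)
#' predict_concentration(p, dosing_regimen(25), times = seq(0, 24, 0.5))
predict_concentration <- function(params, regimen, times) {
  validate_pk_params(params)
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  dose_nmol <- dose_mg_to_nmol(regimen$dose_mg)
  dt <- regimen$tau * (seq_len(regimen$n_doses) - 1L)
  conc <- conc_profile_cpp(as.numeric(times), dt,
                           rep(dose_nmol, length(dt)), as_par_vec(params))
  if (any(!is.finite(conc))) {
    stop("numerical-accuracy error: non-finite concentration computed",
         call. = FALSE)
  }
  new_conc_profile(times, conc)
}

new_conc_profile <- function(times, conc) {
  structure(list(times = as.numeric(times), conc = as.numeric(conc)),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d points over [%g, %g] h, Cmax %.4g nmol/L\n",
              length(x$times), min(x$times), max(x$times), max(x$conc)))
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(time_h = x$times, conc_nmol_per_L = x$conc)
}

#' Write a concentration profile as two-column CSV
#'
#' Columns `time_h`, `conc_nmol_per_L`.
#'
#' @param profile a `conc_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady-state concentration profile over one dosing interval
#'
#' Simulates repeated once-daily administration (default 28 doses, the
#' duration of the adult reference study) and returns the profile over the
#' interval following the last dose, after verifying that the trough has
#' converged: relative change of the pre-dose concentration between
#' successive doses below `tol`.
#'
#' @param params a [pk_params()] object
#' @param regimen a [dosing_regimen()]; its `n_doses` is ignored in favour of
#'   `max_doses`
#' @param grid_step grid resolution, h (must be <= 0.1)
#' @param max_doses administrations to simulate before declaring steady state
#' @param tol relative trough-convergence tolerance
#' @return a `conc_profile` over `[0, tau]`, time origin at the last dose
#' @export
steady_state_profile <- function(params, regimen, grid_step = 0.05,
                                 max_doses = 28L, tol = 1e-6) {
  validate_pk_params(params)
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (grid_step > 0.1) stop("grid_step must be <= 0.1 h", call. = FALSE)
  if (max_doses > 60L) max_doses <- 60L
  tau <- regimen$tau
  dose_nmol <- dose_mg_to_nmol(regimen$dose_mg)
  pv <- as_par_vec(params)
  # trough immediately before each administration
  dt <- tau * (seq_len(max_doses) - 1L)
  troughs <- conc_profile_cpp(dt[-1L], dt, rep(dose_nmol, max_doses), pv)
  nd <- length(troughs)
  if (nd >= 2L) {
    rel <- abs(troughs[nd] - troughs[nd - 1L]) /
      max(troughs[nd], .Machine$double.eps)
    if (rel >= tol) {
      stop(sprintf(
        "trough failed to converge within %d intervals (relative change %.3g)",
        max_doses, rel), call. = FALSE)
    }
  }
  grid <- seq(0, tau, by = grid_step)
  if (grid[length(grid)] < tau) grid <- c(grid, tau)
  t_last <- tau * (max_doses - 1L)
  conc <- conc_profile_cpp(t_last + grid, dt, rep(dose_nmol, max_doses), pv)
  new_conc_profile(grid, conc)
}

#' Secondary exposure metrics over one dosing interval
#'
#' AUC(0-tau) by trapezoidal integration of the supplied profile, Cmax and
#' Tmax as the grid maximum (ties broken to the earliest time), and the
#' average steady-state concentration Css = AUC / tau.
#'
#' @param profile a `conc_profile` covering `[0, tau]` with step <= 0.05 h
#' @param tau dosing interval, h
#' @return object of class `exposure_metrics`: named list with `auc_0_24`
#'   (nmol*h/L), `cmax` (nmol/L), `tmax` (h), `css` (nmol/L)
#' @export
exposure_metrics <- function(profile, tau = 24) {
  stopifnot(inherits(profile, "conc_profile"))
  tt <- profile$times
  if (min(tt) > 1e-9 || max(tt) < tau - 1e-9) {
    stop("profile must span the full dosing interval [0, tau]", call. = FALSE)
  }
  if (max(diff(tt)) > 0.05 + 1e-12) {
    stop("profile grid step must be <= 0.05 h", call. = FALSE)
  }
  keep <- tt <= tau + 1e-9
  tt <- tt[keep]
  cc <- profile$conc[keep]
  auc <- sum(diff(tt) * (cc[-1L] + cc[-length(cc)])) / 2
  imax <- which.max(cc)  # which.max returns the first maximum: earliest time
  structure(list(auc_0_24 = auc, cmax = cc[imax], tmax = tt[imax],
                 css = auc / tau),
            class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf("AUC(0-24) %.4g nmol*h/L | Cmax %.4g nmol/L | Tmax %.3g h | Css %.4g nmol/L\n",
              x$auc_0_24, x$cmax, x$tmax, x$css))
  invisible(x)
}

#' Terminal half-life of the disposition model
#'
#' ln(2) / lambda_z, where lambda_z is the smaller of the two disposition
#' exponents obtained from the standard micro/macro-constant algebra. When
#' the peripheral compartment is negligible (q_f or vp_f ~ 0) the
#' one-compartment value ln(2) * vc_f / cl_f is returned.
#'
#' @param params a [pk_params()] object
#' @return half-life, h
#' @export
terminal_half_life <- function(params) {
  validate_pk_params(params)
  cl <- params[["cl_f"]]; vc <- params[["vc_f"]]
  vp <- params[["vp_f"]]; q <- params[["q_f"]]
  k20 <- cl / vc
  if (q <= 1e-8 * cl || vp <= 1e-8 * vc) {
    return(log(2) / k20)
  }
  k23 <- q / vc; k32 <- q / vp
  s <- k20 + k23 + k32
  lz <- (s - sqrt(s^2 - 4 * k20 * k32)) / 2
  log(2) / lz
}
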