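#' Structural pharmacokinetic parameters
#'
#' Typical (or individual) values of the two-compartment disposition model
#' with sequential zero-/first-order absorption. All parameters are apparent
#' (oral) quantities, i.e. already divided by bioavailability F.
#'
#' @param cl_f apparent clearance CL/F, L/h
#' @param vc_f apparent central volume Vc/F, L
#' @param vp_f apparent peripheral volume Vp/F, L
#' @param q_f apparent intercompartmental clearance Q/F, L/h
#' @param ka first-order absorption rate constant, 1/h
#' @param d1 duration of the zero-order input into the depot, h
#' @param alag1 absorption lag time, h
#' @return an object of class `pk_params` (named numeric vector)
#' @export
#' @examples
#' pk_params(cl_f = 10, vc_f = 50, vp_f = 30, q_f = 6,
#'           ka = 2, d1 = 1.5, alag1 = 0.3)
pk_params <- function(cl_f, vc_f, vp_f, q_f, ka, d1 = 0, alag1 = 0) {
  p <- c(cl_f = cl_f, vc_f = vc_f, vp_f = vp_f, q_f = q_f,
         ka = ka, d1 = d1, alag1 = alag1)
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  if (length(p) != 7L || !is.numeric(p)) {
    stop("pk_params must hold the 7 structural parameters", call. = FALSE)
  }
  if (any(!is.finite(p))) {
    stop("non-finite pharmacokinetic parameter: ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  strict <- p[c("cl_f", "vc_f", "vp_f", "q_f", "ka")]
  if (any(strict <= 0)) {
    stop("cl_f, vc_f, vp_f, q_f and ka must be strictly positive",
         call. = FALSE)
  }
  if (p[["d1"]] < 0 || p[["alag1"]] < 0) {
    stop("d1 and alag1 must be non-negative", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment oral PK parameters (apparent, /F)\n")
  print(unclass(signif(x, 5)))
  invisible(x)
}

# internal: coerce a pk_params (or bare named vector) to the unnamed numeric
# layout expected by the C++ kernels
as_par_vec <- function(p) {
  p <- unclass(p)
  as.numeric(p[c("cl_f", "vc_f", "vp_f", "q_f", "ka", "d1", "alag1")])
}

#' Once-daily oral dosing regimen
#'
#' @param dose_mg dose per administration, mg. The commercially available
#'   tablets are 10 and 25 mg; other positive values are accepted.
#' @param tau dosing interval, h (24 for once daily)
#' @param n_doses number of administrations (>= 1)
#' @return an object of class `dosing_regimen`
#' @export
dosing_regimen <- function(dose_mg, tau = 24, n_doses = 1L) {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1L || dose_mg <= 0) {
    stop("dose_mg must be a single positive number", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) {
    stop("n_doses must be an integer >= 1", call. = FALSE)
  }
  structure(list(dose_mg = dose_mg, tau = tau, n_doses = n_doses),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("%g mg every %g h, %d dose(s)\n", x$dose_mg, x$tau, x$n_doses))
  invisible(x)
}
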