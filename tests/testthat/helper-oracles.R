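# Independent numerical oracles: stiff ODE integration of the structural
# model (deSolve) and adaptive Gauss-Hermite quadrature for the marginal
# likelihood of a one-dimensional random effect.

# states: depot, central, peripheral, cumulative eliminated
ode_oracle <- function(params, dose_nmol, times, rtol = 1e-10) {
  p <- as.list(unclass(params))
  rhs <- function(t, A, .) {
    inp <- if (p$d1 > 0 && t > p$alag1 && t <= p$alag1 + p$d1) {
      dose_nmol / p$d1
    } else 0
    k20 <- p$cl_f / p$vc_f
    k23 <- p$q_f / p$vc_f
    k32 <- p$q_f / p$vp_f
    list(c(inp - p$ka * A[1],
           p$ka * A[1] - (k20 + k23) * A[2] + k32 * A[3],
           k23 * A[2] - k32 * A[3],
           k20 * A[2]))
  }
  tt <- sort(unique(c(0, times, p$alag1, p$alag1 + p$d1)))
  out <- deSolve::ode(c(0, 0, 0, 0), tt, rhs, NULL, rtol = rtol,
                      atol = 1e-10, method = "lsoda")
  out[match(times, tt), , drop = FALSE]
}

# Gauss-Hermite nodes/weights by Golub-Welsch
gh_rule <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1L, ]^2)
}

# -2 log marginal likelihood for one subject with a single random effect on
# clearance, by adaptive Gauss-Hermite quadrature
gh_ofv_cl <- function(y, times, dose_times, dose_amts, params, omega_cl,
                      sigma, n_nodes = 30L) {
  pv0 <- unclass(params)
  pred <- function(eta) {
    pv <- pv0
    pv[["cl_f"]] <- pv[["cl_f"]] * exp(eta)
    p <- structure(pv, class = "pk_params")
    cp <- empbridge:::conc_profile_cpp(times, dose_times, dose_amts,
                                       empbridge:::as_par_vec(p))
    cp
  }
  m2l <- function(eta) {
    f <- pred(eta)
    v <- sigma^2 * pmax(f, 1e-3)^2
    sum(log(2 * pi * v) + (y - f)^2 / v) +
      log(2 * pi * omega_cl) + eta^2 / omega_cl
  }
  opt <- optimize(m2l, c(-3, 3))
  h <- 1e-4
  hess <- (m2l(opt$minimum + h) - 2 * opt$objective +
             m2l(opt$minimum - h)) / h^2
  sd_ad <- sqrt(2 / hess)
  nd <- gh_rule(n_nodes)
  z <- opt$minimum + sqrt(2) * sd_ad * nd$x
  lik <- vapply(z, function(e) exp(-0.5 * m2l(e)), 0)
  integ <- sum(nd$w * lik * exp(nd$x^2)) * sqrt(2) * sd_ad
  -2 * log(integ)
}
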