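#' Rate parameters of the seeded aggregation model
#'
#' Bundles the rate constants and concentrations of the two-moment
#' master-equation description of seeded amyloid fibril formation. The state
#' variables are the fibril number concentration P and fibril mass
#' concentration M (monomer equivalents); free monomer is m = m_total - M.
#' New fibrils form by primary nucleation (rate `k_n * m^n_c`) and by
#' secondary nucleation on fibril surfaces (`k_2 * m^n_2 * M`); mass grows by
#' end elongation at net rate `2 * k_plus * P * (m - m_eq)`, proportional to
#' the supersaturation because the fibril solubility `m_eq` here is a large
#' fraction of the total peptide concentration.
#'
#' @param k_plus Elongation rate constant, mM^-1 h^-1.
#' @param k2 Secondary nucleation rate constant, mM^-n2 h^-1.
#' @param kn Primary nucleation rate constant, mM^(1-nc) h^-1.
#' @param n2,nc Secondary/primary nucleation reaction orders (>= 1).
#' @param m_total Total peptide concentration, mM.
#' @param m_eq Fibril solubility (equilibrium monomer concentration), mM.
#' @param seed_mass Seed concentration in monomer equivalents, mM.
#' @param seed_mean_size Mean number of monomers per seed fibril (> 0); sets
#'   the initial fibril number P(0) = seed_mass / seed_mean_size.
#' @param active_seed_fraction Fraction of seeds that are active, in [0, 1];
#'   scales both seed mass and seed number (the chaperone seed-inactivation
#'   hypothesis parameter).
#' @return A list of class `rate_parameters`.
#' @export
rate_parameters <- function(k_plus,
                            k2 = 0,
                            kn = 0,
                            n2 = 2,
                            nc = 2,
                            m_total = 5,
                            m_eq = 3.5,
                            seed_mass = 0.035,
                            seed_mean_size = 500,
                            active_seed_fraction = 1) {
  p <- list(k_plus = k_plus, k2 = k2, kn = kn, n2 = n2, nc = nc,
            m_total = m_total, m_eq = m_eq, seed_mass = seed_mass,
            seed_mean_size = seed_mean_size,
            active_seed_fraction = active_seed_fraction)
  if (any(unlist(p[c("k_plus", "k2", "kn")]) < 0)) {
    stop_oligochap("Rate constants must be >= 0.", "oligochap_parameter_error")
  }
  if (n2 < 1 || nc < 1) {
    stop_oligochap("Reaction orders must be >= 1.", "oligochap_parameter_error")
  }
  if (m_eq < 0 || m_eq >= m_total) {
    stop_oligochap("Require 0 <= m_eq < m_total.", "oligochap_parameter_error")
  }
  if (seed_mass < 0 || seed_mass >= m_total) {
    stop_oligochap("Require 0 <= seed_mass < m_total.",
                   "oligochap_parameter_error")
  }
  if (seed_mean_size <= 0) {
    stop_oligochap("`seed_mean_size` must be positive.",
                   "oligochap_parameter_error")
  }
  if (active_seed_fraction < 0 || active_seed_fraction > 1) {
    stop_oligochap("`active_seed_fraction` must be in [0, 1].",
                   "oligochap_parameter_error")
  }
  structure(p, class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters>\n")
  cat(sprintf("  k_plus = %.4g mM^-1 h^-1, k2 = %.4g, kn = %.4g (n2 = %g, nc = %g)\n",
              x$k_plus, x$k2, x$kn, x$n2, x$nc))
  cat(sprintf("  m_total = %g mM, m_eq = %g mM\n", x$m_total, x$m_eq))
  cat(sprintf("  seeds: %g mM monomer eq., mean size %g, active fraction %g\n",
              x$seed_mass, x$seed_mean_size, x$active_seed_fraction))
  invisible(x)
}

#' Integrate the two-moment aggregation equations
#'
#' Solves
#' \deqn{dP/dt = k_n m^{n_c} + k_2 m^{n_2} M, \quad
#'       dM/dt = 2 k_+ P (m - m_{eq}), \quad m = m_{total} - M,}
#' with M(0) = active seed mass and P(0) = M(0)/seed_mean_size, using a
#' stiff-capable adaptive integrator (rtol 1e-8, atol 1e-10).
#'
#' @param params A [rate_parameters()] object.
#' @param t_grid Increasing time grid starting at 0, hours.
#' @param rtol,atol Integrator tolerances.
#' @return Tibble with columns `t`, `m`, `M`, `P`.
#' @export
integrate_moments <- function(params, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_parameters"))
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE)) {
    stop_oligochap("`t_grid` must start at 0 and be strictly increasing.",
                   "oligochap_parameter_error")
  }
  M0 <- params$seed_mass * params$active_seed_fraction
  P0 <- M0 / params$seed_mean_size
  rhs <- function(t, y, p) {
    m <- max(p$m_total - y[["M"]], 0)
    dP <- p$kn * m^p$nc + p$k2 * m^p$n2 * y[["M"]]
    dM <- 2 * p$k_plus * y[["P"]] * (m - p$m_eq)
    # fibrils do not redissolve below solubility in this description
    if (m <= p$m_eq && dM < 0) dM <- 0
    list(c(P = dP, M = dM))
  }
  sol <- deSolve::lsoda(c(P = P0, M = M0), t_grid, rhs, params,
                        rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  if (anyNA(out) || any(!is.finite(as.matrix(out))) ||
      any(out$M < -1e-8) || any(out$P < -1e-10)) {
    stop_oligochap("Moment integration failed (non-finite or negative state).",
                   "oligochap_integration_error")
  }
  tibble(t = out$time, m = params$m_total - out$M, M = out$M, P = out$P)
}

#' Oligomer population driven by secondary nucleation
#'
#' Companion time course for the transient oligomer pool: oligomers are
#' generated by the secondary-nucleation flux on fibril surfaces (the dominant
#' oligomer source in an uninhibited seeded reaction) and lost with a
#' first-order rate, \eqn{dO/dt = k_2 (m - m_{eq})^{n_2} M - k_{loss} O},
#' O(0) = 0. The nucleation flux is driven by the supersaturation
#' \eqn{m - m_{eq}} so that oligomer production ceases once the monomer pool
#' relaxes to the fibril solubility; with a solubility this close to the total
#' concentration that is what makes the pulse rise and fall rather than
#' persist at the plateau. The solution is computed by exponential quadrature
#' of the convolution integral on the state grid, giving a pulse peaking in
#' the growth phase.
#'
#' @param state Output of [integrate_moments()].
#' @param params The [rate_parameters()] used for `state`.
#' @param k_loss First-order oligomer loss rate, h^-1.
#' @return `state` with an added column `O` (oligomer concentration, same
#'   concentration units as the source term integral).
#' @export
oligomer_population <- function(state, params, k_loss = 3.5) {
  stopifnot(inherits(params, "rate_parameters"))
  if (k_loss < 0) {
    stop_oligochap("`k_loss` must be >= 0.", "oligochap_parameter_error")
  }
  src <- params$k2 * pmax(state$m - params$m_eq, 0)^params$n2 * state$M
  n <- length(src)
  O <- numeric(n)
  # exponential quadrature of O(t) = int_0^t exp(-k_loss (t - s)) src(s) ds,
  # stepped recursively; the per-step integral is exact for a source linear
  # over the step, and remains well behaved for arbitrarily stiff loss
  for (i in seq_len(n - 1)) {
    h <- state$t[i + 1] - state$t[i]
    z <- k_loss * h
    if (z < 1e-8) {
      w0 <- h / 2; w1 <- h / 2 # trapezoid limit
      decay <- 1 - z
    } else {
      decay <- exp(-z)
      e1 <- (1 - decay) / k_loss
      w1 <- (h - e1) / z # weight of src[i+1]
      w0 <- e1 - w1      # weight of src[i]
    }
    O[i + 1] <- O[i] * decay + w0 * src[i] + w1 * src[i + 1]
  }
  dplyr::mutate(state, O = O)
}

#' Normalize a kinetic trace to mass fraction
#'
#' Assumes the thioflavin-T signal is affine in fibril mass and rescales a
#' trace to the unit interval using the mean of the first 5 points as baseline
#' and the mean of the final 10 percent of points as plateau. The result is
#' clipped to [-0.05, 1.05].
#'
#' @param signal Numeric fluorescence trace (one well).
#' @param drift_tol Maximum allowed relative drift across the final 10% of
#'   points for the plateau to count as reached.
#' @return Normalized numeric vector.
#' @export
normalize_trace <- function(signal, drift_tol = 0.05) {
  n <- length(signal)
  if (n < 10L || any(!is.finite(signal))) {
    stop_oligochap("Trace too short or non-finite.", "oligochap_parameter_error")
  }
  tail_ix <- seq.int(ceiling(0.9 * n), n)
  baseline <- mean(signal[1:5])
  plateau <- mean(signal[tail_ix])
  rng <- plateau - baseline
  if (abs(rng) < 1e-12 * max(abs(signal), 1)) {
    stop_oligochap("Trace has no dynamic range: plateau not reached.",
                   "oligochap_no_plateau_error")
  }
  drift <- diff(range(signal[tail_ix])) / abs(rng)
  if (drift > drift_tol) {
    stop_oligochap(
      sprintf("Final 10%% of points drift by %.1f%% of the dynamic range: plateau not reached.",
              100 * drift),
      "oligochap_no_plateau_error")
  }
  pmin(pmax((signal - baseline) / rng, -0.05), 1.05)
}

#' Aggregation half-time
#'
#' Time of the first upward crossing of 0.5 by a normalized mass-fraction
#' series, linearly interpolated between the bracketing samples.
#'
#' @param t Time grid, hours.
#' @param normalized Normalized mass fraction (same length as `t`).
#' @return Half-time in hours.
#' @export
halftime <- function(t, normalized) {
  stopifnot(length(t) == length(normalized))
  below <- normalized < 0.5
  cross <- which(below[-length(below)] & !below[-1])
  if (length(cross) == 0L) {
    stop_oligochap("Series never crosses 0.5 upward.", "oligochap_no_crossing_error")
  }
  i <- cross[1]
  t[i] + (0.5 - normalized[i]) *
    (t[i + 1] - t[i]) / (normalized[i + 1] - normalized[i])
}

# simulated normalized mass-fraction curve for a parameter set
simulated_mass_fraction <- function(params, t_grid) {
  st <- integrate_moments(params, t_grid)
  M_end <- params$m_total - params$m_eq
  (st$M - st$M[1]) / (M_end - st$M[1])
}

#' Half-time of a simulated parameter set
#'
#' Convenience wrapper: integrates the moments and extracts the half-time of
#' the fibril mass growth between its initial value and the solubility-limited
#' plateau `m_total - m_eq`.
#'
#' @inheritParams integrate_moments
#' @return Half-time in hours.
#' @export
simulated_halftime <- function(params, t_grid) {
  halftime(t_grid, simulated_mass_fraction(params, t_grid))
}
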