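# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: brute-force discretisations and scalar root
# finders only.

# Finite-difference solution of the 1-D diffusion equation on [0, 1] with
# reflecting (zero-flux) boundaries and step initial condition u = 1 on
# [0, 1/2]; returns the fraction of mass in the far half [1/2, 1] after
# dimensionless time tau = kappa * D.
fd_diffused_fraction <- function(tau, nx = 2000, nsteps = 400) {
  # cell-centered grid: the stream interface at 1/2 falls exactly between
  # cells nx/2 and nx/2 + 1, so the step initial condition is represented
  # without a straddling cell
  dx <- 1 / nx
  dt <- tau / nsteps
  x <- (seq_len(nx) - 0.5) * dx
  u <- as.numeric(x < 0.5)
  lam <- dt / (2 * dx^2) # Crank-Nicolson
  # tridiagonal coefficients (zero-flux walls: boundary cells exchange with
  # one neighbour only)
  lower <- rep(-lam, nx); upper <- rep(-lam, nx)
  diag0 <- rep(1 + 2 * lam, nx)
  diag0[1] <- 1 + lam; diag0[nx] <- 1 + lam
  thomas <- function(a, b, c, d) {
    n <- length(d)
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
    for (i in 2:n) {
      m <- b[i] - a[i] * cp[i - 1]
      cp[i] <- c[i] / m
      dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
    }
    out <- numeric(n)
    out[n] <- dp[n]
    for (i in (n - 1):1) out[i] <- dp[i] - cp[i] * out[i + 1]
    out
  }
  # Rannacher start-up: damp the modes excited by the discontinuous initial
  # profile with a few backward-Euler steps before switching to CN, which is
  # only neutrally stable for them
  be_steps <- 4L
  lower_be <- 2 * lower; upper_be <- 2 * upper
  diag_be <- 1 + (diag0 - 1) * 2 # implicit with full dt
  for (s in seq_len(be_steps)) {
    u <- thomas(lower_be, diag_be, upper_be, u)
  }
  for (s in seq_len(nsteps - be_steps)) {
    # explicit half: rhs = (I + lam * L) u with zero-flux ends
    rhs <- u
    rhs[2:(nx - 1)] <- u[2:(nx - 1)] +
      lam * (u[3:nx] - 2 * u[2:(nx - 1)] + u[1:(nx - 2)])
    rhs[1] <- u[1] + lam * (u[2] - u[1])
    rhs[nx] <- u[nx] + lam * (u[nx - 1] - u[nx])
    u <- thomas(lower, diag0, upper, rhs)
  }
  sum(u[x > 0.5]) / sum(u)
}

# Fixed-step classical RK4 integration of the two-moment system.
rk4_moments <- function(params, t_grid, substeps = 10L) {
  rhs <- function(y, p) {
    m <- p$m_total - y[2]
    dP <- p$kn * m^p$nc + p$k2 * m^p$n2 * y[2]
    dM <- 2 * p$k_plus * y[1] * (m - p$m_eq)
    if (m <= p$m_eq && dM < 0) dM <- 0
    c(dP, dM)
  }
  M0 <- params$seed_mass * params$active_seed_fraction
  y <- c(M0 / params$seed_mean_size, M0)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 2)
  out[1, ] <- y
  for (i in seq_len(length(t_grid) - 1)) {
    h <- (t_grid[i + 1] - t_grid[i]) / substeps
    for (s in seq_len(substeps)) {
      k1 <- rhs(y, params)
      k2 <- rhs(y + h / 2 * k1, params)
      k3 <- rhs(y + h / 2 * k2, params)
      k4 <- rhs(y + h * k3, params)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1, ] <- y
  }
  tibble::tibble(t = t_grid, P = out[, 1], M = out[, 2])
}

# Scalar root-finder solution of the mass-action binding equilibrium
# (C - B)(S - B) = K_D * B on the physical bracket [0, min(C, S)].
root_bound_concentration <- function(C, S, K_D) {
  if (C == 0 || S == 0) return(0)
  f <- function(B) (C - B) * (S - B) - K_D * B
  uniroot(f, lower = 0, upper = min(C, S), tol = 1e-14)$root
}

# Direct quadrature of the oligomer convolution
# O(t) = int_0^t exp(-k_loss (t - s)) src(s) ds on a dense grid, with the
# source interpolated by splines; integrates each target time independently.
quadrature_oligomers <- function(t_src, src, t_eval, k_loss) {
  sf <- splinefun(t_src, src)
  vapply(t_eval, function(tt) {
    if (tt == 0) return(0)
    integrate(function(s) exp(-k_loss * (tt - s)) * sf(s),
              lower = 0, upper = tt, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Shared small fixtures -------------------------------------------------------

default_kinetic_params <- function(...) {
  args <- list(...)
  do.call(rate_parameters,
          modifyList(list(k_plus = 0.25, k2 = 0.025, n2 = 2,
                          m_total = 5, m_eq = 3.5, seed_mass = 0.035,
                          seed_mean_size = 500),
                     args))
}

logistic_trace <- function(t, t0 = 6, k = 1.5, lo = 0.2, hi = 1.7) {
  lo + (hi - lo) / (1 + exp(-k * (t - t0)))
}
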