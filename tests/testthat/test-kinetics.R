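test_that("moment integration conserves mass and respects the solubility plateau", {
  p <- default_kinetic_params()
  st <- integrate_moments(p, seq(0, 120, by = 0.5))
  expect_true(all(abs(st$m + st$M - p$m_total) / p$m_total < 1e-6))
  expect_true(all(diff(st$M) > -1e-9)) # non-decreasing above solubility
  expect_true(all(st$M >= 0 & st$P >= 0))
  # 5 mM total with 3.5 mM solubility leaves 3.5 mM free monomer at the end
  expect_equal(tail(st$m, 1), 3.5, tolerance = 1e-5)
  expect_equal(tail(st$M, 1), 1.5, tolerance = 1e-5)
})

test_that("elongation-only early growth matches the analytic linearization", {
  p <- default_kinetic_params(k2 = 0, kn = 0)
  M0 <- p$seed_mass
  P0 <- M0 / p$seed_mean_size
  slope <- 2 * p$k_plus * P0 * (p$m_total - M0 - p$m_eq)
  # first ~1% of the mass conversion
  t_end <- 0.01 * (p$m_total - p$m_eq) / slope
  st <- integrate_moments(p, seq(0, t_end, length.out = 50))
  slope_num <- (tail(st$M, 1) - M0) / t_end
  expect_equal(slope_num, slope, tolerance = 0.01)
})

test_that("adaptive integration agrees with a fixed-step RK4 reference", {
  p <- default_kinetic_params()
  tg <- seq(0, 20, by = 0.1)
  ref <- rk4_moments(p, tg, substeps = 10L)
  st <- integrate_moments(p, tg)
  expect_lt(max(abs(st$M - ref$M)) / max(ref$M), 1e-4)
  expect_lt(max(abs(st$P - ref$P)) / max(ref$P), 1e-4)
})

test_that("halving the active seed fraction delays secondary-nucleation-dominated growth", {
  p <- default_kinetic_params() # kn = 0, k2 > 0, seeds > 0
  tg <- seq(0, 60, by = 0.02)
  th1 <- simulated_halftime(p, tg)
  p$active_seed_fraction <- 0.5
  th2 <- simulated_halftime(p, tg)
  expect_gt(th2, th1)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(rate_parameters(k_plus = -1), class = "oligochap_parameter_error")
  expect_error(rate_parameters(k_plus = 1, m_eq = 6, m_total = 5),
               class = "oligochap_parameter_error")
  expect_error(rate_parameters(k_plus = 1, active_seed_fraction = 1.2),
               class = "oligochap_parameter_error")
  p <- default_kinetic_params()
  expect_error(integrate_moments(p, c(0, 2, 1)),
               class = "oligochap_parameter_error")
  expect_error(integrate_moments(p, c(1, 2, 3)),
               class = "oligochap_parameter_error")
})

test_that("oligomer pulse peaks in the growth phase and matches direct quadrature", {
  p <- default_kinetic_params()
  tg <- seq(0, 16, length.out = 800)
  st <- integrate_moments(p, tg)
  k_loss <- 3.5
  res <- oligomer_population(st, p, k_loss)
  i_pk <- which.max(res$O)
  conv <- (res$M[i_pk] - res$M[1]) / (p$m_total - p$m_eq - res$M[1])
  expect_gt(conv, 0.2)
  expect_lt(conv, 0.8)
  expect_lt(tail(res$O, 1), 0.01 * max(res$O)) # pulse dies out
  # oracle: direct quadrature of the convolution solution
  src <- p$k2 * pmax(res$m - p$m_eq, 0)^p$n2 * res$M
  t_eval <- tg[seq(40, 800, by = 95)]
  O_oracle <- quadrature_oligomers(tg, src, t_eval, k_loss)
  O_hat <- approx(res$t, res$O, xout = t_eval)$y
  expect_equal(O_hat, O_oracle, tolerance = 1e-4)
})

test_that("oligomer pulse degenerate cases", {
  p <- default_kinetic_params()
  tg <- seq(0, 16, length.out = 200)
  st <- integrate_moments(p, tg)
  p0 <- default_kinetic_params(k2 = 0)
  st0 <- integrate_moments(p0, tg)
  expect_true(all(oligomer_population(st0, p0, 1)$O == 0)) # no source
  big <- oligomer_population(st, p, 1e6)$O # instantaneous loss
  expect_lt(max(big), 1e-4 * max(oligomer_population(st, p, 3.5)$O))
  expect_error(oligomer_population(st, p, -1),
               class = "oligochap_parameter_error")
})

test_that("trace normalization is affine invariant and recovers logistic limits", {
  t <- seq(0, 14, by = 0.1)
  y <- logistic_trace(t)
  n1 <- normalize_trace(y)
  n2 <- normalize_trace(3.7 * y - 11)
  expect_equal(n1, n2, tolerance = 1e-12)
  expect_lt(abs(min(n1) - 0), 0.01)
  expect_gt(max(n1), 0.99)
  expect_error(normalize_trace(rep(1, 50)), class = "oligochap_no_plateau_error")
  ramp <- seq(0, 1, length.out = 60) # still rising at the end
  expect_error(normalize_trace(ramp), class = "oligochap_no_plateau_error")
})

test_that("halftime interpolates the first upward half-crossing", {
  t <- seq(0, 14, by = 0.05)
  y <- normalize_trace(logistic_trace(t, t0 = 6))
  expect_equal(halftime(t, y), 6, tolerance = 0.02)
  y2 <- normalize_trace(logistic_trace(t, t0 = 8.5))
  expect_equal(halftime(t, y2) - halftime(t, y), 2.5, tolerance = 0.02)
  expect_error(halftime(t, rep(0.2, length(t))),
               class = "oligochap_no_crossing_error")
})
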