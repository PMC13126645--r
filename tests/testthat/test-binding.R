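test_that("depletion quadratic satisfies mass action against a root-finder oracle", {
  expect_equal(bound_concentration(12.5, 12.5, 12.5), 4.774575,
               tolerance = 1e-6) # frozen from the scalar root finder
  set.seed(4)
  for (i in 1:25) {
    C <- runif(1, 0.1, 500); S <- runif(1, 0.1, 500); K <- runif(1, 0.01, 200)
    B <- bound_concentration(C, S, K)
    expect_equal(B, root_bound_concentration(C, S, K), tolerance = 1e-9)
    expect_true(B >= 0 && B <= min(C, S) + 1e-12)
    expect_lt(abs((C - B) * (S - B) - K * B) / max(K * B, 1e-12), 1e-7)
  }
  expect_equal(bound_concentration(12.5, 400, 0), 12.5) # stoichiometric limit
  expect_equal(bound_concentration(3, 1, 0), 1)
  expect_equal(bound_concentration(12.5, 1e9, 5), 12.5, tolerance = 1e-6)
  expect_error(bound_concentration(-1, 1, 1), class = "oligochap_parameter_error")
})

test_that("isotherm has the plateau limits and monotone decrease", {
  p <- binding_parameters(K_D = 1, C_s = 400, f_0 = 0.42, f_b = 0.15,
                          C_jb6 = 12.5)
  expect_equal(model_fraction(0, p), 0.42)
  expect_equal(model_fraction(1e5, p), 0.15, tolerance = 1e-4)
  # agreement with the oracle-built prediction at a non-trivial point
  B <- root_bound_concentration(12.5, 0.01 * 400, 1)
  expect_equal(model_fraction(0.01, p),
               0.42 + (0.15 - 0.42) * B / 12.5, tolerance = 1e-10)
  set.seed(9)
  for (i in 1:10) {
    pr <- binding_parameters(K_D = runif(1, 0.1, 50), C_s = runif(1, 50, 800),
                             f_0 = runif(1, 0.3, 0.45),
                             f_b = runif(1, 0.05, 0.25), C_jb6 = 12.5)
    f <- model_fraction(10^seq(-4, 0, length.out = 40), pr)
    expect_true(all(diff(f) < 1e-12))
  }
})

test_that("noiseless titrations are recovered to high precision", {
  p <- binding_parameters(K_D = 1, C_s = 400, f_0 = 0.42, f_b = 0.2,
                          C_jb6 = 12.5)
  X <- 10^seq(log10(1.4e-4), log10(0.75), length.out = 14)
  pts <- tibble::tibble(X = X, f = model_fraction(X, p))
  fit <- fit_binding(pts, C_jb6 = 12.5)
  expect_equal(fit$parameters$K_D, 1, tolerance = 1e-3)
  expect_equal(fit$parameters$C_s, 400, tolerance = 1e-3)
  expect_equal(fit$parameters$f_0, 0.42, tolerance = 1e-5)
  expect_equal(fit$parameters$f_b, 0.2, tolerance = 1e-5)
  expect_lt(fit$ess, 1e-12)
})

test_that("degenerate designs are rejected", {
  pts <- tibble::tibble(X = rep(0, 10), f = rnorm(10, 0.42, 0.001))
  expect_error(fit_binding(pts), class = "oligochap_fit_error")
})

test_that("ess profile is 1 at the optimum and rises away from it on clean data", {
  p <- binding_parameters(K_D = 2, C_s = 400, f_0 = 0.42, f_b = 0.2,
                          C_jb6 = 12.5)
  X <- 10^seq(-4, log10(0.75), length.out = 12)
  pts <- tibble::tibble(X = X, f = model_fraction(X, p))
  fit <- fit_binding(pts)
  prof <- ess_profile(pts, fit, kd_grid = c(0.02, 0.2, 2, 20, 200))
  ratio <- prof$profile$ratio
  # on noiseless data the unconstrained optimum sits at the numerical floor:
  # the profile can only tie it (at the generating K_D), never beat it
  # meaningfully, while constrained wrong K_D values are far worse
  expect_lte(min(ratio), 1 + 1e-6)
  expect_gt(ratio[5], 10) # far off-optimum fits are strictly worse
  expect_gt(ratio[1], 10)
  expect_equal(prof$profile$K_D[which.min(ratio)], 2)
})

test_that("synthetic supernatant titration reproduces the one-sided affinity bound", {
  d <- generate_titrations(scenario_config("fig4d", seed = 1))
  fit <- fit_binding(d)
  prof <- ess_profile(d, fit)
  # generating K_D (1 nM) lies in the 1.25-threshold profile interval
  expect_lte(prof$interval[1], 1)
  expect_gte(prof$interval[2], 1)
  # free-chaperone plateau recovered
  expect_equal(fit$parameters$f_0, 0.42, tolerance = 0.02 / 0.42)
  # profile flat (within threshold) at and below the generating K_D
  low <- prof$profile$ratio[prof$profile$ok & prof$profile$K_D <= 1]
  expect_true(all(low <= prof$threshold))
})

test_that("bootstrap standard errors are produced and finite", {
  d <- generate_titrations(scenario_config("fig4d", seed = 3))
  fit <- fit_binding(d, n_boot = 30, seed = 5)
  expect_named(fit$boot_se, c("K_D", "C_s", "f_0", "f_b"))
  expect_true(all(is.finite(fit$boot_se[c("f_0", "f_b")])))
  expect_gt(fit$boot_se[["f_0"]], 0)
})

test_that("chaperone titration at fixed supernatant fraction spans bound to free", {
  # tight binding so the low-chaperone limit is fully bound
  p <- binding_parameters(K_D = 0.01, C_s = 400, f_0 = 0.42, f_b = 0.2,
                          C_jb6 = 12.5)
  curve <- chaperone_titration_curve(c(0.05, 3, 10, 30, 75, 1e4), 0.025, p)
  expect_true(all(diff(curve$r_h_apparent) < 1e-9)) # monotone non-increasing
  expect_equal(curve$r_h_apparent[1], 11, tolerance = 0.05) # all bound
  expect_equal(tail(curve$r_h_apparent, 1), 3, tolerance = 0.05) # excess free
  expect_error(chaperone_titration_curve(10, 0.025, p, r_free = 5, r_bound = 4),
               class = "oligochap_parameter_error")
})
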