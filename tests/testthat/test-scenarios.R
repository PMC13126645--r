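test_that("generators are pure functions of their configuration", {
  for (gen in list(
    function(s) generate_kinetics(scenario_config("fig3a", seed = s,
                                                  overrides = list(t_max = 20))),
    function(s) generate_titrations(scenario_config("fig4d", seed = s)),
    function(s) generate_decays(scenario_config("fig5_37C", seed = s)),
    function(s) generate_saxs(scenario_config("fig3c", seed = s)))) {
    a <- gen(7); b <- gen(7); c2 <- gen(8)
    expect_identical(dplyr::as_tibble(a), dplyr::as_tibble(b))
    expect_false(identical(dplyr::as_tibble(a), dplyr::as_tibble(c2)))
  }
})

test_that("unknown scenarios and mismatched generators are rejected", {
  expect_error(scenario_config("fig9z"), class = "oligochap_config_error")
  expect_error(generate_kinetics(scenario_config("fig4d")),
               class = "oligochap_config_error")
  expect_error(generate_decays(scenario_config("fig3a")),
               class = "oligochap_config_error")
  expect_error(scenario_config("fig3a", noise = list(tht = -1)),
               class = "oligochap_config_error")
})

test_that("chaperone-free kinetics hit the configured half-time and order with dose", {
  tr <- generate_kinetics(scenario_config("fig3a", seed = 2,
                                          noise = list(tht = 0)))
  med <- median_traces(tr)
  th <- med |>
    dplyr::group_by(jb6_conc) |>
    dplyr::summarise(t_half = halftime(t, normalize_trace(signal)),
                     .groups = "drop") |>
    dplyr::arrange(jb6_conc)
  expect_equal(th$t_half[th$jb6_conc == 0], 6.5, tolerance = 0.02)
  expect_equal(th$t_half[th$jb6_conc == 50], 13, tolerance = 0.02)
  expect_true(all(diff(th$t_half) > 0)) # monotone in chaperone dose
})

test_that("replicate counts follow the experimental design", {
  tr <- generate_kinetics(scenario_config("fig3a", seed = 1,
                                          overrides = list(t_max = 10)))
  counts <- tr |>
    dplyr::distinct(jb6_conc, well_id) |>
    dplyr::count(jb6_conc)
  expect_equal(counts$n[counts$jb6_conc == 0], 7)
  expect_true(all(counts$n[counts$jb6_conc > 0] == 5))
})

test_that("noiseless oligomer time course peaks at the co-oligomer size near t_half", {
  tc <- generate_oligomer_timecourse(
    scenario_config("fig4a", noise = list(fraction = 0)))
  expect_equal(tc$r_h_apparent[tc$t == 0][1], 3, tolerance = 1e-3)
  pk <- max(tc$r_h_apparent)
  expect_equal(pk, 11, tolerance = 0.02) # essentially all probe bound at peak
  t_pk <- tc$t[which.max(tc$r_h_apparent)]
  expect_gt(t_pk, 0.5 * 6.5); expect_lt(t_pk, 1.5 * 6.5) # near t_half
  expect_equal(tail(tc$r_h_apparent, 1), 3, tolerance = 0.05) # returns to free
  tb <- generate_oligomer_timecourse(
    scenario_config("fig4b", noise = list(fraction = 0)))
  expect_equal(max(tb$r_h_apparent), 5, tolerance = 0.02)
})

test_that("titration scenarios honor their printed anchor values", {
  d0 <- generate_titrations(scenario_config("fig4d", noise = list(fraction = 0)))
  man <- attr(d0, "manifest")$parameters
  # lowest supernatant fraction sits at the free-chaperone plateau
  expect_equal(d0$f[d0$X == min(d0$X)][1], 0.42, tolerance = 0.01 / 0.42)
  # highest fraction saturates towards the bound plateau
  f_hi <- d0$f[d0$X == max(d0$X)][1]
  expect_equal(f_hi, man$f_b, tolerance = 0.02)
  c4 <- generate_titrations(scenario_config("fig4c", noise = list(r_h = 0)))
  mean_r <- c4 |>
    dplyr::group_by(c_jb6) |>
    dplyr::summarise(r = mean(r_h_apparent), .groups = "drop") |>
    dplyr::arrange(c_jb6)
  expect_true(all(diff(mean_r$r) < 1e-9)) # size falls as probe saturates
})

test_that("decay scenarios encode the reported rates and replicate noise model", {
  d <- generate_decays(scenario_config("fig5_23C", seed = 4,
                                       noise = list(r_h = 0)))
  man <- attr(d, "manifest")$parameters
  expect_equal(man$k_off$without_JB6, 1.3)
  expect_equal(man$k_off$with_JB6, 0.8)
  wo <- dplyr::filter(d, condition == "without_JB6")
  expect_equal(fit_decay(wo)$k_off, 1.3, tolerance = 1e-6)
  # replicate means stay within 2 sd/sqrt(N) of the model curve
  dn <- generate_decays(scenario_config("fig5_23C", seed = 4))
  chk <- dn |>
    dplyr::filter(condition == "without_JB6") |>
    dplyr::group_by(t) |>
    dplyr::summarise(m = mean(r_h), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(mu = 7 * exp(-1.3 * t) + 3)
  frac_in <- mean(abs(chk$m - chk$mu) <= 2 * 0.5 / sqrt(chk$n))
  expect_gt(frac_in, 0.85)
})

test_that("noiseless generator output closes the loop through every fitter", {
  # titration -> binding fit
  d <- generate_titrations(scenario_config("fig4d", noise = list(fraction = 0)))
  man <- attr(d, "manifest")$parameters
  bf <- fit_binding(d)
  expect_equal(bf$parameters$K_D, man$K_D_nM, tolerance = 0.01)
  expect_equal(bf$parameters$C_s, man$C_s_nM, tolerance = 0.01)
  # saxs -> staged fit (covered in detail in the scattering tests)
  s <- generate_saxs(scenario_config("fig3c", noise = list(saxs = 0)))
  sf <- fit_saxs(s, contrast_scale = 0.01)
  expect_equal(sf$concentration, 3.9, tolerance = 1e-3)
  # decays -> exponential fit
  dd <- generate_decays(scenario_config("fig5_37C", noise = list(r_h = 0)))
  expect_equal(fit_decay(dplyr::filter(dd, condition == "with_JB6"))$k_off,
               1.9, tolerance = 1e-6)
})
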