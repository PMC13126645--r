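test_that("Stokes-Einstein conversion matches hand evaluation and scaling laws", {
  # k_B * 298.15 / (6 pi * 8.9e-4 * 3e-9) = 8.179e-11 m^2/s
  expect_equal(stokes_einstein_D(3, 298.15, 8.9e-4), 8.179e-11,
               tolerance = 1e-4)
  expect_equal(stokes_einstein_D(6), stokes_einstein_D(3) / 2,
               tolerance = 1e-12)
  expect_lt(stokes_einstein_D(1e8), 1e-17)
  expect_error(stokes_einstein_D(-1), class = "oligochap_parameter_error")
  expect_error(stokes_einstein_D(3, temperature = 0),
               class = "oligochap_parameter_error")
})

test_that("diffused fraction has the right limits and is strictly monotone in size", {
  cal <- default_calibration()
  expect_lt(diffused_fraction(1e-18, cal), 1e-4)
  expect_gt(diffused_fraction(1e-18, cal), 0)
  expect_equal(diffused_fraction(1e-6, cal), 0.5, tolerance = 1e-9)
  r <- seq(0.5, 50, length.out = 100)
  f <- diffused_fraction(stokes_einstein_D(r), cal)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f < 0.5))
})

test_that("series truncation at 51 odd terms is converged", {
  cal51 <- default_calibration()
  cal501 <- channel_calibration(cal51$kappa, n_terms = 501L)
  D <- seq(1e-3, 5, length.out = 40) / cal51$kappa # kappa*D in [1e-3, 5]
  expect_lt(max(abs(diffused_fraction(D, cal51) - diffused_fraction(D, cal501))),
            1e-10)
})

test_that("forward map agrees with a finite-difference diffusion oracle", {
  cal <- default_calibration()
  for (r_h in c(2, 5, 12)) {
    D <- stokes_einstein_D(r_h)
    tau <- cal$kappa * D / 4 # unit-domain diffusion time
    expect_equal(diffused_fraction(D, cal), fd_diffused_fraction(tau),
                 tolerance = 1e-4)
  }
})

test_that("channel calibration reproduces its anchors", {
  cal <- calibrate_channel(data.frame(r_h = 3, f = 0.42))
  expect_equal(diffused_fraction(stokes_einstein_D(3), cal), 0.42,
               tolerance = 1e-6)
  # two anchors generated from one kappa are recovered exactly
  truth <- channel_calibration(kappa = 5e9)
  anchors <- data.frame(r_h = c(3, 10))
  anchors$f <- diffused_fraction(stokes_einstein_D(anchors$r_h), truth)
  cal2 <- calibrate_channel(anchors)
  expect_equal(cal2$kappa, truth$kappa, tolerance = 1e-6)
  expect_error(calibrate_channel(data.frame(r_h = 3, f = 0.6)),
               class = "oligochap_calibration_error")
})

test_that("inversion round trips and flags out-of-range fractions", {
  cal <- default_calibration()
  r <- seq(1, 30, length.out = 25)
  f <- diffused_fraction(stokes_einstein_D(r), cal)
  expect_lt(max(abs(invert_fraction(f, cal) - r)), 1e-3)
  expect_equal(invert_fraction(0.42, cal), 3, tolerance = 1e-3)
  # fraction above what the smallest allowed particle can produce
  expect_error(invert_fraction(0.49999, cal),
               class = "oligochap_out_of_range_error")
  # a near-equilibrated fraction maps to a small particle, consistently with
  # the forward map evaluated at the returned radius
  r49 <- invert_fraction(0.49, cal)
  expect_lt(r49, 2)
  expect_equal(diffused_fraction(stokes_einstein_D(r49), cal), 0.49,
               tolerance = 1e-5)
})

test_that("mixtures average in fraction space with the expected size bias", {
  cal <- default_calibration()
  one <- mixture_fraction(tibble::tibble(r_h = 7, label_fraction = 1), cal)
  expect_equal(one, diffused_fraction(stokes_einstein_D(7), cal))
  f3 <- diffused_fraction(stokes_einstein_D(3), cal)
  f11 <- diffused_fraction(stokes_einstein_D(11), cal)
  mix <- mixture_fraction(
    tibble::tibble(r_h = c(3, 11), label_fraction = c(0.5, 0.5)), cal)
  expect_equal(mix, (f3 + f11) / 2, tolerance = 1e-12)
  r_app <- invert_fraction(mix, cal)
  expect_gt(r_app, 3); expect_lt(r_app, 11)
  expect_lt(r_app, 7) # fraction-space averaging biases below the midpoint
  # equal component radii collapse to that radius for any weights
  same <- mixture_fraction(
    tibble::tibble(r_h = c(5, 5, 5), label_fraction = c(0.2, 0.3, 0.5)), cal)
  expect_equal(invert_fraction(same, cal), 5, tolerance = 1e-3)
  expect_error(
    mixture_fraction(tibble::tibble(r_h = c(3, 11),
                                    label_fraction = c(0.6, 0.6)), cal),
    class = "oligochap_mixture_error")
})

test_that("two-chamber intensities convert and QC-clip to sizes", {
  m <- tibble::tibble(replicate_id = c("a", "b", "c"),
                      intensity_inlet = c(580, 510, 450),
                      intensity_diffused = c(420, 490, 560))
  expect_warning(out <- size_measurements(m), "clipped")
  expect_equal(out$diffused_fraction[1], 0.42)
  expect_equal(out$diffused_fraction[2], 0.49)
  expect_equal(out$diffused_fraction[3], 0.4999) # 0.554 clipped
  expect_equal(out$r_h_apparent[1], 3, tolerance = 1e-3)
  expect_error(
    size_measurements(tibble::tibble(replicate_id = "x",
                                     intensity_inlet = -1,
                                     intensity_diffused = 2)),
    class = "oligochap_parse_error")
})
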