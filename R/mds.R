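#' Stokes-Einstein diffusion coefficient
#'
#' Converts a hydrodynamic radius to a translational diffusion coefficient,
#' \eqn{D = k_B T / (6 \pi \eta R_h)}.
#'
#' @param r_h Hydrodynamic radius in nm.
#' @param temperature Absolute temperature in K.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Diffusion coefficient in m^2 s^-1 (vectorised over `r_h`).
#' @examples
#' stokes_einstein_D(3) # free chaperone monomer, ~8.2e-11 m^2/s
#' @export
stokes_einstein_D <- function(r_h, temperature = 298.15, viscosity = 8.9e-4) {
  if (any(!is.finite(r_h)) || any(r_h <= 0)) {
    stop_oligochap("`r_h` must be positive and finite.", "oligochap_parameter_error")
  }
  if (temperature <= 0 || viscosity <= 0) {
    stop_oligochap("`temperature` and `viscosity` must be positive.",
                   "oligochap_parameter_error")
  }
  .kB * temperature / (6 * pi * viscosity * (r_h * 1e-9))
}

#' Microfluidic diffusional-sizing channel calibration
#'
#' A one-parameter model of the sizing channel: two streams co-flow in laminar
#' flow, the labelled sample occupying one half of the channel width at the
#' inlet; lateral diffusion during the residence time redistributes it, and the
#' fluorescence split between the two outlet chambers gives the diffused
#' fraction. With reflecting walls and a step initial profile the fraction in
#' the far chamber is the cosine-series solution of the 1-D diffusion equation;
#' the only free constant is `kappa`, the effective residence time per squared
#' channel width, so that `kappa * D` is the dimensionless diffusion number.
#'
#' @param kappa Channel constant in s m^-2; `kappa * D` is dimensionless.
#' @param size_range_id Instrument size-range identifier (2, 3 or 4).
#' @param temperature Absolute temperature in K.
#' @param viscosity Solvent viscosity in Pa s.
#' @param n_terms Truncation order of the odd-cosine series (odd terms up to
#'   `n_terms` are summed).
#' @param r_min,r_max Radii (nm) bounding the invertible range.
#' @return An object of class `mds_calibration`.
#' @seealso [calibrate_channel()], [diffused_fraction()], [invert_fraction()]
#' @export
channel_calibration <- function(kappa,
                                size_range_id = 3L,
                                temperature = 298.15,
                                viscosity = 8.9e-4,
                                n_terms = 51L,
                                r_min = 0.5,
                                r_max = 50) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop_oligochap("`kappa` must be a single positive number.",
                   "oligochap_parameter_error")
  }
  if (!size_range_id %in% 2:4) {
    stop_oligochap("`size_range_id` must be 2, 3 or 4.",
                   "oligochap_parameter_error")
  }
  structure(
    list(kappa = kappa, size_range_id = as.integer(size_range_id),
         temperature = temperature, viscosity = viscosity,
         n_terms = as.integer(n_terms), r_min = r_min, r_max = r_max),
    class = "mds_calibration"
  )
}

#' @export
print.mds_calibration <- function(x, ...) {
  cat("<mds_calibration>\n")
  cat(sprintf("  size range     : %d\n", x$size_range_id))
  cat(sprintf("  kappa          : %.6g s/m^2\n", x$kappa))
  cat(sprintf("  T, viscosity   : %.2f K, %.3g Pa s\n", x$temperature, x$viscosity))
  cat(sprintf("  invertible R_h : [%.2g, %.2g] nm\n", x$r_min, x$r_max))
  invisible(x)
}

#' Diffused fraction for a given diffusivity
#'
#' Fraction of labelled material found in the chamber opposite the sample
#' inlet after transit, for the step-profile two-stream channel:
#' \deqn{f = 1/2 - (4/\pi^2) \sum_{k\ \mathrm{odd}} k^{-2}
#'       \exp(-k^2 \pi^2 \kappa D / 4).}
#' `f` runs from 0 (no diffusion) to 0.5 (complete equilibration) and is
#' strictly decreasing in particle size.
#'
#' @param D Diffusion coefficient(s), m^2 s^-1.
#' @param cal An [channel_calibration()] object.
#' @return Diffused fraction(s) in (0, 0.5).
#' @export
diffused_fraction <- function(D, cal = default_calibration()) {
  stopifnot(inherits(cal, "mds_calibration"))
  if (any(D <= 0)) {
    stop_oligochap("`D` must be positive.", "oligochap_parameter_error")
  }
  k <- seq(1L, cal$n_terms, by = 2L)
  tau <- cal$kappa * D # dimensionless diffusion number
  vapply(tau, function(ti) {
    if (ti < 0.01) {
      # short-time regime: the cosine series needs ever more terms as tau -> 0,
      # while the interface is still far from the walls, so the semi-infinite
      # (image) solution is exact to ~exp(-1/(16 tau)): mass crossed per unit
      # width sqrt(D t / pi) over the half-stream mass 1/2, with t = tau/4
      2 * sqrt(ti / (4 * pi))
    } else {
      0.5 - (4 / pi^2) * sum(exp(-k^2 * pi^2 * ti / 4) / k^2)
    }
  }, numeric(1))
}

# forward map R_h [nm] -> diffused fraction under a calibration
forward_fraction <- function(r_h, cal) {
  diffused_fraction(stokes_einstein_D(r_h, cal$temperature, cal$viscosity), cal)
}

#' Calibrate the channel constant from anchor pairs
#'
#' Solves for `kappa` so that the forward model reproduces one or more known
#' (radius, diffused fraction) pairs in least squares; with a single anchor
#' this is an exact 1-D root find on the strictly monotone forward map.
#'
#' @param anchors A data frame with columns `r_h` (nm) and `f` (diffused
#'   fraction in (0, 0.5)).
#' @param temperature,viscosity,size_range_id,n_terms,r_min,r_max Passed to
#'   [channel_calibration()].
#' @return An `mds_calibration` object.
#' @examples
#' # ship calibration: free 3 nm chaperone monomer reads f = 0.42
#' cal <- calibrate_channel(data.frame(r_h = 3, f = 0.42))
#' diffused_fraction(stokes_einstein_D(3), cal)
#' @export
calibrate_channel <- function(anchors,
                              temperature = 298.15,
                              viscosity = 8.9e-4,
                              size_range_id = 3L,
                              n_terms = 51L,
                              r_min = 0.5,
                              r_max = 50) {
  anchors <- as_tibble(anchors)
  if (nrow(anchors) < 1L || !all(c("r_h", "f") %in% names(anchors))) {
    stop_oligochap("`anchors` needs at least one row with columns r_h and f.",
                   "oligochap_calibration_error")
  }
  if (any(anchors$f <= 0 | anchors$f >= 0.5)) {
    stop_oligochap("Anchor diffused fractions must lie strictly in (0, 0.5).",
                   "oligochap_calibration_error")
  }
  D <- stokes_einstein_D(anchors$r_h, temperature, viscosity)
  make_cal <- function(kappa) {
    channel_calibration(kappa, size_range_id, temperature, viscosity,
                        n_terms, r_min, r_max)
  }
  obj <- function(log_kappa) {
    f_hat <- diffused_fraction(D, make_cal(exp(log_kappa)))
    sum((f_hat - anchors$f)^2)
  }
  if (nrow(anchors) == 1L) {
    root <- uniroot(
      function(lk) diffused_fraction(D, make_cal(exp(lk))) - anchors$f,
      lower = log(1e4), upper = log(1e14), tol = 1e-12
    )
    return(make_cal(exp(root$root)))
  }
  opt <- optimize(obj, interval = c(log(1e4), log(1e14)), tol = 1e-12)
  make_cal(exp(opt$minimum))
}

# cached default calibration anchored at (3 nm, 0.42)
.cal_cache <- new.env(parent = emptyenv())

#' Default shipped calibration
#'
#' Size range 3 anchored so that a 3 nm species reads a diffused fraction of
#' 0.42 in water at 298.15 K. Ranges 2 and 4 are nominal fast/slow variants of
#' the same channel (twice and half the residence constant), spanning roughly
#' the 2-17 nm sensitivity window of the instrument ranges used.
#'
#' @param size_range_id 2, 3 or 4.
#' @return An `mds_calibration` object.
#' @export
default_calibration <- function(size_range_id = 3L) {
  key <- as.character(size_range_id)
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  base <- calibrate_channel(data.frame(r_h = 3, f = 0.42))
  scale <- c(`2` = 2, `3` = 1, `4` = 0.5)[[key]]
  cal <- channel_calibration(base$kappa * scale, size_range_id,
                             base$temperature, base$viscosity, base$n_terms,
                             base$r_min, base$r_max)
  .cal_cache[[key]] <- cal
  cal
}

#' Apparent average hydrodynamic radius from a diffused fraction
#'
#' Inverts the strictly monotone forward map by bisection. A fraction outside
#' the range attainable within `[cal$r_min, cal$r_max]` signals an
#' out-of-range condition (the instrument's "size determination not possible"
#' state, seen e.g. for samples where fibrils clog the channel).
#'
#' @param f Diffused fraction(s).
#' @param cal An `mds_calibration` object.
#' @param tol Radius tolerance in nm for the bisection.
#' @return Apparent radius/radii in nm.
#' @export
invert_fraction <- function(f, cal = default_calibration(), tol = 1e-4) {
  stopifnot(inherits(cal, "mds_calibration"))
  f_min <- forward_fraction(cal$r_max, cal) # largest particle -> smallest f
  f_max <- forward_fraction(cal$r_min, cal)
  vapply(f, function(fi) {
    if (!is.finite(fi) || fi < f_min || fi > f_max) {
      stop_oligochap(
        sprintf(paste0("Diffused fraction %.4g outside invertible range ",
                       "[%.4g, %.4g] for R_h in [%g, %g] nm: ",
                       "size determination not possible."),
                fi, f_min, f_max, cal$r_min, cal$r_max),
        "oligochap_out_of_range_error"
      )
    }
    uniroot(function(r) forward_fraction(r, cal) - fi,
            lower = cal$r_min, upper = cal$r_max, tol = tol)$root
  }, numeric(1))
}

#' Observed diffused fraction of a labelled species mixture
#'
#' The instrument reads one intensity split per sample, so a mixture of
#' labelled species contributes linearly in label fraction:
#' \eqn{f_{obs} = \sum_i w_i f(R_{h,i})}. Averaging happens in fraction space,
#' which biases the apparent radius of a mixture below the arithmetic mean of
#' the component radii.
#'
#' @param mixture Data frame with columns `r_h` (nm) and `label_fraction`
#'   (non-negative, summing to 1).
#' @param cal An `mds_calibration` object.
#' @return Single observed diffused fraction.
#' @export
mixture_fraction <- function(mixture, cal = default_calibration()) {
  mixture <- as_tibble(mixture)
  if (!all(c("r_h", "label_fraction") %in% names(mixture))) {
    stop_oligochap("`mixture` needs columns r_h and label_fraction.",
                   "oligochap_mixture_error")
  }
  w <- mixture$label_fraction
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_oligochap("Label fractions must be >= 0 and sum to 1.",
                   "oligochap_mixture_error")
  }
  sum(w * forward_fraction(mixture$r_h, cal))
}

#' Per-replicate sizing from two-chamber intensities
#'
#' Converts raw two-chamber intensity pairs (or ready diffused fractions) to
#' apparent hydrodynamic radii. Fractions marginally above the physical 0.5
#' equilibration limit (measurement noise) are clipped to 0.4999 with a
#' warning; negative intensities are rejected.
#'
#' @param measurements Tibble with `replicate_id` and either
#'   `diffused_fraction` or both `intensity_inlet` and `intensity_diffused`.
#' @param cal An `mds_calibration` object.
#' @return The input tibble with columns `diffused_fraction` and
#'   `r_h_apparent` (nm) filled in.
#' @export
size_measurements <- function(measurements, cal = default_calibration()) {
  m <- as_tibble(measurements)
  if (!"diffused_fraction" %in% names(m)) {
    if (!all(c("intensity_inlet", "intensity_diffused") %in% names(m))) {
      stop_oligochap(
        "Need `diffused_fraction` or intensity_inlet/intensity_diffused.",
        "oligochap_parse_error")
    }
    if (any(m$intensity_inlet < 0 | m$intensity_diffused < 0)) {
      stop_oligochap("Negative intensities are not physical.",
                     "oligochap_parse_error")
    }
    m$diffused_fraction <-
      m$intensity_diffused / (m$intensity_inlet + m$intensity_diffused)
  }
  over <- m$diffused_fraction > 0.5
  if (any(over)) {
    warn(sprintf("%d diffused fraction(s) > 0.5 clipped to 0.4999 (QC).",
                 sum(over)))
    m$diffused_fraction[over] <- 0.4999
  }
  m$r_h_apparent <- invert_fraction(m$diffused_fraction, cal)
  m
}
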