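#' Bound complex concentration under independent binding with depletion
#'
#' Exact solution of the mass-action equilibrium
#' \eqn{(C - B)(S - B) = K_D B} for the complex concentration B when neither
#' chaperone (total C) nor binding sites (total S) are in large excess:
#' \deqn{B = \frac{(C + S + K_D) - \sqrt{(C + S + K_D)^2 - 4 C S}}{2},}
#' the physically valid root with \eqn{0 \le B \le \min(C, S)}.
#'
#' @param C_total Total chaperone concentration, nM.
#' @param S_total Total binding-site concentration, nM.
#' @param K_D Equilibrium dissociation constant, nM.
#' @return Bound concentration B in nM (vectorised).
#' @examples
#' bound_concentration(12.5, 12.5, 12.5)
#' bound_concentration(12.5, 400, 0) # stoichiometric limit: min(C, S)
#' @export
bound_concentration <- function(C_total, S_total, K_D) {
  if (any(C_total < 0) || any(S_total < 0) || any(K_D < 0)) {
    stop_oligochap("Concentrations and K_D must be >= 0.",
                   "oligochap_parameter_error")
  }
  b <- C_total + S_total + K_D
  disc <- pmax(b^2 - 4 * C_total * S_total, 0)
  # subtraction-safe form: 2CS / (b + sqrt(disc)) avoids cancellation
  out <- 2 * C_total * S_total / (b + sqrt(disc))
  ifelse(b == 0, 0, out)
}

#' Binding parameters of the supernatant-titration isotherm
#'
#' @param K_D Dissociation constant, nM.
#' @param C_s Total binding-site concentration in undiluted supernatant, nM.
#' @param f_0 Diffused fraction of free chaperone.
#' @param f_b Diffused fraction of bound chaperone (f_b < f_0: complexes are
#'   larger, so diffuse less).
#' @param C_jb6 Total labelled chaperone concentration, nM.
#' @return List of class `binding_parameters`.
#' @export
binding_parameters <- function(K_D, C_s, f_0 = 0.42, f_b = 0.18,
                               C_jb6 = 12.5) {
  if (K_D < 0 || C_s < 0 || C_jb6 <= 0) {
    stop_oligochap("K_D, C_s must be >= 0 and C_jb6 > 0.",
                   "oligochap_parameter_error")
  }
  if (!(f_b > 0 && f_b < f_0 && f_0 < 0.5)) {
    stop_oligochap("Require 0 < f_b < f_0 < 0.5.", "oligochap_parameter_error")
  }
  structure(list(K_D = K_D, C_s = C_s, f_0 = f_0, f_b = f_b, C_jb6 = C_jb6),
            class = "binding_parameters")
}

#' Model diffused fraction versus supernatant volume fraction
#'
#' The observed diffused fraction of labelled chaperone mixed with a volume
#' fraction X of oligomer-containing supernatant is the bound-fraction-weighted
#' combination of the free and bound plateaus:
#' \deqn{f(X) = f_0 + (f_b - f_0)\, B(C_{JB6},\, X C_s,\, K_D) / C_{JB6},}
#' with B the depletion-corrected bound concentration. Strictly decreasing in
#' X when f_b < f_0.
#'
#' @param X Supernatant volume fraction(s) in [0, 1].
#' @param p A [binding_parameters()] object.
#' @return Diffused fraction(s).
#' @export
model_fraction <- function(X, p) {
  stopifnot(inherits(p, "binding_parameters"))
  if (any(X < 0)) {
    stop_oligochap("`X` must be >= 0.", "oligochap_parameter_error")
  }
  B <- bound_concentration(p$C_jb6, X * p$C_s, p$K_D)
  p$f_0 + (p$f_b - p$f_0) * B / p$C_jb6
}

# core weighted least-squares engine shared by fit and profile;
# free = character vector among c("K_D","C_s","f_0","f_b")
.binding_ess_fit <- function(points, C_jb6, fixed = list(), starts) {
  nms <- c("K_D", "C_s", "f_0", "f_b")
  free <- setdiff(nms, names(fixed))
  # optimise on transformed scale: log for K_D/C_s, logit-like for fractions
  to_par <- function(v, nm) if (nm %in% c("K_D", "C_s")) log(pmax(v, 1e-12)) else stats::qlogis(v / 0.5)
  from_par <- function(u, nm) if (nm %in% c("K_D", "C_s")) exp(u) else 0.5 * stats::plogis(u)
  model_f <- function(pvals) {
    all_vals <- modifyList(pvals, fixed)
    p <- structure(c(all_vals[nms], list(C_jb6 = C_jb6)),
                   class = "binding_parameters")
    model_fraction(points$X, p)
  }
  obj <- function(u) {
    vals <- fixed
    for (i in seq_along(free)) vals[[free[i]]] <- from_par(u[i], free[i])
    if (vals$f_b >= vals$f_0) return(1e6)
    sum((points$f - model_f(vals))^2)
  }
  # Levenberg-Marquardt polish of a simplex solution: the simplex is robust
  # across the flat low-K_D valley, LM converges tightly near an optimum
  polish <- function(vals) {
    lower <- vapply(free, function(nm)
      if (nm %in% c("K_D", "C_s")) 0 else 1e-6, numeric(1))
    upper <- vapply(free, function(nm)
      if (nm %in% c("K_D", "C_s")) Inf else 0.5 - 1e-6, numeric(1))
    res <- minpack.lm::nls.lm(
      par = vals[free],
      lower = lower, upper = upper,
      fn = function(par) points$f - model_f(setNames(as.list(par), free)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    cand <- modifyList(vals, setNames(as.list(coef(res)), free))
    list(pars = cand, ess = sum(res$fvec^2))
  }
  best <- NULL
  for (st in starts) {
    par0 <- vapply(free, function(nm) to_par(st[[nm]], nm), numeric(1))
    opt <- try(optim(par0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    vals <- fixed
    for (i in seq_along(free)) vals[[free[i]]] <- from_par(opt$par[i], free[i])
    cand <- list(pars = vals, ess = opt$value)
    pol <- try(polish(vals), silent = TRUE)
    if (!inherits(pol, "try-error") && is.finite(pol$ess) &&
        pol$ess <= cand$ess && pol$pars$f_b < pol$pars$f_0) {
      cand <- pol
    }
    if (is.null(best) || cand$ess < best$ess) best <- cand
  }
  if (is.null(best)) {
    stop_oligochap("Binding fit failed from all starts.",
                   "oligochap_fit_error")
  }
  list(pars = best$pars[nms], ess = best$ess)
}

.default_binding_starts <- function(points, C_jb6) {
  f_hi <- max(points$f); f_lo <- min(points$f)
  X_max <- max(points$X)
  lapply(c(0.1, 1, 10, 100), function(kd) {
    list(K_D = kd, C_s = max(C_jb6 / max(X_max, 1e-3), 1),
         f_0 = min(f_hi, 0.49), f_b = max(f_lo, 1e-3))
  })
}

#' Fit the independent-binding isotherm to a supernatant titration
#'
#' Nonlinear least squares of [model_fraction()] over (K_D, C_s, f_0, f_b) on
#' raw diffused fractions, with multistart over log-spaced K_D initialisations
#' (0.1, 1, 10, 100 nM) because the error surface is nearly flat below the
#' true K_D. Optional bootstrap standard errors resample replicates within
#' each X.
#'
#' @param points Tibble with columns `X` (volume fraction) and `f` (diffused
#'   fraction); an optional `replicate_id` supports the bootstrap.
#' @param C_jb6 Total labelled chaperone concentration, nM.
#' @param n_boot Number of bootstrap resamples for standard errors (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `binding_fit`: `parameters`
#'   ([binding_parameters()]), `ess`, `n_points`, and if bootstrapped a
#'   `boot_se` named vector and `boot` tibble of resampled estimates.
#' @export
fit_binding <- function(points, C_jb6 = 12.5, n_boot = 0, seed = 1L) {
  points <- as_tibble(points)
  if (!all(c("X", "f") %in% names(points))) {
    stop_oligochap("`points` needs columns X and f.", "oligochap_parse_error")
  }
  nX <- length(unique(points$X))
  if (nX < 4L) {
    stop_oligochap("Titration design too degenerate to identify the isotherm (need >= 4 distinct X).",
                   "oligochap_fit_error")
  }
  if (nX < 6L) {
    warn("Fewer than 6 distinct X values: plateaus may be poorly constrained.")
  }
  fit1 <- function(pts) {
    .binding_ess_fit(pts, C_jb6, fixed = list(),
                     starts = .default_binding_starts(pts, C_jb6))
  }
  res <- fit1(points)
  out <- list(
    parameters = binding_parameters(res$pars$K_D, res$pars$C_s,
                                    res$pars$f_0, res$pars$f_b, C_jb6),
    ess = res$ess, n_points = nrow(points)
  )
  if (n_boot > 0) {
    set.seed(seed)
    boots <- purrr::map_dfr(seq_len(n_boot), function(b) {
      resampled <- points |>
        dplyr::group_by(.data$X) |>
        dplyr::slice_sample(prop = 1, replace = TRUE) |>
        dplyr::ungroup()
      r <- try(fit1(resampled), silent = TRUE)
      if (inherits(r, "try-error")) return(NULL)
      tibble(K_D = r$pars$K_D, C_s = r$pars$C_s,
             f_0 = r$pars$f_0, f_b = r$pars$f_b)
    })
    out$boot <- boots
    out$boot_se <- vapply(boots, stats::sd, numeric(1))
  }
  structure(out, class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  p <- x$parameters
  cat("<binding_fit>\n")
  cat(sprintf("  K_D = %.4g nM, C_s = %.4g nM, f_0 = %.4g, f_b = %.4g (C_jb6 = %g nM)\n",
              p$K_D, p$C_s, p$f_0, p$f_b, p$C_jb6))
  cat(sprintf("  e.s.s. = %.4g over %d points\n", x$ess, x$n_points))
  cat("  note: C_s is an upper limit to the oligomer concentration in the\n")
  cat("  supernatant, in the limit of one chaperone-binding site per oligomer.\n")
  invisible(x)
}

#' Error-square-sum profile of the dissociation constant
#'
#' For each K_D on a grid, re-optimises the remaining parameters
#' (C_s, f_0, f_b) and reports the ratio of the constrained error square sum
#' to the unconstrained minimum. The interval where the ratio stays at or
#' below `threshold` is the profile confidence region; for a titration that
#' only bounds the affinity from above, the profile is flat at small K_D and
#' rises beyond the identifiable scale.
#'
#' @param points As in [fit_binding()].
#' @param fit A `binding_fit` for these points (refit if omitted).
#' @param kd_grid K_D grid in nM (default 25 log-spaced values, 0.01-1000).
#' @param C_jb6 Total chaperone, nM.
#' @param threshold e.s.s. ratio defining the reported interval.
#' @return Object of class `ess_profile`: tibble `profile` (columns `K_D`,
#'   `ess`, `ratio`, `ok`), the `threshold`, and `interval` (range of grid
#'   K_D with ratio <= threshold).
#' @export
ess_profile <- function(points, fit = NULL,
                        kd_grid = 10^seq(-2, 3, length.out = 25),
                        C_jb6 = 12.5, threshold = 1.25) {
  points <- as_tibble(points)
  if (is.null(fit)) fit <- fit_binding(points, C_jb6)
  p <- fit$parameters
  rows <- purrr::map_dfr(kd_grid, function(kd) {
    st <- list(list(K_D = kd, C_s = p$C_s, f_0 = p$f_0, f_b = p$f_b))
    r <- try(.binding_ess_fit(points, C_jb6, fixed = list(K_D = kd), starts = st),
             silent = TRUE)
    if (inherits(r, "try-error")) {
      tibble(K_D = kd, ess = NA_real_, ok = FALSE)
    } else {
      tibble(K_D = kd, ess = r$ess, ok = TRUE)
    }
  })
  rows$ratio <- rows$ess / fit$ess
  inside <- rows$K_D[which(rows$ok & rows$ratio <= threshold)]
  structure(
    list(profile = rows, threshold = threshold, best = fit,
         interval = if (length(inside)) range(inside) else c(NA_real_, NA_real_)),
    class = "ess_profile"
  )
}

#' @export
print.ess_profile <- function(x, ...) {
  cat("<ess_profile>\n")
  cat(sprintf("  best K_D = %.4g nM (ess = %.4g)\n",
              x$best$parameters$K_D, x$best$ess))
  cat(sprintf("  ratio <= %.3g for K_D in [%.4g, %.4g] nM (grid range)\n",
              x$threshold, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Apparent radius along a chaperone titration at fixed supernatant fraction
#'
#' Emulates titrating labelled chaperone (concentration series `c_jb6`) into a
#' fixed supernatant dilution: at each total chaperone concentration the bound
#' fraction follows from the depletion isotherm, the free/bound mixture is
#' pushed through the forward sizing model, and the observed fraction is
#' inverted to an apparent average hydrodynamic radius. At low chaperone all
#' label is bound and the apparent radius approaches the co-oligomer radius;
#' in excess chaperone it falls towards the free-monomer radius.
#'
#' @param c_jb6 Total chaperone concentrations, nM.
#' @param X_fixed Supernatant volume fraction (e.g. 0.025 for 2.5 percent).
#' @param p A [binding_parameters()] object (f_0/f_b unused here).
#' @param r_free,r_bound Hydrodynamic radii (nm) of free and bound chaperone.
#' @param cal An `mds_calibration`.
#' @return Tibble with `c_jb6`, `bound_fraction`, `f_obs`, `r_h_apparent`.
#' @export
chaperone_titration_curve <- function(c_jb6, X_fixed, p,
                                      r_free = 3, r_bound = 11,
                                      cal = default_calibration()) {
  stopifnot(inherits(p, "binding_parameters"))
  if (r_bound <= r_free) {
    stop_oligochap("`r_bound` must exceed `r_free`.", "oligochap_parameter_error")
  }
  S <- X_fixed * p$C_s
  purrr::map_dfr(c_jb6, function(C) {
    B <- bound_concentration(C, S, p$K_D)
    w_bound <- B / C
    f_obs <- mixture_fraction(
      tibble(r_h = c(r_bound, r_free),
             label_fraction = c(w_bound, 1 - w_bound)), cal)
    tibble(c_jb6 = C, bound_fraction = w_bound, f_obs = f_obs,
           r_h_apparent = invert_fraction(f_obs, cal))
  })
}
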