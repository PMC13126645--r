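#' Fit a single-exponential dissociation decay
#'
#' Fits \eqn{R_h(t) = a e^{-k_{off} t} + c} to an oligomer-size incubation
#' series by constrained nonlinear least squares. Replicate-level points are
#' used when present; if the series carries per-point standard deviations and
#' a single value per timepoint, weights 1/sd^2 are applied. Starting values:
#' a = first minus last radius, c = last radius, k_off = 1/time span.
#'
#' @param series Tibble with columns `t` (h) and `r_h` (nm); optional `sd`
#'   (replicate STD, nm) for weighting of mean-level data.
#' @return Object of class `decay_fit` with elements `a`, `k_off`, `c`,
#'   `ess`, `n_points`, `unidentifiable` (TRUE when the series is flat so
#'   k_off carries no information) and the input `series`.
#' @examples
#' s <- tibble::tibble(t = seq(0, 2, 0.25), r_h = 7 * exp(-3.5 * t) + 3)
#' fit_decay(s)
#' @export
fit_decay <- function(series) {
  series <- as_tibble(series)
  if (!all(c("t", "r_h") %in% names(series))) {
    stop_oligochap("`series` needs columns t and r_h.", "oligochap_parse_error")
  }
  if (length(unique(series$t)) < 4L) {
    stop_oligochap("Need at least 4 distinct timepoints.",
                   "oligochap_fit_error")
  }
  ord <- order(series$t)
  series <- series[ord, ]
  has_reps <- anyDuplicated(series$t) > 0
  w <- if (!has_reps && "sd" %in% names(series) && all(series$sd > 0)) {
    1 / series$sd^2
  } else {
    rep(1, nrow(series))
  }
  r_first <- mean(series$r_h[series$t == min(series$t)])
  r_last <- mean(series$r_h[series$t == max(series$t)])
  a0 <- max(r_first - r_last, 1e-3)
  c0 <- max(r_last, 1e-3)
  k0 <- 1 / diff(range(series$t))
  flat <- {
    # flat series: amplitude indistinguishable from scatter
    s <- stats::sd(series$r_h)
    abs(r_first - r_last) < max(2 * s / sqrt(nrow(series)), 1e-12) &&
      s < 0.05 * mean(series$r_h)
  }
  if (flat) {
    warn("Series is essentially flat: amplitude ~ 0, k_off is unidentifiable.")
    cbar <- sum(w * series$r_h) / sum(w)
    return(structure(
      list(a = 0, k_off = 0, c = cbar,
           ess = sum((series$r_h - cbar)^2), n_points = nrow(series),
           unidentifiable = TRUE, series = series),
      class = "decay_fit"))
  }
  fit <- try(minpack.lm::nlsLM(
    r_h ~ a * exp(-k_off * t) + cc,
    data = series,
    start = list(a = a0, k_off = k0, cc = c0),
    lower = c(0, 0, 1e-6),
    upper = c(Inf, Inf, r_first + 1e-9),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # near-flat series defeat the Jacobian; if a constant describes the data
    # as well as anything, report it with the unidentifiable flag
    cbar <- sum(w * series$r_h) / sum(w)
    if (stats::sd(series$r_h) < 0.1 * cbar) {
      warn("Series is essentially flat: amplitude ~ 0, k_off is unidentifiable.")
      return(structure(
        list(a = 0, k_off = 0, c = cbar,
             ess = sum((series$r_h - cbar)^2), n_points = nrow(series),
             unidentifiable = TRUE, series = series),
        class = "decay_fit"))
    }
    stop_oligochap("Exponential decay fit did not converge.",
                   "oligochap_fit_error")
  }
  cf <- coef(fit)
  unident <- cf[["a"]] < 1e-6
  if (unident) {
    warn("Series is essentially flat: amplitude ~ 0, k_off is unidentifiable.")
  }
  structure(
    list(a = cf[["a"]], k_off = cf[["k_off"]], c = cf[["cc"]],
         ess = sum(stats::resid(fit)^2), n_points = nrow(series),
         unidentifiable = unident, series = series),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>\n")
  cat(sprintf("  r_h(t) = %.4g * exp(-%.4g t) + %.4g  (nm, h)\n",
              x$a, x$k_off, x$c))
  cat(sprintf("  e.s.s. = %.4g over %d points%s\n", x$ess, x$n_points,
              if (x$unidentifiable) "  [k_off unidentifiable]" else ""))
  invisible(x)
}

#' Compare two dissociation rate constants
#'
#' Point estimate and bootstrap percentile confidence interval for the ratio
#' k_off(a) / k_off(b) of two fitted decays. Each bootstrap draw resamples
#' replicates within every timepoint of both series independently and refits
#' both decays. Note the chaperone-containing samples are diluted at time
#' zero by the chaperone addition, which raises their net dissociation rate;
#' no correction is applied for this, so the reported stabilisation is
#' conservative.
#'
#' @param fit_a,fit_b `decay_fit` objects (numerator/denominator).
#' @param n_boot Number of bootstrap resamples (0 = point estimate only).
#' @param level Confidence level for the percentile interval.
#' @param seed RNG seed.
#' @return Object of class `rate_comparison`: `ratio`, `ci` (or NULL),
#'   `n_boot`, `boot` (vector of resampled ratios).
#' @export
compare_rates <- function(fit_a, fit_b, n_boot = 2000, level = 0.95,
                          seed = 1L) {
  stopifnot(inherits(fit_a, "decay_fit"), inherits(fit_b, "decay_fit"))
  if (fit_a$unidentifiable || fit_b$unidentifiable) {
    stop_oligochap(
      "One of the fits has no identifiable rate (flat series); a rate ratio would be meaningless.",
      "oligochap_fit_error")
  }
  ratio <- fit_a$k_off / fit_b$k_off
  if (n_boot <= 0) {
    return(structure(list(ratio = ratio, ci = NULL, n_boot = 0L,
                          boot = numeric(0), level = level),
                     class = "rate_comparison"))
  }
  resample <- function(series) {
    series |>
      dplyr::group_by(.data$t) |>
      dplyr::slice_sample(prop = 1, replace = TRUE) |>
      dplyr::ungroup()
  }
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    ra <- try(fit_decay(resample(fit_a$series)), silent = TRUE)
    rb <- try(fit_decay(resample(fit_b$series)), silent = TRUE)
    if (inherits(ra, "try-error") || inherits(rb, "try-error")) return(NA_real_)
    ra$k_off / rb$k_off
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  ci <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(list(ratio = ratio, ci = ci, n_boot = length(boot), boot = boot,
                 level = level),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("<rate_comparison>\n")
  cat(sprintf("  k_off ratio = %.4g", x$ratio))
  if (!is.null(x$ci)) {
    cat(sprintf("  (%.0f%% bootstrap CI %.4g-%.4g, %d resamples)",
                100 * x$level, x$ci[1], x$ci[2], x$n_boot))
  }
  cat("\n")
  invisible(x)
}
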