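#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline labs
#'   scale_x_log10 scale_y_log10 autoplot theme_minimal
#' @export
ggplot2::autoplot

#' Plot kinetic traces
#'
#' @param traces Long tibble of traces (`t`, `signal`, `well_id`, `jb6_conc`).
#' @param median_only Plot per-condition medians only.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(traces, median_only = FALSE) {
  med <- median_traces(traces)
  p <- ggplot(med, aes(.data$t, .data$signal,
                       colour = factor(.data$jb6_conc))) +
    geom_line(linewidth = 0.8)
  if (!median_only) {
    p <- p + geom_point(data = traces, alpha = 0.15, size = 0.4)
  }
  p + labs(x = "time (h)", y = "ThT fluorescence (a.u.)",
           colour = "chaperone (nM)") +
    theme_minimal()
}

#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, points = NULL, ...) {
  p <- object$parameters
  X_line <- 10^seq(-4, 0, length.out = 200)
  curve <- tibble(X = X_line, f = model_fraction(X_line, p))
  g <- ggplot(curve, aes(.data$X, .data$f)) +
    geom_line(colour = "steelblue") +
    scale_x_log10() +
    labs(x = "supernatant volume fraction X", y = "diffused fraction f",
         title = sprintf("Independent-binding fit: K_D = %.3g nM, C_s = %.3g nM",
                         p$K_D, p$C_s)) +
    theme_minimal()
  if (!is.null(points)) g <- g + geom_point(data = points, alpha = 0.6)
  g
}

#' @method autoplot ess_profile
#' @export
autoplot.ess_profile <- function(object, ...) {
  ggplot(dplyr::filter(object$profile, .data$ok),
         aes(.data$K_D, .data$ratio)) +
    geom_line() + geom_point(size = 0.8) +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    scale_x_log10() +
    labs(x = "K_D (nM)", y = "e.s.s. ratio",
         title = "Profile of the error square sum over fixed K_D") +
    theme_minimal()
}

#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  s <- object$series
  t_line <- seq(min(s$t), max(s$t), length.out = 200)
  fit_line <- tibble(t = t_line,
                     r_h = object$a * exp(-object$k_off * t_line) + object$c)
  ggplot(s, aes(.data$t, .data$r_h)) +
    geom_point(alpha = 0.6) +
    geom_line(data = fit_line, colour = "firebrick") +
    labs(x = "incubation time (h)", y = expression("<R"[h] * "> (nm)"),
         title = sprintf("k_off = %.3g 1/h", object$k_off)) +
    theme_minimal()
}

#' @method autoplot saxs_fit
#' @export
autoplot.saxs_fit <- function(object, curve = NULL, ...) {
  q_line <- 10^seq(-3.5, 0, length.out = 300)
  model <- tibble(
    q = q_line,
    I = composite_intensity(q_line, object$A, object$p, object$r_g,
                            object$concentration, object$contrast_scale,
                            object$bkg))
  g <- ggplot(model, aes(.data$q, .data$I)) +
    geom_line(colour = "goldenrod3") +
    scale_x_log10() + scale_y_log10() +
    labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
         title = sprintf("power law %.2f; coil r_g = %.2g nm, %.2g mM",
                         -object$p, object$r_g, object$concentration)) +
    theme_minimal()
  if (!is.null(curve)) g <- g + geom_point(data = curve, alpha = 0.3, size = 0.5)
  g
}

#' Plot an oligomer sizing time course
#'
#' @param timecourse Output of [generate_oligomer_timecourse()] (or any tibble
#'   with `t` and `r_h_apparent`).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse) {
  means <- timecourse |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(r_h = mean(.data$r_h_apparent), .groups = "drop")
  ggplot(timecourse, aes(.data$t, .data$r_h_apparent)) +
    geom_point(alpha = 0.3, size = 0.7) +
    geom_line(data = means, aes(y = .data$r_h), colour = "purple4") +
    labs(x = "withdrawal time (h)", y = expression("<R"[h] * "> (nm)")) +
    theme_minimal()
}
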