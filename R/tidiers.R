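#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One row per parameter with columns `term`, `estimate` and, when the
#'   fit was bootstrapped, `std.error`.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  p <- x$parameters
  out <- tibble(term = c("K_D", "C_s", "f_0", "f_b"),
                estimate = c(p$K_D, p$C_s, p$f_0, p$f_b))
  if (!is.null(x$boot_se)) out$std.error <- unname(x$boot_se[out$term])
  out
}

#' @rdname tidy.binding_fit
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(ess = x$ess, n_points = x$n_points, C_jb6 = x$parameters$C_jb6)
}

#' Tidy a dissociation decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`a`, `k_off`, `c`).
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("a", "k_off", "c"), estimate = c(x$a, x$k_off, x$c))
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(ess = x$ess, n_points = x$n_points,
         unidentifiable = x$unidentifiable)
}

#' Tidy a composite scattering fit
#'
#' @param x A `saxs_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @method tidy saxs_fit
#' @export
tidy.saxs_fit <- function(x, ...) {
  tibble(term = c("A", "p", "r_g", "concentration", "bkg"),
         estimate = c(x$A, x$p, x$r_g, x$concentration, x$bkg))
}

#' @rdname tidy.saxs_fit
#' @method glance saxs_fit
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble(ess = x$ess, q_lowmax = x$q_lowmax, q_highmin = x$q_highmin,
         refined = x$refined)
}

#' Tidy a hypothesis fit
#'
#' @param x A `hypothesis_fit`.
#' @param ... Unused.
#' @return Per-chaperone-concentration tibble of the free parameter and group
#'   error square sum.
#' @method tidy hypothesis_fit
#' @export
tidy.hypothesis_fit <- function(x, ...) {
  dplyr::mutate(x$groups, hypothesis = x$hypothesis, .before = 1)
}

#' @rdname tidy.hypothesis_fit
#' @method glance hypothesis_fit
#' @export
glance.hypothesis_fit <- function(x, ...) {
  tibble(hypothesis = x$hypothesis, ess = x$ess,
         k_plus = x$baseline$params$k_plus, k2 = x$baseline$params$k2)
}

#' Tidy an error-square-sum profile
#'
#' @param x An `ess_profile`.
#' @param ... Unused.
#' @return The grid tibble with columns `K_D`, `ess`, `ratio`, `ok`.
#' @method tidy ess_profile
#' @export
tidy.ess_profile <- function(x, ...) x$profile

#' @rdname tidy.ess_profile
#' @method glance ess_profile
#' @export
glance.ess_profile <- function(x, ...) {
  tibble(K_D_best = x$best$parameters$K_D, ess_best = x$best$ess,
         threshold = x$threshold,
         interval_lo = x$interval[1], interval_hi = x$interval[2])
}

#' Tidy a rate comparison
#'
#' @param x A `rate_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the ratio and its bootstrap interval.
#' @method tidy rate_comparison
#' @export
tidy.rate_comparison <- function(x, ...) {
  tibble(ratio = x$ratio,
         conf.low = if (is.null(x$ci)) NA_real_ else x$ci[1],
         conf.high = if (is.null(x$ci)) NA_real_ else x$ci[2],
         n_boot = x$n_boot)
}
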