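#' Median replicate trace per condition
#'
#' Collapses replicate wells to the per-timepoint median signal within each
#' chaperone concentration, the form in which seeded kinetic data are usually
#' summarised before global fitting.
#'
#' @param traces Tibble with columns `t` (h), `signal`, `well_id`, `jb6_conc`
#'   (nM); replicates of one condition must share a time grid.
#' @return Tibble with columns `jb6_conc`, `t`, `signal`.
#' @export
median_traces <- function(traces) {
  traces |>
    dplyr::group_by(.data$jb6_conc, .data$t) |>
    dplyr::summarise(signal = median(.data$signal), .groups = "drop") |>
    dplyr::arrange(.data$jb6_conc, .data$t)
}

# ess between a normalized data trace and the model mass fraction on its grid
.trace_ess <- function(params, t, y) {
  yhat <- try(simulated_mass_fraction(params, t), silent = TRUE)
  if (inherits(yhat, "try-error")) return(1e6)
  sum((y - yhat)^2)
}

# fit (k_plus, k2) to the normalized 0 nM median trace, all else fixed
.fit_baseline <- function(t, y, base) {
  t_half_data <- halftime(t, y)
  # initial guess: fixed shape ratio, overall rate scaled to the data halftime
  p0 <- rate_parameters(k_plus = 30, k2 = 3, n2 = base$n2, nc = base$nc,
                        m_total = base$m_total, m_eq = base$m_eq,
                        seed_mass = base$seed_mass,
                        seed_mean_size = base$seed_mean_size)
  t_probe <- seq(0, max(t) * 10, length.out = 400)
  th0 <- simulated_halftime(p0, t_probe)
  s <- th0 / t_half_data
  par0 <- log(c(30 * s, 3 * s))
  obj <- function(lp) {
    p <- p0
    p$k_plus <- exp(lp[1]); p$k2 <- exp(lp[2])
    .trace_ess(p, t, y)
  }
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  p <- p0
  p$k_plus <- exp(opt$par[1]); p$k2 <- exp(opt$par[2])
  list(params = p, ess = opt$value)
}

#' Global fit of one chaperone-inhibition hypothesis
#'
#' Fits seeded kinetic traces at several chaperone concentrations under one of
#' three mechanistic hypotheses for the inhibition: the chaperone reduces the
#' elongation rate (`reduce_k_plus`), reduces the secondary nucleation rate
#' (`reduce_k2`), or inactivates the added seeds (`inactivate_seeds`). Shared
#' parameters (`k_plus`, `k2`) are estimated from the chaperone-free group,
#' then a single free parameter per chaperone concentration - the rate scale
#' factor or the active seed fraction - is profiled by 1-D optimisation on the
#' normalized median trace of that group. The total error square sum across
#' groups ranks the hypotheses.
#'
#' @param traces Tibble with columns `t`, `signal`, `well_id`, `jb6_conc` (nM);
#'   must contain a 0 nM group.
#' @param hypothesis One of `"reduce_k_plus"`, `"reduce_k2"`,
#'   `"inactivate_seeds"`.
#' @param base Named list of fixed structural parameters (`n2`, `nc`,
#'   `m_total`, `m_eq`, `seed_mass`, `seed_mean_size`); defaults match the
#'   5 mM / 0.7 percent-seed experiment.
#' @param baseline Optional precomputed baseline fit (as returned in
#'   `$baseline`), reused when ranking several hypotheses on the same data.
#' @return Object of class `hypothesis_fit`: list with `hypothesis`,
#'   `baseline` (params + ess), `groups` (tibble: jb6_conc, free parameter
#'   value, ess, t_half), and `ess` (total, including the 0 nM group).
#' @export
fit_hypothesis <- function(traces,
                           hypothesis = c("reduce_k_plus", "reduce_k2",
                                          "inactivate_seeds"),
                           base = list(n2 = 2, nc = 2, m_total = 5,
                                       m_eq = 3.5, seed_mass = 0.035,
                                       seed_mean_size = 500),
                           baseline = NULL) {
  hypothesis <- match.arg(hypothesis)
  med <- median_traces(traces)
  if (!0 %in% med$jb6_conc) {
    stop_oligochap("A 0 nM chaperone group is required to anchor shared parameters.",
                   "oligochap_fit_error")
  }
  norm_groups <- med |>
    dplyr::group_by(.data$jb6_conc) |>
    dplyr::group_map(function(g, key) {
      list(jb6 = key$jb6_conc, t = g$t, y = normalize_trace(g$signal))
    })
  g0 <- norm_groups[[which(vapply(norm_groups, function(g) g$jb6, 0) == 0)]]
  if (is.null(baseline)) baseline <- .fit_baseline(g0$t, g0$y, base)
  p_shared <- baseline$params

  fit_group <- function(g) {
    with_theta <- function(theta) {
      p <- p_shared
      switch(hypothesis,
        reduce_k_plus    = { p$k_plus <- theta * p_shared$k_plus },
        reduce_k2        = { p$k2 <- theta * p_shared$k2 },
        inactivate_seeds = { p$active_seed_fraction <- theta })
      p
    }
    opt <- optimize(function(lt) .trace_ess(with_theta(exp(lt)), g$t, g$y),
                    interval = c(log(1e-5), 0), tol = 1e-8)
    theta <- exp(opt$minimum)
    tibble(jb6_conc = g$jb6, theta = theta, ess = opt$objective,
           t_half = tryCatch(halftime(g$t, g$y), error = function(e) NA_real_))
  }
  other <- purrr::keep(norm_groups, function(g) g$jb6 > 0)
  groups <- if (length(other) == 0L) {
    tibble(jb6_conc = numeric(), theta = numeric(), ess = numeric(),
           t_half = numeric())
  } else {
    purrr::map_dfr(other, fit_group)
  }
  total_ess <- baseline$ess + sum(groups$ess)
  if (!is.finite(total_ess)) {
    stop_oligochap("Hypothesis fit did not converge.", "oligochap_fit_error",
                   best = list(baseline = baseline, groups = groups))
  }
  structure(
    list(hypothesis = hypothesis, baseline = baseline, groups = groups,
         ess = total_ess),
    class = "hypothesis_fit"
  )
}

#' @export
print.hypothesis_fit <- function(x, ...) {
  cat(sprintf("<hypothesis_fit: %s>\n", x$hypothesis))
  cat(sprintf("  shared: k_plus = %.4g, k2 = %.4g (0 nM ess = %.3g)\n",
              x$baseline$params$k_plus, x$baseline$params$k2, x$baseline$ess))
  print(x$groups)
  cat(sprintf("  total e.s.s. = %.5g\n", x$ess))
  invisible(x)
}

#' Rank the three inhibition hypotheses
#'
#' Runs [fit_hypothesis()] for all three mechanisms on the same traces
#' (sharing one baseline fit) and returns them ordered by total error square
#' sum, lowest (best) first.
#'
#' @inheritParams fit_hypothesis
#' @return Tibble with columns `hypothesis`, `ess`, and a list-column `fit`.
#' @export
rank_hypotheses <- function(traces,
                            base = list(n2 = 2, nc = 2, m_total = 5,
                                        m_eq = 3.5, seed_mass = 0.035,
                                        seed_mean_size = 500)) {
  med <- median_traces(traces)
  g0 <- dplyr::filter(med, .data$jb6_conc == 0)
  if (nrow(g0) == 0L) {
    stop_oligochap("A 0 nM chaperone group is required.", "oligochap_fit_error")
  }
  baseline <- .fit_baseline(g0$t, normalize_trace(g0$signal), base)
  fits <- purrr::map(
    c("reduce_k_plus", "reduce_k2", "inactivate_seeds"),
    function(h) fit_hypothesis(traces, h, base, baseline = baseline))
  tibble(
    hypothesis = vapply(fits, function(f) f$hypothesis, character(1)),
    ess = vapply(fits, function(f) f$ess, numeric(1)),
    fit = fits
  ) |> dplyr::arrange(.data$ess)
}
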