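---
title: "Models and methods: chaperone-oligomer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: chaperone-oligomer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science behind each module:
the models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Seeded aggregation kinetics

Fibril formation is described by the standard two-moment closure of the
amyloid master equations, tracking fibril number concentration $P$ and fibril
mass concentration $M$ (monomer equivalents), with free monomer
$m = m_\mathrm{total} - M$:

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M, \qquad
  \frac{dM}{dt} = 2 k_+ P\,(m - m_\mathrm{eq}).$$

Assumptions worth stating explicitly:

* **Solubility-limited elongation.** Net elongation is proportional to the
  supersaturation $m - m_\mathrm{eq}$ rather than to $m$. For the peptide
  studied here the measured fibril solubility (3.5 mM) is a large fraction of
  the 5 mM total, so a plateau in fibril mass must coexist with millimolar
  free monomer; elongation proportional to $m$ could not produce that. The
  nucleation terms keep $m$ for simplicity; at these parameters nucleation is
  negligible once $m$ approaches $m_\mathrm{eq}$ in any case.
* **Seed number.** Seeds enter as a mass $M(0)$ (default 0.7% of total in
  monomer equivalents) and a mean size $L_0$ (default 500 monomers per
  sonicated seed), giving $P(0) = M(0)/L_0$. $L_0$ is a configuration
  parameter: sonicated-seed length distributions are instrument dependent and
  only the product $k_+ P(0)$ is constrained by a trace anyway.
* **Reporter linearity.** ThT fluorescence is taken as affine in fibril
  mass; `normalize_trace()` rescales by the mean of the first 5 points
  (baseline) and the final 10% of points (plateau, accepted only if its
  relative drift is below 5%).
* **Identifiability.** A single normalized seeded trace determines the
  amplification rate $\sqrt{k_+ k_2 \cdot (\ldots)}$ — in practice the
  *product* $k_+ k_2$ at fixed reaction orders — while $k_+$ and $k_2$
  individually trade off along a ridge. The tests therefore assert recovery
  of the product, and the hypothesis comparison is built on e.s.s.
  differences, which are insensitive to position along the ridge.

Units are hours and mM throughout the kinetics module; chaperone
concentrations in nM are converted at the boundary.

### Chaperone-inhibition hypotheses

`fit_hypothesis()` implements the three mechanistic candidates for
sub-stoichiometric inhibition: a per-concentration reduction of $k_+$, of
$k_2$, or of the active seed fraction (scaling $M(0)$ and $P(0)$ together).
Shared rates are fitted on the chaperone-free group (median of replicates —
medians are the standard summary for seeded kinetic replicates), then one
free parameter per chaperone concentration is profiled by 1-D optimisation on
the log scale. `rank_hypotheses()` orders the three total e.s.s. values. On
traces generated under seed inactivation the seed hypothesis wins by more
than an order of magnitude; rate-reduction mechanisms change the slope of the
growth phase, not mainly its lag, and cannot reproduce dose-dependent lag
shifts with conserved shape.

Seed inactivation scales both seed number and seed mass; inactivating only
the number would leave inert mass that neither elongates nor catalyses,
which is indistinguishable at these seed levels but less parsimonious.

### Oligomer pulse

The transient oligomer channel solves
$dO/dt = k_2 (m - m_\mathrm{eq})^{n_2} M - k_\mathrm{loss} O$ on top of the
moment solution. The generation term is the secondary-nucleation flux driven
by the *supersaturation*: with a solubility this close to the total
concentration, a flux proportional to $m^{n_2} M$ would keep producing
oligomers at the plateau (where $m = m_\mathrm{eq}$ but $M$ is maximal) and
the pulse would never decay — supersaturation-driven nucleation is what makes
the observed rise-and-fall possible at all. The loss rate defaults to
$k_\mathrm{loss} = 3.5\ \mathrm{h^{-1}}$, the measured 37 °C dissociation
rate of chaperone-free oligomers, which is the one experimental constraint
available for that parameter. The pulse peaks at roughly 40% mass conversion,
slightly before the half-time, and decays to zero afterwards.

## Microfluidic diffusional sizing

The channel is modelled as two co-flowing streams of equal width with the
labelled sample confined to one at the inlet. With reflecting walls and a
step initial profile, lateral diffusion gives a diffused fraction

$$f = \tfrac12 - \frac{4}{\pi^2} \sum_{k\ \mathrm{odd}}
      \frac{1}{k^2}\, e^{-k^2 \pi^2 \kappa D / 4},$$

where $\kappa$ (s·m⁻²) is the only free constant — an effective residence
time per squared channel width — and $D$ follows from the Stokes–Einstein
relation at 298.15 K in water (8.9·10⁻⁴ Pa·s) by default. $f$ runs from 0
(no diffusion) to 0.5 (full equilibration) and is strictly decreasing in
particle size.

The instrument's proprietary fraction-to-radius transform is not public, so
$\kappa$ is calibrated from the one quantitative pair the experiment pins
down: the free chaperone monomer (3 nm) reads $f = 0.42$. This preserves the
monotone fraction-radius relationship, which is all the downstream analysis
uses; absolute $\kappa$ values are not comparable to the vendor's. Size
ranges 2 and 4 ship as nominal 2× and 0.5× variants of the calibrated range
3 constant.

Two conventions follow from how the instrument works and are asserted
throughout:

* **Averaging happens in fraction space.** One intensity split is measured
  per sample, so a mixture contributes
  $f_\mathrm{obs} = \sum_i w_i f(R_{h,i})$ with label-fraction weights; the
  apparent radius of a mixture is therefore biased below the arithmetic mean
  of component radii (a 50/50 mix of 3 and 11 nm species reads well under
  7 nm). This is also why an excess of free chaperone underestimates
  co-oligomer size, and why the chaperone-titration experiment
  (`chaperone_titration_curve()`) is needed to show the probe is fully bound.
* **Out-of-range fractions are a condition, not a number.** Fractions above
  what the smallest allowed radius can produce raise a typed error, mirroring
  the instrument's "size determination not possible" state (e.g. fibrils in
  the channel); fractions marginally above the physical 0.5 limit are clipped
  to 0.4999 with a QC warning, since they arise from intensity noise.

The labelling degree of the chaperone does not enter: only labelled molecules
are observed, and the fraction is a ratio of their intensities.

## Binding isotherm

With total chaperone $C_\mathrm{JB6}$ (12.5 nM in the reference design) and
binding sites $S = X C_s$ carried by a supernatant volume fraction $X$,
independent binding with depletion gives the bound concentration as the
physical root of $(C-B)(S-B) = K_D B$:

$$B = \tfrac12\left[(C+S+K_D) - \sqrt{(C+S+K_D)^2 - 4CS}\right],$$

computed in the subtraction-safe form $2CS/(C+S+K_D+\sqrt{\cdot})$. The
observed fraction interpolates the free and bound plateaus:
$f(X) = f_0 + (f_b - f_0)B/C_\mathrm{JB6}$. The fit runs on raw diffused
fractions (not on radii), over all replicate points jointly, with $K_D$
multistarted at 0.1, 1, 10, 100 nM: because $K_D \ll C_\mathrm{JB6}$ puts
binding in the near-stoichiometric regime, the error surface is nearly flat
below the true $K_D$ and single-start fits are fragile. Each simplex solution
is polished by bounded Levenberg–Marquardt.

`ess_profile()` re-optimises $(C_s, f_0, f_b)$ on a fixed-$K_D$ grid and
reports the e.s.s. ratio to the unconstrained minimum; the interval where the
ratio stays below 1.25 is the reported confidence region. Under the default
noise the profile is flat below ~1 nM and rises above it: the titration
bounds the affinity **from above only**, and the honest summary is that
interval, not the point estimate. $C_s$ is an upper limit to the oligomer
concentration (one chaperone site per oligomer); this caveat is emitted with
every fit.

## Dissociation kinetics

`fit_decay()` fits $R_h(t) = a e^{-k_\mathrm{off} t} + c$ by bounded
nonlinear least squares ($a, k_\mathrm{off} \ge 0$, $0 < c \le R_h(0)$),
starting from $a = R_h(0) - R_h(\mathrm{end})$, $c = R_h(\mathrm{end})$,
$k_\mathrm{off} = 1/\mathrm{span}$. Replicate-level points are fitted when
present; mean-level series with standard deviations get $1/\mathrm{sd}^2$
weights. Flat series return $a = 0$ with an `unidentifiable` flag rather than
a spurious rate, and `compare_rates()` refuses such inputs.

`compare_rates()` gives the rate ratio with a percentile bootstrap CI
(default 2000 resamples), resampling replicates within each timepoint of both
series. One known bias is reported, not corrected: samples incubated *with*
chaperone are diluted at time zero by the chaperone addition, which lowers
their monomer concentration and *raises* their net dissociation rate — so
the measured stabilisation by the chaperone is conservative.

## Small-angle scattering

The composite model is $I(q) = A q^{-p} + s\,c\,P_\mathrm{Debye}(q, R_g) +
\mathrm{bkg}$: an empirical power law for the heterogeneous fibril network at
low $q$ (the measured exponent ≈2.3 indicates attractive fibril-fibril
interactions; a dilute rod would give $q^{-1}$), plus the Debye Gaussian-coil
form factor for the monomers coexisting with fibrils. The contrast constant
$s$ (intensity per mM at $q \to 0$) is treated as known input — computing
absolute contrast from partial specific volumes is out of scope — which makes
the coil concentration well-posed; the generator uses the same constant.
$S(q) \approx 1$ is assumed for the coil term despite the millimolar
concentration; the interacting-network physics lives in the empirically
fitted power law.

`fit_saxs()` stages the estimation: log-log regression below
$q_\mathrm{low} = 0.03$ Å⁻¹ for $(A, p)$; weighted nonlinear least squares
above $q_\mathrm{high} = 0.06$ Å⁻¹ (the monomer-dominance crossover) for
$(R_g, c, \mathrm{bkg})$ at fixed power law; then a joint refinement of all
five parameters, which removes the small slope bias the coil tail imprints on
the first stage. Reporting the bare low-$q$ slope uses $q < 0.01$ Å⁻¹, deep
in the network regime.

## Synthetic-data generators

Each scenario is a pure function of `scenario_config()` — identical seeds
give identical bytes. Defaults encode the study conditions; everything the
study does not pin down is a documented constant, chosen once:

* **fig3a** — 5 mM peptide, 0.7% seeds, chaperone at 0/50/150/300/1000 nM,
  7 replicates at 0 nM and 5 otherwise. The baseline rates are calibrated at
  run time so the chaperone-free half-time is exactly 6.5 h (inside the
  observed ≈6–7 h), exploiting the exact time-rescaling of the $k_n = 0$
  system; the seed-inactivation constant in
  $a = 1/(1 + [\mathrm{JB6}]/K_\mathrm{inact})$ is solved so 50 nM doubles
  the half-time. Both printed constraints therefore hold by construction,
  not by frozen magic numbers. ThT noise: Gaussian, 2% of the dynamic range.
* **fig4a/fig4b** — the oligomer pulse drives a binding-site concentration
  peaking at $C_s = 400$ nM (consistent with the titration scenario); the
  free (3 nm) / co-oligomer (11 nm, or 5 nm for the fast-aggregating
  full-length analogue) mixture passes through the forward sizing model and
  back. Noiseless, the apparent radius starts at 3 nm, peaks at the
  co-oligomer radius near the half-time, and returns to 3 nm.
* **fig4c/fig4d** — titrations from the same binding parameters
  ($K_D = 1$ nM, $f_0 = 0.42$, $f_b = f(11\,\mathrm{nm})$, $C_s = 400$ nM);
  fig4d uses 12 log-spaced $X$ values over $1.4\cdot10^{-4}$–0.75 with 5
  replicates. The diffused-fraction noise default (σ = 0.015 absolute) is
  the level at which the scenario reproduces the *qualitative* printed
  behaviour of the real titration — an e.s.s. profile flat below ~1 nM, so
  only an upper affinity bound — while still recovering $f_0$ to better than
  0.01. A smaller σ would pin $K_D$ tightly, which the real experiment
  demonstrably could not.
* **fig5_37C/fig5_23C** — decays from $7 e^{-k_\mathrm{off} t} + 3$ nm with
  the four condition rates 3.5/1.9 and 1.3/0.8 h⁻¹, σ = 0.5 nm, 4 replicates
  per point. Sampling is one measurement per 5 min over 0–2 h (37 °C) or per
  10 min over 0–4 h (23 °C): at this density the design's information
  content puts the rate-estimate sampling CV near 5–7%, so the 15% recovery
  the series are meant to support holds with margin (Monte Carlo: ~98% of
  seeds).
* **fig3c** — composite curve with $p = 2.3$, $c = 3.9$ mM, $R_g = 1$ nm,
  the power-law amplitude pinned by the crossover at 0.06 Å⁻¹, and
  multiplicative lognormal noise (2%).

What the generators deliberately do **not** emulate: instrument raw images,
pipetting/timing artefacts, the unknown true oligomer-population dynamics
(the supersaturation-source pulse is a stand-in), fibril material clogging
the channel, or a calibrated model of the full-length peptide (fig4b is a
structural emulation). Passing tests on these scenarios therefore show the
*estimators* are correct and well-conditioned under the stated statistical
structure — not that real instrument data will be this clean.

## Numerical choices

* ODEs: `deSolve::lsoda`, rtol 1e-8, atol 1e-10; mass conservation holds to
  1e-6 relative by construction ($m$ is eliminated) and is asserted anyway.
* Oligomer convolution: per-step exponential quadrature, exact for a source
  linear over the step and stable for arbitrarily stiff loss rates.
* Sizing series: 51 odd terms; for $\kappa D < 0.01$ the semi-infinite
  (image) short-time solution replaces the series, whose term count would
  otherwise diverge as $\kappa D \to 0$ (the switch is continuous to ~1e-12).
  Inversion by bisection to 1e-4 nm on a strictly monotone map.
* Debye function: closed form with `expm1`; below $u = (qR_g)^2 = 10^{-4}$
  the series $1 - u/3 + u^2/12$, where the closed form's remaining
  cancellation would dominate.
* Binding fit: Nelder–Mead on log/logit-transformed parameters for global
  robustness, then bounded Levenberg–Marquardt polish of every start.
* Test-time problem sizes: kinetic grids of 100–250 points, 60-point
  titrations, 100-point decay series, 180-point scattering curves, bootstraps
  of a few hundred resamples — the full suite runs in about a minute.

## Known limitations

* The channel constant is a stand-in calibration; apparent radii are
  consistent within this package but not instrument-absolute beyond the
  anchored 3 nm / 0.42 pair.
* $k_+$ and $k_2$ are reported as a ridge; only their product is meaningful
  from a single seeded condition.
* The dissociation comparison inherits the dilution bias described above.
* The binding model is single-site and at-equilibrium; cooperative binding
  or slow association during the incubation would alias into $C_s$ and the
  plateaus.
* Oligomer concentrations from $C_s$ are upper bounds, not counts.
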