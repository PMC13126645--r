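# oligochap

Quantitative analysis of how a molecular chaperone (the DnaJ-family protein
DNAJB6b, "JB6") inhibits seeded amyloid aggregation and binds the transient
oligomers formed along the way. The package is built around the experimental
logic of a microfluidic diffusional sizing (MDS) study of the model peptide
Aβ20–34: labelled chaperone is mixed with the supernatant of an aggregating
sample, and any increase in its average hydrodynamic radius ⟨R_h⟩ reports on
binding to species too small to pellet but large enough to slow diffusion —
operationally, oligomers.

It is intended for biophysicists who want to analyse (or simulate, for
planning and validation) four data streams with one consistent toolchain:

1. **Seeded aggregation kinetics** (ThT fluorescence). Two-moment
   master equations for fibril number *P* and fibril mass *M*:

   dP/dt = k_n·m^(n_c) + k₂·m^(n₂)·M,
   dM/dt = 2·k₊·P·(m − m_eq),  m = m_total − M,

   with solubility-limited elongation (the fibril solubility m_eq = 3.5 mM is
   a large fraction of the 5 mM total, so the ThT plateau coexists with
   millimolar free monomer). Three chaperone-inhibition hypotheses — reduced
   k₊, reduced k₂, or inactivated seeds — are fitted globally and ranked by
   error square sum (e.s.s.).
2. **Diffusional sizing**. A calibrated one-parameter channel model maps
   hydrodynamic radius → Stokes–Einstein diffusivity → diffused fraction
   f ∈ (0, 0.5), and inverts the measured fraction back to an apparent
   ⟨R_h⟩, including label-weighted mixtures of free and bound chaperone.
   The shipped calibration reproduces the anchor f = 0.42 at R_h = 3 nm
   (the free chaperone monomer).
3. **Binding isotherms**. The depletion-corrected independent-binding model
   f(X) = f₀ + (f_b − f₀)·B/C_JB6, with B the exact quadratic solution of
   (C − B)(S − B) = K_D·B and S = X·C_s the sites carried by a supernatant
   volume fraction X; multistart least squares plus e.s.s. profiling of K_D
   (the data bound the affinity from above — the profile is flat at low K_D).
4. **Oligomer stability**. Single-exponential dissociation fits
   R_h(t) = a·e^(−k_off·t) + c and bootstrap comparison of rate constants
   across ±chaperone and temperature conditions.
5. **SAXS**. A composite fibril-network power law A·q^(−p) plus Debye
   random-coil term for the coexisting monomers, giving the monomer
   concentration and coil radius of gyration from the scattered intensity.

Every data stream has a seeded synthetic generator (`scenario_config()` +
`generate_*()`) whose defaults encode the study conditions, so the entire
pipeline runs and is tested without any instrument data.

## Worked example: does the chaperone stabilise oligomers?

Simulate the 37 °C oligomer-dissociation experiment (sizing series withdrawn
over 2 h, 4 replicates per point, ±chaperone), fit both decays, and compare
rates:

```r
library(oligochap)
library(dplyr)

d37 <- generate_decays(scenario_config("fig5_37C", seed = 42))
fit_free <- fit_decay(filter(d37, condition == "without_JB6"))
fit_jb6  <- fit_decay(filter(d37, condition == "with_JB6"))
fit_free
#> <decay_fit>
#>   r_h(t) = 7.378 * exp(-3.804 t) + 3.036  (nm, h)
#>   e.s.s. = 25.86 over 100 points
fit_jb6
#> <decay_fit>
#>   r_h(t) = 7.053 * exp(-2.161 t) + 3.139  (nm, h)
#>   e.s.s. = 19.35 over 100 points

compare_rates(fit_free, fit_jb6, n_boot = 2000, seed = 42)
#> <rate_comparison>
#>   k_off ratio = 1.76  (95% bootstrap CI 1.504-2.073, 2000 resamples)
```

The ~10 nm oligomers decay to the 3 nm free-chaperone baseline; without
chaperone the dissociation rate constant is ≈3.8 h⁻¹ versus ≈2.2 h⁻¹ with it,
and the bootstrap interval for the ratio excludes 1: chaperone-free oligomers
dissociate roughly twice as fast, i.e. the chaperone stabilises them. Fits
are tidyverse-friendly (`tidy()`, `glance()`, `autoplot()`), e.g.
`tidy(fit_free)` returns the three parameters as a tibble.

The same pattern applies to the other streams: `generate_kinetics()` +
`rank_hypotheses()` for the seed-inactivation analysis,
`generate_titrations()` + `fit_binding()` + `ess_profile()` for the binding
curve, `generate_saxs()` + `fit_saxs()` for the scattering decomposition.

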