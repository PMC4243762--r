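# probekit

Photophysical characterization of laurdan-family solvatochromic membrane
probes (laurdan, M-laurdan, MoC-laurdan, C-laurdan) in R.

These dyes report on the polarity and hydration of their surroundings: in
an ordered, dehydrated lipid bilayer they emit from the blue locally
excited (LE) state, while in a polar, hydrated environment solvent
relaxation shifts emission to the red intramolecular-charge-transfer (ICT)
band. The workhorse observable is the **generalized polarization**

```
GP = (I440 - I490) / (I440 + I490)
```

which, together with quantum yields, TCSPC lifetimes, steady-state
anisotropy and rotational relaxation times, distinguishes
solid-ordered (So), liquid-ordered (Lo) and liquid-disordered (Ld)
membrane phases. probekit implements that entire workflow:

- **photophysics** — GP from intensities or spectra, relative quantum
  yields `phi = (S/S_r)(OD_r/OD)(n/n_r)^2 phi_r`, de-excitation rate
  constants `kr = phi/tau`, `knr = (1 - phi)/tau`, brightness
  `epsilon * phi`, and GP-vs-relaxation-time correlation.
- **decay** — TCSPC forward model `I(t) = sum_i alpha_i exp(-t/tau_i)`,
  Poisson simulation, weighted least-squares fitting with optional IRF
  reconvolution, model selection, and the intensity-weighted mean
  lifetime `<tau> = sum(alpha_i tau_i^2) / sum(alpha_i tau_i)`.
- **anisotropy** — G-factor correction
  `r = (Ivv - G Ivh)/(Ivv + 2 G Ivh)` and the Perrin-Weber rotational
  relaxation time `theta = tau r / (r0 - r)`.
- **scans** — Boltzmann-sigmoid melting-transition fits of GP(T)/r(T)
  scans and one-site (`I = Imax t/(t_half + t)`) insertion kinetics.
- **solvents** — dioxane/water dielectric mixing, Lippert-Mataga
  orientational polarizability and Lippert regression.
- **imaging** — per-pixel GP maps with intensity masking from spectral
  TIFF stacks (two-photon microscopy workflow).
- **synthetic** — seeded generators for every input: two-band spectra,
  Poisson decays, polarized intensities, thermal scans, insertion traces
  and multi-region image scenes.

The published characterization tables (probe identities, solvent
photophysics, lipid-environment lifetimes) ship as plain-text data; see
`probe_table()`, `solvent_photophysics()`, `lipid_lifetimes()`,
`solvent_table()`.

## Worked example

```r
library(probekit)

# Mean lifetime from a two-component TCSPC fit (laurdan in DPPC, 20 degC)
comps <- decay_components(c(0.56, 0.44), c(6.18, 0.53))
round_half_up(mean_lifetime(comps), 2)
#> 5.82                          # ns; dominated by the 6.18 ns component

# De-excitation rates from quantum yield + lifetime (laurdan, chloroform)
rate_constants(phi = 0.61, tau = 2.78)
#> $kr 0.2194  $knr 0.1403       # ns^-1; kr + knr = 1/tau

# Simulate a 1e6-count TCSPC measurement with a 0.5 ns FWHM IRF and re-fit
h <- simulate_decay(comps, irf = gaussian_irf(), total_counts = 1e6, seed = 42)
fit_decay(h, n_components = 2)
#> <decay_fit> 2 component(s), reduced chi2 = 1.066, <tau> = 5.795 ns
#>   alpha1 =  56.2%  tau1 = 6.146 ns
#>   alpha2 =  43.8%  tau2 = 0.524 ns

# Melting transition of a synthetic DPPC-like GP(T) scan
fit_transition(gen_thermal_scan(tm = 41, seed = 42))
#> <transition_fit> Tm = 40.93 degC, width = 1.41 degC,
#>                  plateaus 0.555 -> -0.101 (rmse 0.011)

# Anisotropy and Perrin-Weber relaxation time from polarized counts
p <- gen_polarized(r_true = 0.25, total_intensity = 1e6, g_true = 0.95,
                   poisson = TRUE, seed = 42)
r <- steady_state_anisotropy(p)
rotational_relaxation_time(r, tau = 5.82)
#> r = 0.2505, theta = 9.76 ns
```

The fitted decay recovers the true parameters to a few percent at
10^6 counts; the transition fit lands within 0.1 degC of the true 41 degC
midpoint at realistic noise; the anisotropy round trip is exact up to
photon-counting error.

`run_pipeline(list(seed = 1, out_dir = "out"))` chains all stages on a
seeded synthetic study and writes a summary CSV (seed recorded in its
header), a JSON report and a GP-map TIFF.

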