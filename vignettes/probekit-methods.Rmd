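---
title: "probekit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{probekit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probekit)
```

probekit implements the photophysical characterization workflow for
laurdan-family solvatochromic membrane probes. This vignette is the
package's own account of the models it fits, the defaults it ships, and
the choices made where the underlying methodology left the design open.
Units are fixed package-wide: wavelengths nm, wavenumbers cm^-1, decay
times ns, kinetic times minutes, temperatures degC.

## Generalized polarization

GP is the normalized two-channel contrast `(I440 - I490)/(I440 + I490)`.
The two channels sample the locally excited (LE, blue) and
intramolecular-charge-transfer (ICT, red, solvent-relaxed) emission bands,
so GP increases with lipid order and decreases with hydration. Two reading
conventions coexist in practice and both are supported by the `bandwidth`
argument of `gp_from_spectrum()`:

- `bandwidth = 0` (default): linear interpolation at exactly 440 and
  490 nm, matching point reads on a scanning spectrofluorimeter;
- `bandwidth = 10`: trapezoid integration over `center +- 5` nm, matching
  the 10 nm spectral channels of a two-photon microscope detector.

Whether historical spectrofluorimeter GP values used point reads or
narrow-band integration is generally not recorded; the difference is well
below typical inter-sample variability for bands tens of nm wide, and the
parameter makes either convention explicit. In imaging (`gp_map()`)
channels are matched by nearest center within 1 nm and read as single
planes — the microscope hardware already integrates over its 10 nm
channel, so no further band summing is applied.

Pixels with summed channel intensity below `min_total_intensity` are
masked; the threshold an acquisition actually needs depends on background
level and is deliberately configurable (default 0, i.e. only
zero-intensity pixels are dropped). No G-factor enters two-photon GP maps;
no polarizers are involved.

## TCSPC decay analysis

The impulse response is modeled as `I(t) = sum_i alpha_i exp(-t/tau_i)`
with *amplitude* fractions `sum alpha_i = 1`. Reported decay tables print
these amplitudes as percentages alongside component lifetimes; the
intensity-weighted mean lifetime is

```
<tau> = sum(alpha_i tau_i^2) / sum(alpha_i tau_i)
```

(each component's steady-state intensity share is `alpha_i tau_i`). One
printed statement of the amplitude normalization in the source material
for the bundled tables is typographically garbled (`I_i tau_i = alpha_1`);
parameterizing directly in normalized amplitudes `alpha_i = I_i / tau_i`
is the reading that makes those tables self-consistent, and it is what
`mean_lifetime()` assumes.

`fit_decay()` minimizes Poisson-weighted (Neyman) residuals
`(model - counts)/sqrt(max(counts, 1))` with Levenberg-Marquardt
(minpack.lm), parameterized in log-lifetimes and log-amplitudes so
positivity is structural. Choices worth knowing:

- **Fit window.** Without an IRF the fit runs from the peak bin to the
  last bin with at least one count (tail fit). With an IRF the model is
  reconvolved (discrete linear convolution with the unit-normalized IRF)
  and the window extends over the full histogram, because the rising edge
  carries the pulse-position information that a tail fit discards.
- **Zero-count bins** get unit variance, the standard Neyman guard.
- **Starting values** are deterministic: the slow lifetime from a
  log-linear regression on the late half of the occupied window, the fast
  lifetime from the early 15% (falling back to `tau_slow/5` when the two
  estimates do not separate), amplitudes split evenly at the peak scale.
  No random restarts, so fits are reproducible by construction.
- **Model size** is capped at two components, the largest model the
  bundled tables use; `select_model()` accepts the 2-component model only
  when it improves reduced chi-square by more than 10% (relative), which
  cleanly separates well-spaced simulations (tau ratio >= 5) from
  single-exponential ones.
- **Reference deconvolution.** Historical instruments often deconvolved
  against a mono-exponential reference fluorophore (e.g. POPOP,
  tau = 1.35 ns in ethanol). probekit approximates this with measured-IRF
  reconvolution, plus the delta-IRF tail-fit mode for synthetic data; the
  exact reference-deconvolution variant used by any given legacy
  instrument is usually unspecified and is not reproduced. For the same
  reason published chi-square values (sometimes > 4) are not comparable
  to probekit's: the legacy weighting is unknown.

At the study conditions (10^6 counts, 1024 x 0.05 ns bins, Gaussian IRF of
0.5 ns FWHM centered at 2 ns) the simulate-fit round trip recovers both
lifetimes of the DPPC-like pair (6.18/0.53 ns, 56/44) with median relative
error around 1-3% and amplitudes within ~0.01; the residual downward bias
on the fast component at lower counts is the known Neyman-weighting bias
and stays well inside 5% at 10^6 counts.

## Anisotropy and rotational relaxation

`r = (Ivv - G Ivh)/(Ivv + 2 G Ivh)` with `G = Ihv/Ihh` measured in the
horizontal-excitation geometry. The Perrin-Weber relation
`r0/r = 1 + tau/theta` is inverted as
`theta = tau r/(r0 - r)`; `r0` defaults to 0.4, the theoretical limit for
collinear absorption and emission dipoles, and is configurable because the
effective fundamental anisotropy of a real probe/filter combination can be
lower. The lifetime paired with a steady-state `r` is the
intensity-weighted `<tau>` from the decay module — a steady-state
anisotropy is an intensity-weighted average, so the intensity-weighted
lifetime is the consistent companion; a component lifetime can be passed
instead where a dominant component is known. Values outside [-0.2, 0.4]
are physically implausible for one-photon excitation and can be screened
with `anisotropy_is_physical()`, but are never silently altered.

## Thermal scans and insertion kinetics

A melting transition appears as a steep sigmoidal drop of GP or anisotropy
with temperature. probekit fits the descending Boltzmann form

```
v(T) = lower + (upper - lower) / (1 + exp((T - Tm)/w))
```

by Levenberg-Marquardt with deterministic starts (Tm at the steepest
finite-difference descent, plateaus from the first/last three points,
width = range/10). The sign ambiguity of `w` (the mirrored
parameterization describes the same curve) is normalized after fitting. A
transition is *detected* only when the fitted amplitude exceeds 3x the
residual RMSE and Tm is interior to the scanned range: on the standard
10-60 degC, 2 degC grid with noise sigma = 0.01 this recovers a 41 degC
midpoint within +-0.15 degC while flat scans at the same noise level are
never flagged. The sigmoid is a phenomenological choice — the data being
modeled show a plateau/steep-fall/plateau shape without a stated
functional form — and two-step transitions (ripple phases) are out of
scope.

Insertion of probe into vesicles is fit with the one-site saturation
hyperbola through the origin, `I(t) = Imax t/(t_half + t)`, so
`I(t_half) = Imax/2` by construction and the fitted curve passes through
(0, 0) as the first post-injection measurements do. When the sampled times
all sit far beyond the half-rise the Jacobian becomes near-singular and
`t_half` is unidentified; the fit then reports `poorly_determined = TRUE`
(standard error above half the estimate, or a singular covariance) rather
than failing.

## Solvent-polarity models

Dioxane/water mixtures interpolate the dielectric constant linearly in
mole fraction between 2.2 (dioxane) and 80.1 (water) at 20 degC,
deliberately ignoring mixing non-ideality — the model is the definition of
the polarity ladder, not a thermodynamic claim. The Lippert-Mataga
orientational polarizability is taken in its standard form

```
delta_f = (eps - 1)/(2 eps + 1) - (n^2 - 1)/(2 n^2 + 1)
```

and Stokes shifts in `10^7 (1/lambda_abs - 1/lambda_em)` cm^-1. Solvent
refractive indices (20 degC literature values) ship in `solvent_table()`
because polarity tabulations typically list only the dielectric constant;
the table is editable data, not code. Per-solvent absorption maxima are
not tabulated here, so Lippert analyses of synthetic data define their own
`lambda_abs`.

## Synthetic data: what it emulates, what it does not

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes: Poisson noise for count-like
data (decays, polarized counts, image channels), additive Gaussian noise
for analog spectra and scans. Every generator is deterministic given its
seed.

The spectrum generator mixes two Gaussian bands (LE at 440 nm, ICT at
490 nm, sd 25 nm) with an ICT weight
`w = 0.15 + 0.005 eps + 0.40 [protic]`, clamped to [0, 1]. These
coefficients are a package calibration, not measured values: they encode
the qualitative solvent pattern (GP falls roughly linearly with dielectric
constant; hydrogen-bond-donating solvents depress GP far beyond their
dielectric constant alone) so that a nonpolar solvent yields GP near +0.5
and protic solvents with eps > 20 yield GP below -0.2. Consequences a user
should keep in mind: passing tests show the *analysis* recovers what the
generator encodes; they do not show the generator reproduces real probe
spectra (no vibronic structure, no temperature dependence of band shape,
no dye-specific band positions).

Scene generation solves the GP equation exactly for each region's true GP
at its mean intensity in the 440/490 channels and fills the remaining
channels from a fixed template shape; real spectral images have per-pixel
spectral variation the template lacks. The default study sizes keep the
full suite fast: 20-seed recovery studies for decays (10^6 counts each)
and thermal scans, 50 x 50 two-region scenes at 10^4 expected counts per
pixel, all chosen as representative single-instrument workloads.

## Known limitations

- Decay analysis: no global multi-curve fitting, no lifetime
  distributions, no time-resolved anisotropy decays, at most two
  components.
- Quantum yields are relative (reference-standard) only; no
  integrating-sphere absolute yields, and no inner-filter correction
  beyond warning above OD 0.05.
- The Lippert module stops at the regression; no Onsager cavity-radius or
  dipole-moment extraction.
- Imaging stops at GP maps, masks and histograms; segmentation and
  biological assignment of structures are out of scope.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(seed = 1, out_dir = tempfile()))
res$decay      # recovered two-component fit of the synthetic decay
res$scans      # Tm and insertion-time estimates
res$imaging    # region GP means of the synthetic scene
```

The pipeline writes a summary CSV whose header records the seed, a JSON
report, and the GP map as a 32-bit float TIFF; identical configuration and
seed reproduce identical files.
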