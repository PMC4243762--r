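#' Generalized polarization from two channel intensities
#'
#' GP is the normalized difference of the blue-edge (440 nm) and red-edge
#' (490 nm) emission intensities, `(I440 - I490) / (I440 + I490)`. It reports
#' on the polarity/hydration of the probe environment: +1 means all emission
#' in the blue (locally excited) channel, -1 all in the red
#' (charge-transfer, solvent-relaxed) channel.
#'
#' @param i440 Intensity in the 440 nm channel (arbitrary units, >= 0).
#'   Vectorized; recycled against `i490`.
#' @param i490 Intensity in the 490 nm channel (>= 0).
#' @return GP value(s) in \[-1, 1\].
#' @examples
#' compute_gp(3, 1)   # 0.5
#' compute_gp(5, 5)   # 0
#' @export
compute_gp <- function(i440, i490) {
  if (!is.numeric(i440) || !is.numeric(i490))
    stop("intensities must be numeric", call. = FALSE)
  if (anyNA(i440) || anyNA(i490))
    stop("intensities must not contain NA", call. = FALSE)
  if (any(i440 < 0) || any(i490 < 0))
    stop("intensities must be non-negative", call. = FALSE)
  tot <- i440 + i490
  if (any(tot <= 0))
    stop("GP undefined: both channel intensities are zero", call. = FALSE)
  (i440 - i490) / tot
}

#' Emission spectrum container
#'
#' A wavelength-indexed emission intensity series, the unit of data produced
#' by the spectrofluorimeter (370-600 nm scan, 360 nm excitation by default).
#'
#' @param wavelengths Wavelengths in nm, strictly ascending.
#' @param intensities Intensities (arbitrary units, >= 0), same length.
#' @param excitation Excitation wavelength in nm.
#' @param meta Named list of free-form sample metadata (solvent, lipid mix,
#'   temperature, ...).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, excitation = 360,
                              meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have the same length", call. = FALSE)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least two points", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 excitation = excitation, meta = meta),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %.0f-%.0f nm, excitation %.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$excitation))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

# Point read (linear interpolation) or trapezoid band integral of a spectrum.
band_intensity <- function(spec, center, bandwidth = 0) {
  wl <- spec$wavelengths
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo < min(wl) || hi > max(wl))
    stop(sprintf("channel %g nm (bandwidth %g) outside spectral range %g-%g nm",
                 center, bandwidth, min(wl), max(wl)), call. = FALSE)
  if (bandwidth <= 0)
    return(stats::approx(wl, spec$intensities, xout = center)$y)
  grid <- sort(unique(c(lo, hi, wl[wl > lo & wl < hi])))
  y <- stats::approx(wl, spec$intensities, xout = grid)$y
  sum(diff(grid) * (y[-length(y)] + y[-1]) / 2)
}

#' GP read out of an emission spectrum
#'
#' Evaluates the two GP channels on a spectrum and feeds them to
#' [compute_gp()]. With `bandwidth = 0` (spectrofluorimeter convention) the
#' intensities are linearly interpolated point reads at the channel centers;
#' with `bandwidth > 0` (imaging convention, e.g. the microscope's 10 nm
#' channels) each channel is a trapezoid integral over
#' `center +- bandwidth/2`.
#'
#' @param spec An [emission_spectrum()].
#' @param centers Channel centers in nm, default `c(440, 490)`.
#' @param bandwidth Channel bandwidth in nm; 0 means point interpolation.
#' @return GP value in \[-1, 1\].
#' @export
gp_from_spectrum <- function(spec, centers = c(440, 490), bandwidth = 0) {
  stopifnot(inherits(spec, "emission_spectrum"), length(centers) == 2L)
  ia <- band_intensity(spec, centers[1], bandwidth)
  ib <- band_intensity(spec, centers[2], bandwidth)
  compute_gp(ia, ib)
}

#' Quantum-yield measurement of one sample
#'
#' Bundles the three quantities entering the relative quantum-yield formula:
#' integrated emission area, optical density at the excitation wavelength,
#' and solvent refractive index. Optical densities are kept at or below 0.05
#' in practice to avoid inner-filter effects; larger values are accepted
#' with a warning.
#'
#' @param area Integrated emission intensity S (arbitrary units, > 0).
#' @param od Optical density at the excitation wavelength (> 0).
#' @param n Refractive index of the solvent (>= 1).
#' @return An object of class `qy_sample`.
#' @export
qy_sample <- function(area, od, n) {
  if (!is.numeric(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  if (!is.numeric(od) || od <= 0) stop("od must be > 0", call. = FALSE)
  if (od > 0.05)
    warning("optical density above 0.05: inner-filter effects likely",
            call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("refractive index must be >= 1", call. = FALSE)
  structure(list(area = area, od = od, n = n), class = "qy_sample")
}

#' Relative quantum yield against a reference standard
#'
#' Computes `phi = (S/S_r) * (OD_r/OD) * (n/n_r)^2 * phi_r`, the standard
#' comparative method: emission areas are normalized by absorbed photons
#' (optical density) and corrected for the refractive-index difference
#' between the sample and reference solvents. POPOP in cyclohexane
#' (`phi_r = 0.97`) is the customary reference for this probe family.
#'
#' @param sample A [qy_sample()] for the unknown.
#' @param reference A [qy_sample()] for the reference standard.
#' @param phi_ref Quantum yield of the reference (default 0.97, POPOP in
#'   cyclohexane).
#' @return Quantum yield of the sample.
#' @export
quantum_yield <- function(sample, reference, phi_ref = 0.97) {
  stopifnot(inherits(sample, "qy_sample"), inherits(reference, "qy_sample"))
  if (phi_ref < 0 || phi_ref > 1)
    stop("phi_ref must lie in [0, 1]", call. = FALSE)
  (sample$area / reference$area) * (reference$od / sample$od) *
    (sample$n / reference$n)^2 * phi_ref
}

#' Radiative and non-radiative de-excitation rate constants
#'
#' From a quantum yield and a fluorescence lifetime: `kr = phi / tau` and
#' `knr = (1 - phi) / tau`. By construction `kr + knr = 1 / tau`.
#'
#' @param phi Quantum yield in \[0, 1\]. Vectorized.
#' @param tau Fluorescence lifetime in ns (> 0). Vectorized.
#' @return A list with components `kr` and `knr`, both in ns^-1.
#' @examples
#' rate_constants(0.61, 2.78)
#' @export
rate_constants <- function(phi, tau) {
  if (any(tau <= 0)) stop("lifetime must be > 0", call. = FALSE)
  if (any(phi < 0 | phi > 1)) stop("quantum yield must lie in [0, 1]", call. = FALSE)
  list(kr = phi / tau, knr = (1 - phi) / tau)
}

#' Molecular brightness
#'
#' Product of the molar extinction coefficient and the quantum yield,
#' conventionally rounded to the nearest 100 M^-1 cm^-1 for reporting.
#'
#' @param epsilon Molar extinction coefficient in M^-1 cm^-1 (> 0).
#' @param phi Quantum yield in \[0, 1\].
#' @param round_to Reporting granularity; 0 or less disables rounding.
#' @return Brightness in M^-1 cm^-1.
#' @export
brightness <- function(epsilon, phi, round_to = 100) {
  if (any(epsilon <= 0)) stop("epsilon must be > 0", call. = FALSE)
  if (any(phi < 0 | phi > 1)) stop("quantum yield must lie in [0, 1]", call. = FALSE)
  b <- epsilon * phi
  if (round_to > 0) b <- round_half_up(b / round_to) * round_to
  b
}

#' GP versus rotational relaxation time correlation
#'
#' Ordinary least-squares regression of GP on rotational relaxation time,
#' with the Pearson correlation coefficient. Used to ask whether hydration
#' (GP) and rotational order (relaxation time) change in a correlated way
#' across membrane compositions. 95% confidence bands follow from the
#' standard OLS formulae via `predict(fit$lm, interval = "confidence")`.
#'
#' @param relaxation_time Rotational relaxation times in ns (>= 3 values).
#' @param gp Matching GP values.
#' @return A list of class `gp_correlation` with `pearson_r`, `slope`,
#'   `intercept`, `slope_se`, `n` and the underlying `lm` fit.
#' @export
gp_relaxation_correlation <- function(relaxation_time, gp) {
  if (length(relaxation_time) != length(gp))
    stop("inputs must have the same length", call. = FALSE)
  if (length(gp) < 3L)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  if (stats::sd(relaxation_time) == 0 || stats::sd(gp) == 0)
    stop("insufficient data: zero variance on one axis", call. = FALSE)
  fit <- stats::lm(gp ~ relaxation_time)
  cf <- suppressWarnings(summary(fit))$coefficients  # exact lines are valid input
  structure(list(pearson_r = stats::cor(relaxation_time, gp),
                 slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
                 slope_se = unname(cf[2, 2]), n = length(gp), lm = fit),
            class = "gp_correlation")
}

#' @export
print.gp_correlation <- function(x, ...) {
  cat(sprintf("<gp_correlation> n = %d, r = %.3f, GP = %.4f + %.4f * theta\n",
              x$n, x$pearson_r, x$intercept, x$slope))
  invisible(x)
}

#' Probe identity record
#'
#' Name, formula and basic single-number photophysics (molar extinction
#' coefficient at 360 nm and quantum yield) of one probe.
#'
#' @param name,formula Probe name and molecular formula.
#' @param molecular_weight Molecular weight in g/mol.
#' @param epsilon_360 Molar extinction coefficient at 360 nm (M^-1 cm^-1, > 0).
#' @param phi Quantum yield in \[0, 1\].
#' @return An object of class `probe_record`.
#' @export
probe_record <- function(name, formula = NA_character_,
                         molecular_weight = NA_real_, epsilon_360, phi) {
  if (epsilon_360 <= 0) stop("epsilon_360 must be > 0", call. = FALSE)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, formula = formula,
                 molecular_weight = molecular_weight,
                 epsilon_360 = epsilon_360, phi = phi),
            class = "probe_record")
}

#' Half-up decimal rounding
#'
#' Rounds halves away from zero (the convention used for reported tables),
#' unlike [round()], which rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
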