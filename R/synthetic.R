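#' Two-band emission-spectrum model
#'
#' Generative model of a solvatochromic probe's emission: a blue locally
#' excited (LE) band near 440 nm and a red intramolecular-charge-transfer
#' (ICT) band near 490 nm, mixed by an ICT weight that grows with solvent
#' dielectric constant and jumps for hydrogen-bond-donating (polar-protic)
#' solvents. The default weight map `w = 0.15 + 0.005 * eps (+ 0.40 if
#' protic)`, clamped to \[0, 1\], is a package calibration chosen so that a
#' nonpolar solvent gives GP near +0.5 and a protic solvent with eps > 20
#' gives GP below -0.2, bracketing the observed solvent-class pattern.
#'
#' @param le_center,ict_center Band centers in nm.
#' @param le_width,ict_width Gaussian band widths (sd, nm).
#' @param base_weight,eps_coef,protic_bonus Coefficients of the
#'   ICT-weight map.
#' @param amplitude Peak-scale amplitude (arbitrary units).
#' @param noise_sd Additive Gaussian noise sd (same units as amplitude).
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(le_center = 440, ict_center = 490,
                           le_width = 25, ict_width = 25,
                           base_weight = 0.15, eps_coef = 0.005,
                           protic_bonus = 0.40, amplitude = 1,
                           noise_sd = 0.005) {
  if (le_center < 370 || le_center > 600 || ict_center < 370 || ict_center > 600)
    stop("band centers must lie within 370-600 nm", call. = FALSE)
  structure(list(le_center = le_center, ict_center = ict_center,
                 le_width = le_width, ict_width = ict_width,
                 base_weight = base_weight, eps_coef = eps_coef,
                 protic_bonus = protic_bonus, amplitude = amplitude,
                 noise_sd = noise_sd), class = "spectrum_model")
}

#' ICT band weight for a solvent
#'
#' @param model A [spectrum_model()].
#' @param solvent A [solvent_spec()].
#' @return ICT weight in \[0, 1\].
#' @export
ict_weight <- function(model, solvent) {
  w <- model$base_weight + model$eps_coef * solvent$epsilon +
    model$protic_bonus * (solvent$class == "polar-protic")
  min(max(w, 0), 1)
}

#' Generate a synthetic emission spectrum
#'
#' Samples the two-band model on the 370-600 nm grid (1 nm steps) for a
#' given solvent, with additive Gaussian noise (clipped at zero). With the
#' default calibration the GP read from the spectrum decreases strictly
#' with the dielectric constant along a dioxane/water ladder.
#'
#' @param model A [spectrum_model()].
#' @param solvent A [solvent_spec()].
#' @param seed Optional integer seed for the noise.
#' @param w Optional ICT weight override in \[0, 1\] (bypasses the solvent
#'   map; useful for limit checks).
#' @return An [emission_spectrum()] with solvent metadata.
#' @export
gen_spectrum <- function(model, solvent, seed = NULL, w = NULL) {
  stopifnot(inherits(model, "spectrum_model"), inherits(solvent, "solvent_spec"))
  if (is.null(w)) w <- ict_weight(model, solvent)
  if (w < 0 || w > 1) stop("ICT weight must lie in [0, 1]", call. = FALSE)
  wl <- 370:600
  shape <- (1 - w) * exp(-((wl - model$le_center) / model$le_width)^2 / 2) +
    w * exp(-((wl - model$ict_center) / model$ict_width)^2 / 2)
  y <- model$amplitude * shape
  if (model$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y + stats::rnorm(length(wl), sd = model$noise_sd), 0)
  }
  emission_spectrum(wl, y, excitation = 360,
                    meta = list(solvent = solvent$name,
                                epsilon = solvent$epsilon,
                                class = solvent$class, ict_weight = w))
}

#' Generate polarized intensities with known anisotropy
#'
#' Inverts the anisotropy equation: given a true anisotropy, a total
#' intensity `Ivv + 2 Ivh` and an instrumental G-factor, produces the four
#' polarizer-combination intensities such that
#' [steady_state_anisotropy()] recovers `r_true` exactly (to machine
#' precision) in the noiseless case. With `poisson = TRUE` each intensity
#' is Poisson-sampled, emulating photon-counting detection.
#'
#' @param r_true True anisotropy, in (-0.5, 1).
#' @param total_intensity Total intensity `Ivv + 2 Ivh` (counts).
#' @param g_true Instrumental G-factor (> 0).
#' @param poisson Add Poisson counting noise?
#' @param seed Optional integer seed.
#' @return A [polarized_intensities()] quadruple.
#' @export
gen_polarized <- function(r_true, total_intensity, g_true = 1,
                          poisson = FALSE, seed = NULL) {
  if (r_true <= -0.5 || r_true >= 1)
    stop("r_true must lie in (-0.5, 1)", call. = FALSE)
  if (g_true <= 0) stop("g_true must be > 0", call. = FALSE)
  # ivh from r = (ivv - g ivh)/(ivv + 2 g ivh) with ivv = T - 2 ivh
  ivh <- total_intensity * (1 - r_true) / (2 + g_true + 2 * r_true * (g_true - 1))
  ivv <- total_intensity - 2 * ivh
  ihh <- total_intensity / 2
  ihv <- g_true * ihh
  v <- c(ivv, ivh, ihv, ihh)
  if (poisson) {
    if (!is.null(seed)) set.seed(seed)
    v <- stats::rpois(4, v)
  }
  polarized_intensities(v[1], v[2], v[3], v[4])
}

#' Generate a sigmoidal thermal scan
#'
#' Boltzmann sigmoid sampled on the standard 10-60 degC / 2 degC grid with
#' Gaussian noise; defaults emulate a DPPC melting scan read in GP
#' (Tm = 41 degC, plateaus 0.55 -> -0.10).
#'
#' @param tm Transition midpoint in degC.
#' @param width Transition width in degC (> 0).
#' @param upper,lower High- and low-temperature plateaus.
#' @param temperatures Acquisition grid in degC.
#' @param noise_sd Gaussian noise sd.
#' @param seed Optional integer seed.
#' @param quantity `"GP"` or `"anisotropy"`.
#' @return A [thermal_scan()].
#' @export
gen_thermal_scan <- function(tm = 41, width = 1.5, upper = 0.55,
                             lower = -0.10, temperatures = seq(10, 60, by = 2),
                             noise_sd = 0.01, seed = NULL,
                             quantity = c("GP", "anisotropy")) {
  quantity <- match.arg(quantity)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  v <- lower + (upper - lower) / (1 + exp((temperatures - tm) / width))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  thermal_scan(temperatures, v, quantity = quantity)
}

#' Generate a one-site insertion trace
#'
#' Rectangular hyperbola `I(t) = imax * t / (t_half + t)` sampled on a
#' minute grid with Gaussian noise (relative to `imax`, clipped at zero).
#' At `t = 4 * t_half` the noiseless curve reaches 80% of the plateau.
#'
#' @param imax Plateau intensity.
#' @param t_half Half-insertion time in minutes (> 0).
#' @param duration Trace duration in minutes.
#' @param by Sampling step in minutes.
#' @param noise_sd Noise sd as a fraction of `imax` (e.g. 0.05 = 5%).
#' @param seed Optional integer seed.
#' @return A [kinetic_trace()].
#' @export
gen_insertion_trace <- function(imax = 100, t_half = 4.5, duration = 60,
                                by = 1, noise_sd = 0.05, seed = NULL) {
  if (t_half <= 0) stop("t_half must be > 0", call. = FALSE)
  t <- seq(0, duration, by = by)
  y <- imax * t / (t_half + t)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y + stats::rnorm(length(t), sd = noise_sd * imax), 0)
  }
  kinetic_trace(t, y)
}

#' Generate a spectral image stack with regions of known GP
#'
#' Builds a scene from a region-label matrix: within each region the 440
#' and 490 nm channel expectations solve the GP equation for the region's
#' true GP at its mean intensity (`I440 = I (1+GP)/2`, `I490 = I (1-GP)/2`),
#' and each pixel is Poisson-sampled. Remaining channels are filled from a
#' fixed template emission shape scaled to the region intensity, so the
#' stack looks like a full spectral acquisition. Regions with zero mean
#' intensity act as dark background.
#'
#' @param regions Integer matrix of region labels (values index
#'   `region_gp` / `region_intensity`; 0 = dark background).
#' @param region_gp True GP per region label, in \[-1, 1\].
#' @param region_intensity Mean summed 440+490 intensity (expected counts
#'   per pixel) per region label.
#' @param channel_centers Channel grid in nm (must include 440 and 490).
#' @param seed Optional integer seed for the Poisson sampling.
#' @param poisson Add Poisson noise? (`FALSE` gives expectations.)
#' @return A [spectral_stack()].
#' @export
gen_scene <- function(regions, region_gp, region_intensity,
                      channel_centers = seq(420, 600, by = 10), seed = NULL,
                      poisson = TRUE) {
  regions <- as.matrix(regions)
  labels <- sort(unique(regions[regions > 0]))
  if (length(region_gp) < max(c(labels, 0)) ||
      length(region_intensity) < max(c(labels, 0)))
    stop("region_gp / region_intensity must cover every region label",
         call. = FALSE)
  if (any(region_gp < -1 | region_gp > 1))
    stop("region GP values must lie in [-1, 1]", call. = FALSE)
  ka <- which(abs(channel_centers - 440) <= 1)[1]
  kb <- which(abs(channel_centers - 490) <= 1)[1]
  if (is.na(ka) || is.na(kb))
    stop("channel grid must include 440 and 490 nm", call. = FALSE)
  # template shape for the non-GP channels (broad two-band profile)
  template <- exp(-((channel_centers - 440) / 30)^2 / 2) +
    exp(-((channel_centers - 490) / 35)^2 / 2)
  template <- template / (template[ka] + template[kb])
  nr <- nrow(regions)
  nc <- ncol(regions)
  nch <- length(channel_centers)
  pix <- array(0, dim = c(nr, nc, nch))
  for (lab in labels) {
    sel <- regions == lab
    ia <- region_intensity[lab] * (1 + region_gp[lab]) / 2
    ib <- region_intensity[lab] * (1 - region_gp[lab]) / 2
    for (k in seq_len(nch)) {
      pix[, , k][sel] <- if (k == ka) ia else if (k == kb) ib else
        region_intensity[lab] * template[k]
    }
  }
  if (poisson) {
    if (!is.null(seed)) set.seed(seed)
    pix[] <- stats::rpois(length(pix), pix)
  }
  spectral_stack(pix, channel_centers)
}
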