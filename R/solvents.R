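#' Solvent specification
#'
#' Name, dielectric constant, refractive index and polarity class of a
#' solvent, the metadata the solvatochromism models consume.
#'
#' @param name Solvent name.
#' @param epsilon Static dielectric constant (>= 1).
#' @param n Refractive index (>= 1).
#' @param class One of `"nonpolar"`, `"polar-aprotic"`, `"polar-protic"`.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(name, epsilon, n = 1.4,
                         class = c("nonpolar", "polar-aprotic", "polar-protic")) {
  class <- match.arg(class)
  if (epsilon < 1) stop("dielectric constant must be >= 1", call. = FALSE)
  if (n < 1) stop("refractive index must be >= 1", call. = FALSE)
  structure(list(name = name, epsilon = epsilon, n = n, class = class),
            class = "solvent_spec")
}

#' Dielectric constant of a dioxane/water mixture
#'
#' Ideal (linear-in-mole-fraction) mixing between 1,4-dioxane
#' (eps = 2.2 at 20 degC) and water (eps = 80.1 at 20 degC). Such mixtures
#' emulate the polarity gradient across a bilayer, from the apolar core to
#' the hydrated head-group region.
#'
#' @param x_dioxane Mole fraction of dioxane in \[0, 1\].
#' @param eps_dioxane,eps_water Endpoint dielectric constants.
#' @return Dielectric constant of the mixture.
#' @export
mixture_dielectric <- function(x_dioxane, eps_dioxane = 2.2, eps_water = 80.1) {
  if (any(x_dioxane < 0 | x_dioxane > 1))
    stop("mole fraction must lie in [0, 1]", call. = FALSE)
  x_dioxane * eps_dioxane + (1 - x_dioxane) * eps_water
}

#' Dioxane mole fraction giving a target dielectric constant
#'
#' Exact inverse of [mixture_dielectric()]; the round trip is the identity.
#'
#' @param epsilon Target dielectric constant, within the endpoint range.
#' @param eps_dioxane,eps_water Endpoint dielectric constants.
#' @return Mole fraction of dioxane.
#' @export
mole_fraction_for_epsilon <- function(epsilon, eps_dioxane = 2.2,
                                      eps_water = 80.1) {
  lo <- min(eps_dioxane, eps_water)
  hi <- max(eps_dioxane, eps_water)
  if (any(epsilon < lo | epsilon > hi))
    stop(sprintf("target dielectric constant outside [%g, %g]", lo, hi),
         call. = FALSE)
  (eps_water - epsilon) / (eps_water - eps_dioxane)
}

#' Stokes shift in wavenumbers
#'
#' `10^7 * (1/lambda_abs - 1/lambda_em)` with wavelengths in nm; positive
#' when emission is red of absorption, as for these dyes.
#'
#' @param lambda_abs Absorption maximum in nm (> 0).
#' @param lambda_em Emission maximum in nm (> 0).
#' @return Stokes shift in cm^-1.
#' @export
stokes_shift_cm <- function(lambda_abs, lambda_em) {
  if (any(lambda_abs <= 0) || any(lambda_em <= 0))
    stop("wavelengths must be > 0", call. = FALSE)
  1e7 * (1 / lambda_abs - 1 / lambda_em)
}

#' Lippert-Mataga orientational polarizability
#'
#' `delta_f = (eps - 1)/(2 eps + 1) - (n^2 - 1)/(2 n^2 + 1)`: the solvent's
#' orientational (slow, dipolar) response with the electronic (fast,
#' refractive) part subtracted. It vanishes when `eps = n^2`, i.e. when the
#' solvent has no permanent-dipole response.
#'
#' @param epsilon Dielectric constant (>= 1). Vectorized.
#' @param n Refractive index (>= 1). Vectorized.
#' @return Orientational polarizability (dimensionless).
#' @export
orientational_polarizability <- function(epsilon, n) {
  if (any(epsilon < 1)) stop("dielectric constant must be >= 1", call. = FALSE)
  if (any(n < 1)) stop("refractive index must be >= 1", call. = FALSE)
  (epsilon - 1) / (2 * epsilon + 1) - (n^2 - 1) / (2 * n^2 + 1)
}

#' Lippert plot regression
#'
#' OLS line of Stokes shift (cm^-1) on orientational polarizability
#' delta_f. A common slope across dyes indicates a similar sensitivity to
#' solvent polarity (similar excited-state dipole change).
#'
#' @param delta_f Orientational polarizabilities (>= 3 points).
#' @param stokes_shift Stokes shifts in cm^-1, same length.
#' @return A list of class `lippert_fit` with `slope`, `intercept`,
#'   `r_squared`, `slope_se`, `n` and the `lm` fit.
#' @export
lippert_fit <- function(delta_f, stokes_shift) {
  if (length(delta_f) != length(stokes_shift))
    stop("inputs must have the same length", call. = FALSE)
  if (length(delta_f) < 3L)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  if (stats::sd(delta_f) == 0)
    stop("insufficient data: delta_f has zero variance", call. = FALSE)
  fit <- stats::lm(stokes_shift ~ delta_f)
  sm <- suppressWarnings(summary(fit))  # exactly collinear points are valid
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 slope_se = unname(sm$coefficients[2, 2]),
                 n = length(delta_f), lm = fit),
            class = "lippert_fit")
}

#' @export
print.lippert_fit <- function(x, ...) {
  cat(sprintf("<lippert_fit> slope = %.0f cm^-1, intercept = %.0f cm^-1, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
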