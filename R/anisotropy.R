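#' Polarized intensity quadruple
#'
#' The four polarizer-combination intensities of a steady-state anisotropy
#' measurement. The first subscript is the excitation polarizer, the second
#' the emission polarizer; v = vertical, h = horizontal.
#'
#' @param ivv,ivh,ihv,ihh Intensities (>= 0). `ihh > 0` is required to form
#'   the G-factor.
#' @return An object of class `polarized_intensities`.
#' @export
polarized_intensities <- function(ivv, ivh, ihv, ihh) {
  v <- c(ivv = ivv, ivh = ivh, ihv = ihv, ihh = ihh)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all four intensities must be finite and non-negative", call. = FALSE)
  structure(as.list(v), class = "polarized_intensities")
}

#' Instrumental G-factor
#'
#' `G = Ihv / Ihh` corrects the detection arm's polarization bias: with
#' horizontal excitation both emission polarizer settings see the same
#' photoselected population, so any intensity difference is instrumental.
#'
#' @param ihv Intensity, horizontal excitation / vertical emission.
#' @param ihh Intensity, horizontal excitation / horizontal emission (> 0).
#' @return The G-factor.
#' @export
g_factor <- function(ihv, ihh) {
  if (any(ihh <= 0)) stop("ihh must be > 0 to form the G-factor", call. = FALSE)
  ihv / ihh
}

#' G-factor-corrected steady-state anisotropy
#'
#' `r = (Ivv - G * Ivh) / (Ivv + 2 * G * Ivh)`. Mathematically r lies in
#' \[-0.5, 1\]; one-photon measurements of mobile fluorophores fall in the
#' physically meaningful band \[-0.2, 0.4\] (see [anisotropy_is_physical()]).
#'
#' @param p A [polarized_intensities()] quadruple, or the `ivv` intensity.
#' @param ivh Vertical/horizontal intensity when `p` is given as a number.
#' @param g G-factor; defaults to [g_factor()] of the quadruple's
#'   horizontal-excitation pair, or 1 for bare intensities.
#' @return Anisotropy r.
#' @export
steady_state_anisotropy <- function(p, ivh = NULL, g = NULL) {
  if (inherits(p, "polarized_intensities")) {
    if (is.null(g)) g <- g_factor(p$ihv, p$ihh)
    ivv <- p$ivv
    ivh <- p$ivh
  } else {
    ivv <- p
    if (is.null(ivh)) stop("ivh required", call. = FALSE)
    if (is.null(g)) g <- 1
  }
  den <- ivv + 2 * g * ivh
  if (any(den <= 0))
    stop("anisotropy undefined: total intensity is zero", call. = FALSE)
  (ivv - g * ivh) / den
}

#' Is an anisotropy value in the physically meaningful range?
#'
#' Flags values outside \[-0.2, 0.4\], the band attainable with one-photon
#' excitation of a randomly oriented population; values outside it usually
#' indicate scattering or G-factor problems. Informational only.
#'
#' @param r Anisotropy value(s).
#' @return Logical vector.
#' @export
anisotropy_is_physical <- function(r) r >= -0.2 & r <= 0.4

#' Perrin-Weber rotational relaxation time
#'
#' Inverts the Perrin relation `r0 / r = 1 + tau / theta` to
#' `theta = tau * r / (r0 - r)`: the steady-state anisotropy is depolarized
#' from its fundamental value r0 by rotation during the excited-state
#' lifetime. The intensity-weighted mean lifetime from [mean_lifetime()] is
#' the natural `tau` to pair with a steady-state `r`.
#'
#' @param r Measured anisotropy, `0 < r < r0`.
#' @param tau Fluorescence lifetime in ns (> 0).
#' @param r0 Fundamental (frozen) anisotropy; default 0.4, the collinear
#'   absorption/emission-dipole limit.
#' @return Rotational relaxation time theta in ns.
#' @examples
#' rotational_relaxation_time(0.2, 3)   # theta = tau at r = r0/2
#' @export
rotational_relaxation_time <- function(r, tau, r0 = 0.4) {
  if (any(tau <= 0)) stop("lifetime must be > 0", call. = FALSE)
  if (any(r <= 0)) stop("anisotropy must be > 0 for a finite theta", call. = FALSE)
  if (any(r >= r0))
    stop("immobile limit: r >= r0 implies an infinite relaxation time",
         call. = FALSE)
  tau * r / (r0 - r)
}
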