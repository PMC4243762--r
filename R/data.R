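#' Bundled probe identity table
#'
#' Formula, molecular weight, molar extinction coefficient at 360 nm,
#' quantum yield and brightness (all measured in chloroform) for the four
#' laurdan-family probes: laurdan, M-laurdan, MoC-laurdan and C-laurdan.
#'
#' @return A data frame with columns `name`, `formula`, `molecular_weight`
#'   (g/mol), `epsilon_360` (M^-1 cm^-1), `phi`, `brightness`.
#' @export
probe_table <- function() {
  utils::read.csv(system.file("extdata", "probes.csv", package = "probekit"),
                  stringsAsFactors = FALSE)
}

#' Bundled solvent photophysics table
#'
#' Quantum yield, lifetime (with fit chi-square), de-excitation rate
#' constants and GP of the four probes dissolved at 1 uM in seven pure
#' solvents spanning the three polarity classes.
#'
#' @return A data frame with columns `dye`, `solvent`, `solvent_class`,
#'   `epsilon`, `phi`, `chi2`, `tau_ns`, `kr`, `knr`, `gp`.
#' @export
solvent_photophysics <- function() {
  utils::read.csv(system.file("extdata", "solvent_photophysics.csv",
                              package = "probekit"),
                  stringsAsFactors = FALSE)
}

#' Bundled lipid-environment lifetime table
#'
#' One- and two-exponential TCSPC fit results (amplitude percentages,
#' component lifetimes, reduced chi-square and intensity-weighted mean
#' lifetime) for the four probes in twelve lipid-vesicle compositions at
#' 20 and 50 degC. Single-exponential rows carry `NA` in the second
#' component columns.
#'
#' @return A data frame with columns `dye`, `sample`, `temperature_c`,
#'   `chi2`, `alpha1_pct`, `tau1_ns`, `alpha2_pct`, `tau2_ns`,
#'   `mean_tau_ns`.
#' @export
lipid_lifetimes <- function() {
  utils::read.csv(system.file("extdata", "lipid_lifetimes.csv",
                              package = "probekit"),
                  stringsAsFactors = FALSE)
}

#' Bundled solvent property table
#'
#' Dielectric constants, refractive indices (20 degC) and polarity classes
#' of the pure solvents used across the package, plus water, 1,4-dioxane
#' and cyclohexane (the quantum-yield reference solvent).
#'
#' @return A data frame with columns `name`, `epsilon`, `n`, `class`.
#' @export
solvent_table <- function() {
  utils::read.csv(system.file("extdata", "solvents.csv", package = "probekit"),
                  stringsAsFactors = FALSE)
}

#' Solvent spec from the bundled table
#'
#' @param name Solvent name as listed in [solvent_table()].
#' @return A [solvent_spec()].
#' @export
lookup_solvent <- function(name) {
  tab <- solvent_table()
  i <- match(name, tab$name)
  if (is.na(i))
    stop(sprintf("unknown solvent '%s'; see solvent_table()", name),
         call. = FALSE)
  solvent_spec(tab$name[i], tab$epsilon[i], tab$n[i], tab$class[i])
}
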