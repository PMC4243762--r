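# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

two_band_spectrum <- function(w_ict = 0.3, amplitude = 1) {
  wl <- 370:600
  y <- amplitude * ((1 - w_ict) * exp(-((wl - 440) / 25)^2 / 2) +
                      w_ict * exp(-((wl - 490) / 25)^2 / 2))
  emission_spectrum(wl, y)
}

flat_noise_scan <- function(seed, level = 0.3, sd = 0.01) {
  set.seed(seed)
  thermal_scan(seq(10, 60, by = 2), level + stats::rnorm(26, sd = sd))
}

two_region_labels <- function(nr = 40, nc = 40) {
  reg <- matrix(1L, nr, nc)
  reg[, (nc %/% 2 + 1):nc] <- 2L
  reg
}
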