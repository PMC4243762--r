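#' Multi-channel spectral image stack
#'
#' Pixel intensities per emission channel, as produced by spectral imaging
#' (one pass from 420 to 600 nm in 10 nm steps on the two-photon
#' microscope). Pixels are stored row-major with the origin at the top-left;
#' channel `k` of the array is the image at `channel_centers[k]`.
#'
#' @param pixels Numeric array `rows x cols x channels` of intensities
#'   (>= 0), or a list of equally sized matrices (one per channel).
#' @param channel_centers Channel center wavelengths in nm, ascending,
#'   unique, one per channel.
#' @return An object of class `spectral_stack`.
#' @export
spectral_stack <- function(pixels, channel_centers) {
  if (is.list(pixels)) {
    dims <- unique(lapply(pixels, dim))
    if (length(dims) != 1L)
      stop("all channels must share one pixel grid shape", call. = FALSE)
    pixels <- array(unlist(pixels), dim = c(dims[[1]], length(pixels)))
  }
  if (length(dim(pixels)) != 3L)
    stop("pixels must be a rows x cols x channels array", call. = FALSE)
  channel_centers <- as.numeric(channel_centers)
  if (dim(pixels)[3] != length(channel_centers))
    stop("one channel center per channel plane required", call. = FALSE)
  if (any(duplicated(channel_centers)) || any(diff(channel_centers) <= 0))
    stop("channel centers must be unique and ascending", call. = FALSE)
  if (any(pixels < 0)) stop("pixel intensities must be >= 0", call. = FALSE)
  structure(list(pixels = pixels, channel_centers = channel_centers),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<spectral_stack> %d x %d pixels, %d channels (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$channel_centers), max(x$channel_centers)))
  invisible(x)
}

# Index of the channel whose center is nearest to `nm`, within +-1 nm.
match_channel <- function(stack, nm) {
  d <- abs(stack$channel_centers - nm)
  k <- which.min(d)
  if (d[k] > 1)
    stop(sprintf("no channel within 1 nm of %g nm (available: %s)",
                 nm, paste(stack$channel_centers, collapse = ", ")),
         call. = FALSE)
  k
}

#' Per-pixel GP map from a spectral stack
#'
#' Applies the GP formula pixelwise to the 440 and 490 nm channel images:
#' `GP = (I_a - I_b) / (I_a + I_b)`. Pixels whose summed channel intensity
#' falls below `min_total_intensity` (or is zero) are masked out and carry
#' no GP value. Channels are matched by nearest center within 1 nm, i.e.
#' the 10-nm microscope channels are read as single planes, not band sums.
#'
#' @param stack A [spectral_stack()].
#' @param ch_a,ch_b Channel center wavelengths in nm (default 440 / 490).
#' @param min_total_intensity Mask threshold on `I_a + I_b` (default 0:
#'   only zero-intensity pixels are masked).
#' @param background Scalar background to subtract from each channel before
#'   the ratio (clamped at zero), default 0.
#' @return An object of class `gp_map` with matrices `gp` (NA where
#'   masked) and `mask`, plus the threshold and channels used.
#' @export
gp_map <- function(stack, ch_a = 440, ch_b = 490, min_total_intensity = 0,
                   background = c(0, 0)) {
  stopifnot(inherits(stack, "spectral_stack"))
  ia <- pmax(stack$pixels[, , match_channel(stack, ch_a)] - background[1], 0)
  ib <- pmax(stack$pixels[, , match_channel(stack, ch_b)] - background[2], 0)
  tot <- ia + ib
  mask <- tot >= min_total_intensity & tot > 0
  gp <- matrix(NA_real_, nrow(tot), ncol(tot))
  gp[mask] <- (ia[mask] - ib[mask]) / tot[mask]
  structure(list(gp = gp, mask = mask, threshold = min_total_intensity,
                 channels = c(ch_a, ch_b)), class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  cat(sprintf("<gp_map> %d x %d, %d/%d pixels unmasked (threshold %g)\n",
              nrow(x$gp), ncol(x$gp), sum(x$mask), length(x$mask),
              x$threshold))
  invisible(x)
}

#' Total fluorescence image over a spectral band
#'
#' Per-pixel sum of all channels whose centers fall inside `band`
#' (inclusive); the default sums the whole stack, the usual companion
#' image to a GP map.
#'
#' @param stack A [spectral_stack()].
#' @param band `c(lo, hi)` in nm.
#' @return Matrix of per-pixel summed intensities.
#' @export
total_fluorescence <- function(stack, band = range(stack$channel_centers)) {
  stopifnot(inherits(stack, "spectral_stack"))
  sel <- stack$channel_centers >= band[1] & stack$channel_centers <= band[2]
  if (!any(sel)) stop("empty band: no channels selected", call. = FALSE)
  apply(stack$pixels[, , sel, drop = FALSE], c(1, 2), sum)
}

#' GP distribution of a map
#'
#' Histogram of unmasked per-pixel GP values over \[-1, 1\] plus summary
#' statistics. The mode is reported as the midpoint of the fullest bin.
#'
#' @param map A [gp_map()].
#' @param bins Number of equal-width bins over \[-1, 1\].
#' @return A list with `breaks`, `counts`, `mids`, `mean`, `median`,
#'   `mode` and `n_pixels`.
#' @export
gp_histogram <- function(map, bins = 40) {
  stopifnot(inherits(map, "gp_map"))
  v <- map$gp[map$mask]
  if (length(v) == 0L)
    stop("empty map: no unmasked pixels", call. = FALSE)
  breaks <- seq(-1, 1, length.out = bins + 1)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       mean = mean(v), median = stats::median(v),
       mode = h$mids[which.max(h$counts)], n_pixels = length(v))
}
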