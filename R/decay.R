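#' Multi-exponential decay components
#'
#' Normalized pre-exponential fractions `alpha` and lifetimes `tau` of a sum
#' of exponentials. Fractions must sum to 1; lifetimes are in ns.
#'
#' @param alpha Pre-exponential fractions in (0, 1\]; must sum to 1 within
#'   1e-9 unless `normalize = TRUE`.
#' @param tau Lifetimes in ns (> 0), same length as `alpha`.
#' @param normalize If `TRUE`, rescale `alpha` to sum to 1.
#' @return An object of class `decay_components`.
#' @examples
#' decay_components(c(0.56, 0.44), c(6.18, 0.53))
#' @export
decay_components <- function(alpha, tau, normalize = FALSE) {
  alpha <- as.numeric(alpha)
  tau <- as.numeric(tau)
  if (length(alpha) == 0L) stop("empty component list", call. = FALSE)
  if (length(alpha) != length(tau))
    stop("alpha and tau must have the same length", call. = FALSE)
  if (any(tau <= 0)) stop("lifetimes must be > 0", call. = FALSE)
  if (any(alpha <= 0)) stop("amplitude fractions must be > 0", call. = FALSE)
  if (normalize) alpha <- alpha / sum(alpha)
  if (abs(sum(alpha) - 1) > 1e-9)
    stop("amplitude fractions must sum to 1 (use normalize = TRUE)",
         call. = FALSE)
  structure(list(alpha = alpha, tau = tau), class = "decay_components")
}

#' Amplitude-normalized multi-exponential decay model
#'
#' Evaluates `I(t) = sum_i alpha_i * exp(-t / tau_i)`, the impulse-response
#' model underlying TCSPC analysis. `I(0) = 1` because the fractions sum
#' to 1.
#'
#' @param components A [decay_components()] object.
#' @param t Times in ns (>= 0). Vectorized.
#' @return Model intensity at `t`.
#' @export
decay_model <- function(components, t) {
  stopifnot(inherits(components, "decay_components"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  drop(exp(-outer(t, components$tau, "/")) %*% components$alpha)
}

#' Intensity-weighted mean fluorescence lifetime
#'
#' `<tau> = sum(alpha_i * tau_i^2) / sum(alpha_i * tau_i)`, the mean of the
#' component lifetimes weighted by their steady-state intensity
#' contributions `alpha_i * tau_i`. For a single component it returns that
#' lifetime exactly; in general it lies between the smallest and largest
#' component lifetime.
#'
#' @param components A [decay_components()] object.
#' @return Mean lifetime in ns.
#' @examples
#' mean_lifetime(decay_components(c(0.56, 0.44), c(6.18, 0.53)))  # 5.82 ns
#' @export
mean_lifetime <- function(components) {
  stopifnot(inherits(components, "decay_components"))
  a <- components$alpha
  tau <- components$tau
  sum(a * tau^2) / sum(a * tau)
}

#' TCSPC decay histogram
#'
#' Counts per uniformly spaced time bin, optionally paired with an
#' instrument-response histogram on the same bins. Counts are photon counts
#' in measured data; noiseless model expectations (non-integer) are also
#' accepted so exact-model fits can be expressed.
#'
#' @param bin_centers Bin centers in ns, uniformly spaced, ascending.
#' @param counts Non-negative counts per bin.
#' @param irf Optional instrument-response values on the same bins (used as
#'   a shape; normalized internally).
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(bin_centers, counts, irf = NULL) {
  bin_centers <- as.numeric(bin_centers)
  counts <- as.numeric(counts)
  if (length(bin_centers) != length(counts))
    stop("bin_centers and counts must have the same length", call. = FALSE)
  if (length(bin_centers) < 3L) stop("too few bins", call. = FALSE)
  dw <- diff(bin_centers)
  if (any(dw <= 0) || diff(range(dw)) > 1e-8 * dw[1])
    stop("bins must be uniform and ascending", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(irf)) {
    irf <- as.numeric(irf)
    if (length(irf) != length(counts))
      stop("IRF must have the same number of bins as the decay", call. = FALSE)
    if (any(irf < 0) || sum(irf) <= 0)
      stop("IRF must be non-negative with positive total", call. = FALSE)
  }
  structure(list(bin_centers = bin_centers, counts = counts, irf = irf,
                 bin_width = dw[1], total_counts = sum(counts)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins x %.4g ns, %.4g counts%s\n",
              length(x$counts), x$bin_width, x$total_counts,
              if (is.null(x$irf)) "" else ", with IRF"))
  invisible(x)
}

# Discrete linear convolution with a normalized IRF shape (same bin grid).
convolve_irf <- function(y, irf) {
  n <- length(y)
  k <- irf / sum(irf)
  stats::convolve(y, rev(k), type = "open")[seq_len(n)]
}

#' Gaussian instrument response on a TCSPC bin grid
#'
#' @param n_bins Number of bins.
#' @param bin_width Bin width in ns.
#' @param center Pulse center in ns.
#' @param fwhm Full width at half maximum in ns.
#' @return Numeric vector of length `n_bins` (unit area).
#' @export
gaussian_irf <- function(n_bins = 1024, bin_width = 0.05, center = 2,
                         fwhm = 0.5) {
  t <- (seq_len(n_bins) - 0.5) * bin_width
  y <- stats::dnorm(t, mean = center, sd = fwhm / (2 * sqrt(2 * log(2))))
  y / sum(y)
}

#' Simulate a Poisson-noised TCSPC measurement
#'
#' Forward model of the photon-counting instrument: the multi-exponential
#' impulse response is evaluated on the bin grid, convolved with the IRF
#' when one is given, scaled to the requested total expected counts, and
#' Poisson-sampled per bin. Fixing the seed makes the histogram bit-for-bit
#' reproducible.
#'
#' @param components A [decay_components()] object (the true decay).
#' @param irf Optional IRF shape on the same bin grid (e.g. from
#'   [gaussian_irf()]).
#' @param total_counts Expected total photon count (> 0).
#' @param n_bins,bin_width Histogram geometry (default 1024 x 0.05 ns).
#' @param seed Optional integer seed for the Poisson sampling.
#' @param poisson If `FALSE`, return the noiseless expectation instead of a
#'   Poisson draw.
#' @return A [decay_histogram()] carrying the IRF when one was supplied.
#' @export
simulate_decay <- function(components, irf = NULL, total_counts = 1e6,
                           n_bins = 1024, bin_width = 0.05, seed = NULL,
                           poisson = TRUE) {
  stopifnot(inherits(components, "decay_components"))
  if (total_counts <= 0) stop("total_counts must be > 0", call. = FALSE)
  if (!is.null(irf) && length(irf) != n_bins)
    stop("IRF length must equal n_bins", call. = FALSE)
  t <- (seq_len(n_bins) - 0.5) * bin_width
  expected <- decay_model(components, t)
  if (!is.null(irf)) expected <- convolve_irf(expected, irf)
  expected <- pmax(expected, 0) * total_counts / sum(expected)
  if (poisson) {
    if (!is.null(seed)) set.seed(seed)
    counts <- stats::rpois(n_bins, expected)
  } else {
    counts <- expected
  }
  decay_histogram(t, counts, irf = irf)
}

# Tail log-linear starting guesses: slow lifetime from the late part of the
# fitting window, fast lifetime from the early part.
decay_start_values <- function(t, counts, n) {
  pos <- which(counts > 0)
  fit_seg <- function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    sl <- stats::coef(stats::lm(log(counts[idx]) ~ t[idx]))[2]
    if (is.na(sl) || sl >= 0) NA_real_ else -1 / sl
  }
  late <- pos[pos >= stats::quantile(pos, 0.5)]
  tau_slow <- fit_seg(late)
  if (is.na(tau_slow)) tau_slow <- diff(range(t)) / 3
  if (n == 1L) return(list(tau = tau_slow, A = max(counts)))
  early <- pos[pos <= stats::quantile(pos, 0.15)]
  tau_fast <- fit_seg(early)
  if (is.na(tau_fast) || tau_fast >= tau_slow / 1.5) tau_fast <- tau_slow / 5
  list(tau = c(tau_slow, tau_fast), A = rep(max(counts) / 2, 2))
}

#' Fit a sum of exponentials to a TCSPC histogram
#'
#' Weighted least squares in the Poisson (Neyman) approximation: residuals
#' are `(model - counts) / sqrt(max(counts, 1))`, so empty bins get unit
#' variance. When the histogram carries an IRF the model is reconvolved
#' with it and the fit spans the full histogram (the rise encodes the pulse
#' position); without an IRF a tail fit from the peak bin to the last
#' occupied bin is performed. Free parameters are log-lifetimes and
#' log-amplitudes (Levenberg-Marquardt); amplitudes are renormalized to
#' fractions summing to 1 and components are sorted by descending lifetime.
#'
#' @param hist A [decay_histogram()].
#' @param n_components 1 or 2 exponential components.
#' @param fit_range Optional `c(tmin, tmax)` in ns overriding the default
#'   fitting window.
#' @return An object of class `decay_fit` with elements `components`
#'   ([decay_components()]), `chi2` (reduced chi-square), `mean_tau`,
#'   `n_components`, `scale` and `window`.
#' @export
fit_decay <- function(hist, n_components = 1, fit_range = NULL) {
  stopifnot(inherits(hist, "decay_histogram"))
  n <- as.integer(n_components)
  if (n > 2L)
    stop("unsupported: at most 2 exponential components", call. = FALSE)
  if (n < 1L) stop("n_components must be 1 or 2", call. = FALSE)
  t <- hist$bin_centers
  counts <- hist$counts
  irf <- hist$irf

  occupied <- which(counts >= 1)
  if (length(occupied) == 0L) stop("empty histogram", call. = FALSE)
  i1 <- if (is.null(irf)) which.max(counts) else 1L
  i2 <- max(occupied)
  if (!is.null(fit_range)) {
    i1 <- max(1L, which(t >= fit_range[1])[1])
    i2 <- max(which(t <= fit_range[2]))
  }
  win <- i1:i2
  if (length(win) < 10L * 2L * n)
    stop("too few bins in the fitting window for the requested model",
         call. = FALSE)
  w <- sqrt(pmax(counts[win], 1))

  model_counts <- function(tau, A) {
    y <- drop(exp(-outer(t, tau, "/")) %*% A)
    if (!is.null(irf)) y <- convolve_irf(y, irf)
    y
  }
  resfun <- function(p) {
    tau <- exp(p[seq_len(n)])
    A <- exp(p[n + seq_len(n)])
    (model_counts(tau, A)[win] - counts[win]) / w
  }
  st <- decay_start_values(t[win], counts[win], n)
  p0 <- log(c(st$tau, st$A))
  fit <- minpack.lm::nls.lm(par = p0, fn = resfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-12, ptol = 1e-12))
  if (!(fit$info %in% 1:4)) {
    cond <- structure(
      class = c("probekit_fit_failure", "error", "condition"),
      list(message = paste0("decay fit did not converge: ", fit$message),
           call = sys.call(-1), last_par = exp(fit$par)))
    stop(cond)
  }
  tau <- exp(fit$par[seq_len(n)])
  A <- exp(fit$par[n + seq_len(n)])
  ord <- order(tau, decreasing = TRUE)
  tau <- tau[ord]
  A <- A[ord]
  comps <- decay_components(A / sum(A), tau)
  dof <- max(length(win) - 2L * n, 1L)
  structure(list(components = comps,
                 chi2 = sum(fit$fvec^2) / dof,
                 mean_tau = mean_lifetime(comps),
                 n_components = n, scale = sum(A),
                 window_ns = t[c(i1, i2)]),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d component(s), reduced chi2 = %.3f, <tau> = %.3f ns\n",
              x$n_components, x$chi2, x$mean_tau))
  for (i in seq_along(x$components$tau))
    cat(sprintf("  alpha%d = %5.1f%%  tau%d = %.3f ns\n",
                i, 100 * x$components$alpha[i], i, x$components$tau[i]))
  invisible(x)
}

#' Choose between 1- and 2-component decay models
#'
#' Fits the histogram with 1..`max_components` exponentials and accepts a
#' larger model only when it improves the reduced chi-square by more than a
#' relative threshold (default 10%). A 2-component fit that fails to
#' converge falls back to the 1-component model.
#'
#' @param hist A [decay_histogram()].
#' @param max_components Largest model to consider (<= 2).
#' @param chi2_improvement_threshold Minimum relative chi-square improvement
#'   required to accept each additional component.
#' @return A list with `n_components`, the chosen `fit`, all `fits`, and
#'   the relative `improvement` of the larger over the smaller model.
#' @export
select_model <- function(hist, max_components = 2,
                         chi2_improvement_threshold = 0.1) {
  fits <- list(fit_decay(hist, 1))
  chosen <- 1L
  improvement <- NA_real_
  if (max_components >= 2L) {
    f2 <- tryCatch(fit_decay(hist, 2), error = function(e) NULL)
    if (!is.null(f2)) {
      fits[[2]] <- f2
      improvement <- (fits[[1]]$chi2 - f2$chi2) / fits[[1]]$chi2
      if (is.finite(improvement) && improvement > chi2_improvement_threshold)
        chosen <- 2L
    }
  }
  list(n_components = chosen, fit = fits[[chosen]], fits = fits,
       improvement = improvement)
}
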