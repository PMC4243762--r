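#' Temperature scan of GP or anisotropy
#'
#' A temperature-indexed series of GP or anisotropy values, the raw
#' material of a melting-transition analysis. The canonical acquisition
#' grid is 10-60 degC in 2 degC steps.
#'
#' @param temperatures Temperatures in degC, strictly ascending, >= 6 points.
#' @param values GP or anisotropy values, same length.
#' @param quantity `"GP"` or `"anisotropy"`.
#' @return An object of class `thermal_scan`.
#' @export
thermal_scan <- function(temperatures, values, quantity = c("GP", "anisotropy")) {
  quantity <- match.arg(quantity)
  temperatures <- as.numeric(temperatures)
  values <- as.numeric(values)
  if (length(temperatures) != length(values))
    stop("temperatures and values must have the same length", call. = FALSE)
  if (length(temperatures) < 6L)
    stop("a thermal scan needs at least 6 points", call. = FALSE)
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly ascending", call. = FALSE)
  structure(list(temperatures = temperatures, values = values,
                 quantity = quantity), class = "thermal_scan")
}

#' Fit a melting transition to a thermal scan
#'
#' Least-squares fit of a descending Boltzmann sigmoid
#' `v(T) = lower + (upper - lower) / (1 + exp((T - Tm)/w))`: GP and
#' anisotropy both fall steeply when a bilayer melts from the gel (So) to
#' the fluid (Ld) phase, and Tm is the midpoint of that fall. A transition
#' is reported as `detected` only when the fitted amplitude exceeds three
#' times the residual RMSE and Tm lies inside the scanned range, so flat
#' scans (pure Lo, or a probe blind to the transition) return
#' `detected = FALSE` rather than a spurious Tm.
#'
#' Initialization: Tm at the steepest finite-difference descent, plateaus
#' from the first and last three points, width 1/10 of the scanned range.
#'
#' @param scan A [thermal_scan()].
#' @return An object of class `transition_fit` with `tm`, `width`,
#'   `upper_plateau`, `lower_plateau`, `detected`, `rmse`, `converged` and
#'   the `fitted` curve.
#' @export
fit_transition <- function(scan) {
  stopifnot(inherits(scan, "thermal_scan"))
  temp <- scan$temperatures
  v <- scan$values
  span <- diff(range(temp))
  d <- diff(v) / diff(temp)
  tm0 <- mean(temp[which.min(d) + 0:1])
  upper0 <- mean(v[1:3])
  lower0 <- mean(v[length(v) - 2:0])
  if (upper0 <= lower0) upper0 <- lower0 + 1e-3
  df <- data.frame(temp = temp, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ p_lo + (p_up - p_lo) / (1 + exp((temp - tm) / w)),
      data = df,
      start = list(p_lo = lower0, p_up = upper0, tm = tm0, w = span / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tm = NA_real_, width = NA_real_,
                          upper_plateau = NA_real_, lower_plateau = NA_real_,
                          detected = FALSE, rmse = NA_real_,
                          converged = FALSE, fitted = NULL,
                          quantity = scan$quantity),
                     class = "transition_fit"))
  }
  cf <- stats::coef(fit)
  up <- cf[["p_up"]]
  lo <- cf[["p_lo"]]
  w_ <- cf[["w"]]
  if (w_ < 0) {  # mirrored parameterization of the same curve
    tmp <- up
    up <- lo
    lo <- tmp
    w_ <- -w_
  }
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  amplitude <- up - lo
  detected <- amplitude > 3 * rmse &&
    cf[["tm"]] > min(temp) && cf[["tm"]] < max(temp)
  structure(list(tm = cf[["tm"]], width = w_,
                 upper_plateau = up, lower_plateau = lo,
                 detected = detected, rmse = rmse, converged = TRUE,
                 fitted = stats::fitted(fit), quantity = scan$quantity),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<transition_fit> Tm = %.2f degC, width = %.2f degC, plateaus %.3f -> %.3f (rmse %.2g)\n",
                x$tm, x$width, x$upper_plateau, x$lower_plateau, x$rmse))
  else
    cat("<transition_fit> no transition detected\n")
  invisible(x)
}

#' Probe-insertion kinetic trace
#'
#' Fluorescence intensity versus time after injecting probe onto vesicles:
#' intensity rises from near zero as the dye partitions into the bilayer
#' and plateaus once insertion is complete.
#'
#' @param times Times in minutes (>= 0), strictly ascending, >= 5 points.
#' @param intensities Intensities (>= 0), same length.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, intensities) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("times and intensities must have the same length", call. = FALSE)
  if (length(times) < 5L)
    stop("a kinetic trace needs at least 5 points", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly ascending", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(times = times, intensities = intensities),
            class = "kinetic_trace")
}

#' One-site insertion-kinetics fit
#'
#' Least-squares fit of the rectangular hyperbola through the origin,
#' `I(t) = Imax * t / (t_half + t)` (the one-site saturation-binding form):
#' `I(t_half) = Imax / 2` by construction, so `t_half` is the half-insertion
#' time. The fit is flagged `poorly_determined` when the standard error of
#' `t_half` exceeds half its estimate, which happens when the trace only
#' samples times well past the half-rise.
#'
#' @param trace A [kinetic_trace()].
#' @return An object of class `insertion_fit` with `imax`, `t_half`,
#'   `t_half_se`, `rmse` and `poorly_determined`.
#' @export
fit_insertion <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times
  y <- trace$intensities
  if (stats::cor(t, y) < 0)
    stop("fit failure: trace is decreasing, not an insertion curve",
         call. = FALSE)
  half <- max(y) / 2
  i_half <- which(y >= half)[1]
  if (is.na(i_half) || t[i_half] >= max(t))
    stop("fit failure: no point beyond the apparent half-rise", call. = FALSE)
  th0 <- max(t[i_half], min(t[t > 0]))
  resfun <- function(p) p[1] * t / (p[2] + t) - y
  fit <- minpack.lm::nls.lm(par = c(imax = 1.05 * max(y), th = th0),
                            fn = resfun, lower = c(1e-12, 1e-9),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  imax <- fit$par[[1]]
  t_half <- fit$par[[2]]
  dof <- max(length(t) - 2L, 1L)
  sigma2 <- sum(fit$fvec^2) / dof
  # covariance from the final Jacobian; a singular one means t_half is
  # unidentified by the sampled time range
  J <- cbind(t / (t_half + t), -imax * t / (t_half + t)^2)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  t_half_se <- if (is.null(cov)) Inf else sqrt(cov[2, 2])
  structure(list(imax = imax, t_half = t_half,
                 t_half_se = t_half_se,
                 rmse = sqrt(mean(fit$fvec^2)),
                 poorly_determined = is.na(t_half_se) ||
                   t_half_se > 0.5 * t_half),
            class = "insertion_fit")
}

#' @export
print.insertion_fit <- function(x, ...) {
  cat(sprintf("<insertion_fit> Imax = %.3g, t_half = %.2f min (se %.2g)%s\n",
              x$imax, x$t_half, x$t_half_se,
              if (x$poorly_determined) " [poorly determined]" else ""))
  invisible(x)
}
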