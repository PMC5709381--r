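#' Time- and ensemble-averaged mean squared displacement
#'
#' Computes the lateral (x, y) MSD over all sliding time origins and all
#' selected particles, on the frame-time grid:
#' `MSD(k dt) = < |r(t + k dt) - r(t)|^2 >_{t, particles}`.
#' The sliding-origin sums are evaluated with the FFT autocorrelation
#' identity, so all lags cost `O(T log T)` per particle. An initial
#' equilibration stretch (`discard_initial`, default 50 ns) is removed
#' before analysis; the trajectory must be unwrapped (or carry its unwrapped
#' copy) and should have net drift removed ([remove_com_motion()]).
#'
#' @param traj an [mc_trajectory()].
#' @param selection integer particle indices, or a species name; default all
#'   particles.
#' @param max_lag largest lag in ns; default half the analysed duration.
#' @param discard_initial initial time to drop (ns).
#' @param lag_thin keep every frame-lag up to `lag_thin` frames, then
#'   log-spaced lags (about 50 per decade); `Inf` keeps every lag.
#' @return an `msd_curve`: data frame with `lag` (ns), `msd` (nm^2) and
#'   `n_samples` (particle-origin pairs per point).
#' @export
compute_msd <- function(traj, selection = NULL, max_lag = NULL,
                        discard_initial = 50, lag_thin = 100L) {
  stopifnot(inherits(traj, "mc_trajectory"))
  sel <- resolve_selection(traj, selection)
  if (length(sel) == 0L)
    mc_stop("'selection' matches no particles", "mc_argument_error")
  co <- unwrapped_coords(traj, "compute_msd")
  skip <- floor(discard_initial / traj$dt)
  if (skip >= n_frames(traj) - 1L)
    mc_stop("'discard_initial' leaves fewer than 2 frames",
            "mc_argument_error")
  frames <- (skip + 1L):n_frames(traj)
  T <- length(frames)
  duration <- (T - 1L) * traj$dt
  max_lag <- max_lag %||% (duration / 2)
  kmax <- min(T - 1L, max(1L, floor(max_lag / traj$dt)))
  msd <- numeric(kmax)
  # FFT sliding-origin MSD, accumulated over particles in chunks
  chunk <- max(1L, as.integer(2^21 / T))
  for (s in seq(1L, length(sel), by = chunk)) {
    cols <- sel[s:min(s + chunk - 1L, length(sel))]
    acc <- matrix(0, T - 1L, length(cols))
    for (k in 1:2) {
      x <- co[frames, cols, k, drop = FALSE]
      dim(x) <- c(T, length(cols))
      acc <- acc + msd_1d_fft(x)
    }
    msd <- msd + rowSums(acc)[1:kmax]
  }
  msd <- msd / length(sel)
  lags_f <- seq_len(kmax)
  keep <- thin_lags(lags_f, lag_thin)
  out <- data.frame(lag = lags_f[keep] * traj$dt, msd = msd[keep],
                    n_samples = (T - lags_f[keep]) * length(sel))
  species <- unique(traj$topology$species[sel])
  attr(out, "species") <- if (length(species) == 1L) species else "mixed"
  attr(out, "dt") <- traj$dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

# per-particle time-averaged MSD for one dimension; x is T x P
# msd(k) = (S1(k) - 2*S2(k)) / (T - k),  S2 by FFT autocorrelation
msd_1d_fft <- function(x) {
  T <- nrow(x); P <- ncol(x)
  pad <- rbind(x, matrix(0, T, P))
  A <- stats::mvfft(pad)
  S2 <- Re(stats::mvfft(A * Conj(A), inverse = TRUE))[1:T, , drop = FALSE] /
    (2 * T)
  sq <- x^2
  Q <- 2 * colSums(sq)
  head_c <- apply(sq, 2L, cumsum)
  tail_c <- apply(sq[T:1, , drop = FALSE], 2L, cumsum)
  k <- seq_len(T - 1L)
  S1 <- matrix(Q, T - 1L, P, byrow = TRUE) -
    head_c[k, , drop = FALSE] - tail_c[k, , drop = FALSE]
  (S1 - 2 * S2[k + 1L, , drop = FALSE]) /
    matrix(T - k, T - 1L, P)
}

thin_lags <- function(lags, lag_thin) {
  if (!is.finite(lag_thin) || max(lags) <= lag_thin) return(rep(TRUE, length(lags)))
  logs <- unique(round(10^seq(log10(lag_thin), log10(max(lags)),
                              by = 0.02)))
  # always keep the endpoint so stated fit ranges are fully covered
  lags <= lag_thin | lags %in% logs | lags == max(lags)
}

resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(n_particles(traj)))
  if (is.character(selection))
    return(which(traj$topology$species %in% selection |
                   traj$topology$role %in% selection))
  as.integer(selection)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %s: %d lags, %g to %g ns\n",
              attr(x, "species"), nrow(x), min(x$lag), max(x$lag)))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$lag, x$msd, log = log, xlab = expression(Delta * t ~ "(ns)"),
                 ylab = expression(MSD ~ (nm^2)), type = "l", ...)
  invisible(x)
}

#' Fit the anomalous-diffusion model MSD = 4 D Δt^α
#'
#' Nonlinear least squares of the two-dimensional anomalous diffusion law
#' `MSD(dt) = 4 * D_alpha * dt^alpha` to an [compute_msd()] curve, over the
#' lag range `[fit_min, fit_max]` (defaults 1 ns to 2 us, the conventional
#' window for microsecond-scale membrane trajectories). The optimizer is
#' Levenberg-Marquardt, initialized from the ordinary log-log regression;
#' parameter standard deviations come from the fit covariance. If the curve
#' is shorter than `fit_max` the range clamps to the data with a warning.
#'
#' @param curve an `msd_curve`, or any data frame with `lag` and `msd`.
#' @param fit_min,fit_max fit range in ns.
#' @param weights optional per-point weights for weighted least squares;
#'   default unweighted.
#' @return an object of class `anomalous_fit` with components `D_alpha`,
#'   `alpha`, `sd` (named standard deviations), `fit_range`, `fit` (the
#'   underlying `nls` object) and the fitted subset of the curve.
#' @seealso [alpha_profile()], [compute_msd()]; methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @export
fit_anomalous <- function(curve, fit_min = 1, fit_max = 2000,
                          weights = NULL) {
  if (fit_max > max(curve$lag)) {
    mc_warn(sprintf(
      "fit range clamped to available lags: %g -> %g ns",
      fit_max, max(curve$lag)), "mc_fit_range_warning")
    fit_max <- max(curve$lag)
  }
  sub <- curve[curve$lag >= fit_min & curve$lag <= fit_max, , drop = FALSE]
  if (nrow(sub) < 5L)
    mc_stop("need at least 5 lag points in the fit range",
            "mc_argument_error")
  if (any(sub$msd <= 0))
    mc_stop("MSD must be positive throughout the fit range",
            "mc_fit_domain_error")
  ll <- stats::lm(log(msd) ~ log(lag), data = sub)
  start <- list(D = exp(unname(stats::coef(ll)[1])) / 4,
                alpha = unname(stats::coef(ll)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ 4 * D * lag^alpha, data = sub, start = start,
                      weights = weights %||% rep(1, nrow(sub)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) mc_stop(
      sprintf("anomalous fit did not converge: %s", conditionMessage(e)),
      "mc_fit_error"))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(
    D_alpha = unname(est["D"]), alpha = unname(est["alpha"]),
    sd = c(D_alpha = unname(se["D"]), alpha = unname(se["alpha"])),
    fit_range = c(fit_min, fit_max), fit = fit, curve = sub,
    species = attr(curve, "species") %||% "unknown"
  ), class = "anomalous_fit")
}

#' @export
print.anomalous_fit <- function(x, digits = 4, ...) {
  cat("Anomalous diffusion fit: MSD = 4 * D_alpha * dt^alpha\n")
  cat(sprintf("  species:   %s\n", x$species))
  cat(sprintf("  fit range: %g to %g ns (%d points)\n",
              x$fit_range[1], x$fit_range[2], nrow(x$curve)))
  cat(sprintf("  D_alpha = %s (sd %s) nm^2/ns^alpha\n",
              format(x$D_alpha, digits = digits),
              format(x$sd["D_alpha"], digits = 2)))
  cat(sprintf("  alpha   = %s (sd %s)\n",
              format(x$alpha, digits = digits),
              format(x$sd["alpha"], digits = 2)))
  invisible(x)
}

#' @export
summary.anomalous_fit <- function(object, ...) {
  out <- list(
    coefficients = cbind(
      Estimate = c(D_alpha = object$D_alpha, alpha = object$alpha),
      `Std. Error` = object$sd),
    fit_range = object$fit_range,
    n = nrow(object$curve),
    species = object$species,
    rss = sum(stats::residuals(object$fit)^2))
  class(out) <- "summary.anomalous_fit"
  out
}

#' @export
print.summary.anomalous_fit <- function(x, ...) {
  cat(sprintf("Anomalous diffusion fit (%s), %d points in [%g, %g] ns\n",
              x$species, x$n, x$fit_range[1], x$fit_range[2]))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual sum of squares: %g\n", x$rss))
  invisible(x)
}

#' @export
coef.anomalous_fit <- function(object, ...) {
  c(D_alpha = object$D_alpha, alpha = object$alpha)
}

#' @export
predict.anomalous_fit <- function(object, newdata = NULL, ...) {
  lag <- if (is.null(newdata)) object$curve$lag else
    (newdata$lag %||% newdata)
  4 * object$D_alpha * lag^object$alpha
}

#' @export
residuals.anomalous_fit <- function(object, ...) {
  object$curve$msd - predict(object)
}

#' @export
plot.anomalous_fit <- function(x, ...) {
  graphics::plot(x$curve$lag, x$curve$msd, log = "xy",
                 xlab = expression(Delta * t ~ "(ns)"),
                 ylab = expression(MSD ~ (nm^2)), ...)
  graphics::lines(x$curve$lag, predict(x), col = 2, lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "D = %.3g, alpha = %.3g", x$D_alpha, x$alpha))
  invisible(x)
}

#' Simulate trajectories at the fitted diffusion parameters
#'
#' Draws synthetic 2D trajectories from the fitted `(D_alpha, alpha)` via
#' the exact fractional-Brownian generator, closing the loop between fit and
#' generator (a parametric bootstrap of the fitted law).
#'
#' @param object an `anomalous_fit`.
#' @param nsim number of trajectories to simulate.
#' @param seed RNG seed.
#' @param n_particles,n_frames,dt,box generator settings.
#' @param ... unused.
#' @return list of [mc_trajectory()] objects of length `nsim`.
#' @export
simulate.anomalous_fit <- function(object, nsim = 1, seed = NULL,
                                   n_particles = 100L, n_frames = 1024L,
                                   dt = 1, box = c(137, 137, 20), ...) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- min(max(object$alpha, 1e-6), 2)
  spec <- diffusion_spec(object$species, object$D_alpha, alpha, n_particles)
  lapply(seq_len(nsim), function(i)
    generate_diffusive_trajectory(mc_preset("simulated", list(spec),
                                            n_frames = n_frames, dt = dt,
                                            box = box, seed = NULL)))
}

#' Lag-dependent anomalous exponent profile
#'
#' Slides a fixed-width window (in decades of lag time) along the log-log
#' MSD curve and reports the local ordinary-least-squares slope
#' `alpha(dt) = d log MSD / d log dt` at each window centre. This resolves
#' regimes the single global fit averages over: short-lag caging,
#' intermediate subdiffusion and long-lag recovery toward alpha = 1.
#'
#' @param curve an `msd_curve`.
#' @param window_decades window width in decades (default 0.5).
#' @param step_decades spacing of window centres in decades (default 0.1).
#' @return an `alpha_profile`: data frame with `center` (ns), `alpha`, and
#'   `n_points` per window.
#' @export
alpha_profile <- function(curve, window_decades = 0.5, step_decades = 0.1) {
  pos <- curve$msd > 0 & curve$lag > 0
  lg <- log10(curve$lag[pos]); lm_ <- log10(curve$msd[pos])
  span <- max(lg) - min(lg)
  if (span < window_decades)
    mc_stop("curve spans fewer decades than the window width",
            "mc_argument_error")
  centers <- seq(min(lg) + window_decades / 2, max(lg) - window_decades / 2,
                 by = step_decades)
  half <- window_decades / 2
  rows <- lapply(centers, function(cc) {
    inwin <- abs(lg - cc) <= half + 1e-12
    if (sum(inwin) < 3L) return(NULL)
    sl <- stats::cov(lg[inwin], lm_[inwin]) / stats::var(lg[inwin])
    data.frame(center = 10^cc, alpha = sl, n_points = sum(inwin))
  })
  out <- do.call(rbind, rows)
  attr(out, "window_decades") <- window_decades
  class(out) <- c("alpha_profile", "data.frame")
  out
}

#' @export
plot.alpha_profile <- function(x, ...) {
  graphics::plot(x$center, x$alpha, log = "x", type = "b",
                 xlab = expression(Delta * t ~ "(ns)"),
                 ylab = expression(alpha), ylim = c(0, max(1.2, x$alpha)),
                 ...)
  graphics::abline(h = 1, lty = 2, col = "grey")
  invisible(x)
}

#' Per-interval displacement series (MSD convergence diagnostic)
#'
#' Mean squared displacement over consecutive non-overlapping intervals of
#' fixed length, as a time series: a flat series indicates stationary
#' diffusive sampling, a decaying one reflects e.g. progressive cluster
#' growth. Plateau assessment is left to the caller.
#'
#' @param traj an unwrapped [mc_trajectory()].
#' @param selection particles, as in [compute_msd()].
#' @param interval interval length in ns.
#' @return data frame with `time` (interval start, ns) and `msd_step`
#'   (mean squared lateral displacement over the interval, nm^2).
#' @export
msd_convergence_diagnostic <- function(traj, selection = NULL, interval = 10) {
  sel <- resolve_selection(traj, selection)
  co <- unwrapped_coords(traj, "msd_convergence_diagnostic")
  k <- max(1L, floor(interval / traj$dt))
  starts <- seq(1L, n_frames(traj) - k, by = k)
  msd <- vapply(starts, function(t0) {
    dx <- co[t0 + k, sel, 1] - co[t0, sel, 1]
    dy <- co[t0 + k, sel, 2] - co[t0, sel, 2]
    mean(dx^2 + dy^2)
  }, 0)
  data.frame(time = (starts - 1L) * traj$dt, msd_step = msd)
}
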