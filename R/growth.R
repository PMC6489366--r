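# Non-parametric growth-rate estimation.
#
# Log optical density is regressed on time with a Gaussian process
# (squared-exponential kernel + observation noise); the maximal specific
# growth rate is the maximum of the posterior mean derivative of log OD,
# which is available analytically for this kernel. Hyperparameters are set
# by marginal-likelihood maximisation with multi-start.

gp_nll <- function(theta, t, y) {
  sf2 <- exp(2 * theta[1]); ell <- exp(theta[2]); sn2 <- exp(2 * theta[3])
  n <- length(t)
  D <- outer(t, t, "-")
  K <- sf2 * exp(-0.5 * (D / ell)^2)
  diag(K) <- diag(K) + sn2 + 1e-10 * sf2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

#' Fit a Gaussian process to a growth curve and extract the maximal rate
#'
#' Regresses log OD on time with a squared-exponential-kernel Gaussian
#' process plus observation noise. Kernel variance, length scale and noise
#' are chosen by maximising the marginal likelihood from `n_restarts`
#' deterministic multi-starts. The maximal specific growth rate is the
#' maximum over a fine time grid of the posterior mean derivative of log OD;
#' its uncertainty comes from the derivative-process variance at that time.
#'
#' @param curve Growth-curve `data.frame` with columns `time_min`
#'   (strictly increasing) and `od` (> 0), e.g. from
#'   [generate_growth_curve()] or [read_growth_curve()].
#' @param blank Optional background OD subtracted before the log transform;
#'   points that become non-positive are dropped with a warning.
#' @param grid_size Size of the evaluation grid for the derivative.
#' @param n_restarts Number of optimisation restarts (default 5).
#' @param seed Seed for the restart draws.
#' @return An object of class `psk_growth_fit`: `mu_max` (per minute),
#'   `mu_max_sd`, `t_at_max` (minutes), `doubling_time` (minutes), the
#'   fitted mean/sd of log OD and its derivative on the grid (`grid`
#'   data.frame), and the optimised kernel settings (`kernel`).
#' @examples
#' gc <- generate_growth_curve(mu_max = 0.01, noise_sd = 0, seed = 1)
#' fit <- fit_growth_gp(gc)
#' fit$mu_max
#' @export
fit_growth_gp <- function(curve, blank = 0, grid_size = 200, n_restarts = 5,
                          seed = 1) {
  stopifnot(is.data.frame(curve), all(c("time_min", "od") %in% names(curve)))
  t <- curve$time_min
  od <- curve$od - blank
  if (any(diff(t) <= 0)) stop("'time_min' must be strictly increasing")
  keep <- od > 0
  if (!all(keep)) {
    warning(sum(!keep), " non-positive OD value(s) after blank subtraction dropped")
    t <- t[keep]; od <- od[keep]
  }
  if (length(t) < 10L) stop("need at least 10 usable time points")
  y0 <- log(od)
  ybar <- mean(y0)
  y <- y0 - ybar
  sdy <- max(stats::sd(y), 1e-8)
  rng_t <- diff(range(t))
  dt_med <- stats::median(diff(t))

  lower <- c(log(sdy * 1e-3), log(2 * dt_med), log(sdy * 1e-4 + 1e-9))
  upper <- c(log(sdy * 30), log(3 * rng_t), log(sdy * 1.5 + 1e-9))
  starts <- with_seed(seed, {
    s0 <- c(log(sdy), log(rng_t / 5), log(sdy / 10 + 1e-9))
    extra <- replicate(max(n_restarts - 1L, 0L),
                       stats::runif(3, lower, upper), simplify = FALSE)
    c(list(s0), extra)
  })
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      stats::optim(s, gp_nll, t = t, y = y, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("marginal-likelihood optimisation failed")
  th <- best$par
  sf2 <- exp(2 * th[1]); ell <- exp(th[2]); sn2 <- exp(2 * th[3])

  D <- outer(t, t, "-")
  K <- sf2 * exp(-0.5 * (D / ell)^2)
  diag(K) <- diag(K) + sn2 + 1e-10 * sf2
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))

  s_grid <- seq(min(t), max(t), length.out = grid_size)
  Ds <- outer(s_grid, t, "-")
  Ks <- sf2 * exp(-0.5 * (Ds / ell)^2)
  mean_f <- as.numeric(Ks %*% alpha) + ybar
  Vf <- forwardsolve(t(ch), t(Ks))
  var_f <- pmax(sf2 - colSums(Vf^2), 0)
  # derivative kernel: d/ds k(s, t_i) = -(s - t_i)/ell^2 * k(s, t_i)
  K1 <- -(Ds / ell^2) * Ks
  mean_d <- as.numeric(K1 %*% alpha)
  W <- forwardsolve(t(ch), t(K1))
  var_d <- pmax(sf2 / ell^2 - colSums(W^2), 0)

  i_max <- which.max(mean_d)
  mu_max <- mean_d[i_max]
  structure(
    list(mu_max = mu_max,
         mu_max_sd = sqrt(var_d[i_max]),
         t_at_max = s_grid[i_max],
         doubling_time = if (mu_max > 0) log(2) / mu_max else Inf,
         grid = data.frame(time_min = s_grid,
                           log_od_mean = mean_f,
                           log_od_sd = sqrt(var_f),
                           dlog_od_mean = mean_d,
                           dlog_od_sd = sqrt(var_d)),
         kernel = c(signal_sd = sqrt(sf2), length_scale = ell,
                    noise_sd = sqrt(sn2)),
         n_points = length(t),
         marginal_nll = best$value),
    class = "psk_growth_fit"
  )
}

#' @export
print.psk_growth_fit <- function(x, ...) {
  cat(sprintf(
    "GP growth fit (%d points)\n  mu_max = %.5g +/- %.2g per minute at t = %.0f min\n  doubling time = %.1f min\n",
    x$n_points, x$mu_max, x$mu_max_sd, x$t_at_max, x$doubling_time))
  invisible(x)
}

#' Burden ratio from a pair of doubling times
#'
#' The model's burden parameter is the ratio of the plasmid-free doubling
#' time to the plasmid-bearing doubling time; equivalently the ratio of
#' maximal growth rates with roles reversed.
#'
#' @param dt_free Plasmid-free doubling time, minutes (> 0).
#' @param dt_bearing Plasmid-bearing doubling time, minutes (> 0).
#' @return `gamma = dt_free / dt_bearing`.
#' @examples
#' gamma_from_doubling_times(20, 25)  # a plasmid that slows growth: 0.8
#' @export
gamma_from_doubling_times <- function(dt_free, dt_bearing) {
  if (!is.numeric(dt_free) || !is.numeric(dt_bearing) ||
      any(dt_free <= 0) || any(dt_bearing <= 0))
    stop("doubling times must be > 0")
  dt_free / dt_bearing
}

#' Burden ratio from two fitted growth curves
#'
#' @param fit_bearing,fit_free [fit_growth_gp()] results for the
#'   plasmid-bearing and plasmid-free strains.
#' @return `gamma = mu_max_bearing / mu_max_free` (identical to the
#'   doubling-time ratio since the `ln 2` factors cancel).
#' @export
gamma_from_growth_fits <- function(fit_bearing, fit_free) {
  stopifnot(inherits(fit_bearing, "psk_growth_fit"),
            inherits(fit_free, "psk_growth_fit"))
  fit_bearing$mu_max / fit_free$mu_max
}
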