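# Hierarchical Bayesian inference of (lambda, gamma, omega) from loss curves
# and competition dilution series.
#
# Parameterisation: population means and scales on transformed scales
# (logit lambda, log gamma, logit omega) with non-centred per-replicate
# deviations; a Beta observation model with inferred precision scores the
# bounded per-passage fractions. Sampling is by an affine-invariant
# ensemble (stretch-move) MCMC run as several independent ensembles, with
# split-Rhat convergence diagnostics and a prior-posterior overlap statistic
# flagging non-identifiable parameters.

#' Prior specification for the hierarchical model
#'
#' All priors act on transformed scales. Population means get normal priors;
#' population (replicate-to-replicate) scales get half-normal priors; the
#' Beta observation precision gets a log-normal prior.
#'
#' @param lambda_mu Normal prior `c(location, scale)` for the population mean
#'   of logit lambda. The default centres lambda near `plogis(-6) ~ 2.5e-3`
#'   with a wide scale.
#' @param lambda_tau Half-normal scale for the population sd of logit lambda.
#' @param gamma_mu Normal prior for the population mean of log gamma.
#' @param gamma_tau Half-normal scale for the population sd of log gamma.
#' @param omega_mu Normal prior for the population mean of logit omega.
#' @param omega_tau Half-normal scale for the population sd of logit omega.
#' @param phi_mu Normal prior `c(location, scale)` for log of the Beta
#'   observation precision.
#' @return An object of class `psk_priors`.
#' @export
prior_spec <- function(lambda_mu = c(-6, 3), lambda_tau = 0.5,
                       gamma_mu = c(0, 0.5), gamma_tau = 0.25,
                       omega_mu = c(0, 2), omega_tau = 0.5,
                       phi_mu = c(log(100), 2)) {
  chk <- function(p, nm) {
    if (length(p) != 2L || !is.numeric(p) || p[2] <= 0)
      stop("'", nm, "' must be c(location, scale) with scale > 0")
  }
  chk(lambda_mu, "lambda_mu"); chk(gamma_mu, "gamma_mu")
  chk(omega_mu, "omega_mu"); chk(phi_mu, "phi_mu")
  if (lambda_tau <= 0 || gamma_tau <= 0 || omega_tau <= 0)
    stop("population-scale priors must be > 0")
  structure(list(lambda_mu = lambda_mu, lambda_tau = lambda_tau,
                 gamma_mu = gamma_mu, gamma_tau = gamma_tau,
                 omega_mu = omega_mu, omega_tau = omega_tau,
                 phi_mu = phi_mu),
            class = "psk_priors")
}

# split a long curves data.frame into per-replicate observation lists
split_curves <- function(curves) {
  stopifnot(is.data.frame(curves),
            all(c("replicate_id", "passage", "fraction") %in% names(curves)))
  if (any(curves$fraction < 0 | curves$fraction > 1))
    stop("fractions outside [0, 1] in curves")
  lapply(split(curves, curves$replicate_id), function(d) {
    d <- d[order(d$passage), , drop = FALSE]
    ne <- if ("n_events" %in% names(d)) d$n_events else rep(NA_real_, nrow(d))
    eps <- ifelse(is.finite(ne) & ne > 0, 1 / (2 * ne), 1e-4)
    list(passage = d$passage,
         obs = pmin(pmax(d$fraction, eps), 1 - eps),
         eps = eps)
  })
}

#' Log-likelihood of loss curves under the Beta observation model
#'
#' Scores each observed per-passage fraction against the deterministic model
#' fraction for its replicate under a Beta distribution with mean equal to
#' the model fraction and the given precision. Observed fractions of exactly
#' 0 or 1 are mapped into the open interval by `eps = 1/(2 * n_events)`
#' (`1e-4` when event counts are absent).
#'
#' @param curves Loss-curve `data.frame` (`replicate_id`, `passage`,
#'   `fraction`, optional `n_events`).
#' @param replicate_params List of [psk_params()], one per replicate (in the
#'   order of `sort(unique(curves$replicate_id))`).
#' @param protocol A [passaging_protocol()].
#' @param noise_precision Beta precision `phi` (> 0).
#' @return The total log-likelihood (a scalar).
#' @export
psk_log_likelihood <- function(curves, replicate_params, protocol,
                               noise_precision) {
  obs <- split_curves(curves)
  if (length(obs) != length(replicate_params))
    stop("got ", length(obs), " replicates but ", length(replicate_params),
         " parameter sets")
  stopifnot(noise_precision > 0)
  total <- 0
  for (i in seq_along(obs)) {
    f <- fraction_at_passages(replicate_params[[i]], protocol,
                              obs[[i]]$passage)
    # the model mean is confined to the same open interval as the mapped
    # observations so that a saturated model curve scores a saturated
    # observation at its mode rather than in a degenerate tail
    eps <- obs[[i]]$eps
    f <- pmin(pmax(f, eps), 1 - eps)
    total <- total + sum(stats::dbeta(obs[[i]]$obs, f * noise_precision,
                                      (1 - f) * noise_precision, log = TRUE))
  }
  total
}

# ---- internal: vectorised forward model and log posterior ------------------

# model fractions for a flat vector of (a, b, cc) systems at shared passage
# times; returns a P x n matrix, overflow-safe (see fraction_at_passages)
traj_flat <- function(a, b, cc, f0, t) {
  Dt <- outer(t, a - b)                             # P x n
  aDt <- abs(Dt)
  g <- -expm1(-aDt) / pmax(aDt, 1e-300)
  g[aDt < 1e-12] <- 1
  u <- f0 * exp(pmin(Dt, 0))
  v <- (1 - f0) * exp(pmin(-Dt, 0)) +
    rep(cc, each = length(t)) * f0 * t * g
  u / (u + v)
}

# model fractions for R replicates at shared passage vector; returns P x R
traj_matrix <- function(lambda, gamma, omega, mechanism, protocol, passages) {
  a <- gamma * (1 - lambda)
  if (mechanism == "BACTERIOCIN") {
    b <- 1 - 2 * omega
    cc <- lambda * gamma
  } else {
    b <- rep(1, length(a))
    cc <- (1 - omega) * lambda * gamma
  }
  traj_flat(a, b, cc, protocol$initial_fraction,
            passages * protocol$tau_per_passage)
}

# layout: [mu_l, ls_l, mu_g, ls_g, (mu_w, ls_w,) log_phi, z_l(R), z_g(R), (z_w(R))]
theta_layout <- function(R, has_omega) {
  n_top <- if (has_omega) 7L else 5L
  n_z <- if (has_omega) 3L else 2L
  list(d = n_top + n_z * R, n_top = n_top, R = R, has_omega = has_omega)
}

unpack_theta <- function(theta, lay) {
  R <- lay$R
  if (lay$has_omega) {
    list(mu_l = theta[1], ls_l = theta[2], mu_g = theta[3], ls_g = theta[4],
         mu_w = theta[5], ls_w = theta[6], log_phi = theta[7],
         z_l = theta[7 + seq_len(R)], z_g = theta[7 + R + seq_len(R)],
         z_w = theta[7 + 2 * R + seq_len(R)])
  } else {
    list(mu_l = theta[1], ls_l = theta[2], mu_g = theta[3], ls_g = theta[4],
         log_phi = theta[5],
         z_l = theta[5 + seq_len(R)], z_g = theta[5 + R + seq_len(R)])
  }
}

# Batched log posterior: takes an n x d matrix of walker positions and
# returns an n-vector. Batching moves the sampler's inner loop into
# vectorised arithmetic over walkers x replicates x passages.
make_log_post <- function(obs_mat, eps_mat, passages, protocol, priors,
                          mechanism, lay) {
  has_w <- lay$has_omega
  R <- lay$R
  off <- lay$n_top
  P <- length(passages)
  t <- passages * protocol$tau_per_passage
  f0 <- protocol$initial_fraction
  # expanded to P x (n*R) blocks, walker index varying fastest
  expand_cols <- function(m, n) m[, rep(seq_len(R), each = n), drop = FALSE]
  phi_idx <- if (has_w) 7L else 5L
  function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
    n <- nrow(theta)
    bad <- !is.finite(rowSums(theta))
    theta[bad, ] <- 0
    mu_l <- theta[, 1L]; sig_l <- exp(theta[, 2L])
    mu_g <- theta[, 3L]; sig_g <- exp(theta[, 4L])
    phi <- exp(theta[, phi_idx])
    bad <- bad | !is.finite(phi) | phi > 1e8
    z_l <- theta[, off + seq_len(R), drop = FALSE]
    z_g <- theta[, off + R + seq_len(R), drop = FALSE]
    lambda <- stats::plogis(mu_l + sig_l * z_l)      # n x R
    gamma <- exp(mu_g + sig_g * z_g)
    bad <- bad | !is.finite(rowSums(gamma))
    gamma[!is.finite(gamma)] <- 1
    if (has_w) {
      mu_w <- theta[, 5L]; sig_w <- exp(theta[, 6L])
      z_w <- theta[, off + 2L * R + seq_len(R), drop = FALSE]
      omega <- stats::plogis(mu_w + sig_w * z_w)
    } else {
      omega <- matrix(0, n, R)
    }
    a <- gamma * (1 - lambda)
    if (mechanism == "BACTERIOCIN") {
      b <- 1 - 2 * omega
      cc <- lambda * gamma
    } else {
      b <- matrix(1, n, R)
      cc <- (1 - omega) * lambda * gamma
    }
    f <- traj_flat(as.numeric(a), as.numeric(b), as.numeric(cc), f0, t)
    lo <- expand_cols(eps_mat, n)
    f <- pmin(pmax(f, lo), 1 - lo)
    prec <- rep(rep(phi, R), each = P)
    dens <- stats::dbeta(expand_cols(obs_mat, n), f * prec, (1 - f) * prec,
                         log = TRUE)
    ll <- rowSums(matrix(colSums(dens), n, R))
    lp <- stats::dnorm(mu_l, priors$lambda_mu[1], priors$lambda_mu[2], log = TRUE) +
      stats::dnorm(sig_l, 0, priors$lambda_tau, log = TRUE) + log(2) + theta[, 2L] +
      stats::dnorm(mu_g, priors$gamma_mu[1], priors$gamma_mu[2], log = TRUE) +
      stats::dnorm(sig_g, 0, priors$gamma_tau, log = TRUE) + log(2) + theta[, 4L] +
      stats::dnorm(theta[, phi_idx], priors$phi_mu[1], priors$phi_mu[2], log = TRUE) +
      rowSums(stats::dnorm(z_l, log = TRUE)) +
      rowSums(stats::dnorm(z_g, log = TRUE))
    if (has_w) {
      lp <- lp +
        stats::dnorm(mu_w, priors$omega_mu[1], priors$omega_mu[2], log = TRUE) +
        stats::dnorm(sig_w, 0, priors$omega_tau, log = TRUE) + log(2) + theta[, 6L] +
        rowSums(stats::dnorm(z_w, log = TRUE))
    }
    out <- ll + lp
    out[bad | !is.finite(out)] <- -Inf
    out
  }
}

# ---- internal: affine-invariant ensemble sampler ---------------------------

# Goodman & Weare stretch move over a batched log posterior (n x d matrix in,
# n-vector out); each half of the ensemble is updated against the other in a
# single vectorised sweep. Returns draws[step, walker, dim].
run_ensemble <- function(log_post, init, n_steps, a = 1.3) {
  W <- nrow(init); d <- ncol(init)
  x <- init
  lp <- log_post(x)
  draws <- array(NA_real_, c(n_steps, W, d))
  half <- W %/% 2L
  sets <- list(seq_len(half), (half + 1L):W)
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    for (g in 1:2) {
      act <- sets[[g]]; oth <- sets[[3L - g]]
      na <- length(act)
      z <- ((a - 1) * stats::runif(na) + 1)^2 / a
      j <- oth[sample.int(length(oth), na, replace = TRUE)]
      # z has one entry per active walker and recycles down matrix rows, so
      # each walker's whole coordinate vector is stretched by its own z
      prop <- x[j, , drop = FALSE] +
        z * (x[act, , drop = FALSE] - x[j, , drop = FALSE])
      lp_prop <- log_post(prop)
      log_acc <- (d - 1) * log(z) + lp_prop - lp[act]
      acc <- is.finite(lp_prop) & log(stats::runif(na)) < log_acc
      if (any(acc)) {
        x[act[acc], ] <- prop[acc, , drop = FALSE]
        lp[act[acc]] <- lp_prop[acc]
        n_acc <- n_acc + sum(acc)
      }
    }
    draws[s, , ] <- x
  }
  list(draws = draws, lp = lp, accept_rate = n_acc / (n_steps * W))
}

# multi-start Nelder-Mead MAP over selected coordinates of log_post
profile_map <- function(log_post, center, opt_idx, n_starts = 4) {
  best <- center
  best_val <- log_post(center)
  obj <- function(x) {
    th <- center
    th[opt_idx] <- x
    v <- -log_post(th)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- c(list(center[opt_idx]),
              lapply(seq_len(n_starts - 1L), function(i)
                center[opt_idx] + stats::rnorm(length(opt_idx), 0, 1)))
  for (s in starts) {
    op <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                                control = list(maxit = 2000)),
                   error = function(e) NULL)
    if (!is.null(op) && -op$value > best_val) {
      best_val <- -op$value
      best[opt_idx] <- op$par
    }
  }
  best
}

# data-informed start for the hierarchical sampler: fit each replicate's
# curve independently on the transformed scale, take moments of the
# per-replicate estimates as the population locations/scales, express the
# estimates as non-centred deviations, then profile the noise precision
hier_init <- function(obs, protocol, priors, mechanism, lay, log_post) {
  R <- lay$R
  has_w <- lay$has_omega
  est <- matrix(NA_real_, R, 3L)
  for (r in seq_len(R)) {
    o <- obs[[r]]
    fobj <- function(th) {
      lam <- stats::plogis(th[1L]); gam <- exp(th[2L])
      ome <- if (has_w) stats::plogis(th[3L]) else 0
      if (!is.finite(gam) || gam <= 0) return(1e10)
      p <- psk_params(lam, gam, ome, mechanism = mechanism)
      f <- fraction_at_passages(p, protocol, o$passage)
      f <- pmin(pmax(f, o$eps), 1 - o$eps)
      nll <- -sum(stats::dbeta(o$obs, f * 200, (1 - f) * 200, log = TRUE)) -
        stats::dnorm(th[1L], priors$lambda_mu[1], priors$lambda_mu[2], log = TRUE) -
        stats::dnorm(th[2L], priors$gamma_mu[1], priors$gamma_mu[2], log = TRUE)
      if (has_w)
        nll <- nll - stats::dnorm(th[3L], priors$omega_mu[1],
                                  priors$omega_mu[2], log = TRUE)
      if (!is.finite(nll)) 1e10 else nll
    }
    s0 <- c(priors$lambda_mu[1], priors$gamma_mu[1],
            if (has_w) priors$omega_mu[1])
    op <- tryCatch(stats::optim(s0, fobj, method = "Nelder-Mead",
                                control = list(maxit = 1500)),
                   error = function(e) NULL)
    est[r, seq_along(s0)] <- if (is.null(op)) s0 else op$par
  }
  mu <- colMeans(est, na.rm = TRUE)
  sg <- pmax(apply(est, 2L, stats::sd, na.rm = TRUE), 0.05)
  z <- sweep(sweep(est, 2L, mu), 2L, sg, "/")
  z[!is.finite(z)] <- 0
  z <- pmin(pmax(z, -3), 3)
  build <- function(log_phi) {
    if (has_w)
      c(mu[1L], log(sg[1L]), mu[2L], log(sg[2L]), mu[3L], log(sg[3L]),
        log_phi, z[, 1L], z[, 2L], z[, 3L])
    else
      c(mu[1L], log(sg[1L]), mu[2L], log(sg[2L]), log_phi, z[, 1L], z[, 2L])
  }
  op_phi <- stats::optimize(function(lp_phi) {
    v <- -log_post(build(lp_phi))
    if (!is.finite(v)) 1e10 else v
  }, interval = priors$phi_mu[1] + c(-6, 10))
  build(op_phi$minimum)
}

init_walkers <- function(log_post, center, spread, W, max_tries = 200) {
  d <- length(center)
  init <- matrix(NA_real_, W, d)
  for (w in seq_len(W)) {
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      cand <- center + spread * stats::rnorm(d)
      if (is.finite(log_post(cand))) {
        init[w, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not initialise the sampler at a finite posterior density; ",
           "check that the curves carry information under the chosen priors")
  }
  init
}

# ---- diagnostics -----------------------------------------------------------

# split-Rhat for ensemble MCMC: each ensemble's pooled walkers form one
# chain, split into iteration halves so that both between-ensemble
# disagreement and within-ensemble drift inflate the statistic.
# 'per_chain' is a list of [iter, walker] matrices, one per ensemble.
split_rhat <- function(per_chain) {
  groups <- unlist(lapply(per_chain, function(m) {
    n <- nrow(m)
    if (n < 4L) return(NULL)
    h <- n %/% 2L
    list(as.numeric(m[seq_len(h), , drop = FALSE]),
         as.numeric(m[(n - h + 1L):n, , drop = FALSE]))
  }), recursive = FALSE)
  if (length(groups) < 2L) return(NA_real_)
  nn <- min(lengths(groups))
  groups <- lapply(groups, function(g) g[seq_len(nn)])
  mu <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, stats::var, numeric(1))
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude effective sample size from the mean autocorrelation across chains
ess_basic <- function(mat, max_lag = 100L) {
  n <- nrow(mat); m <- ncol(mat)
  max_lag <- min(max_lag, n - 2L)
  rho <- rep(0, max_lag)
  for (j in seq_len(m)) {
    x <- mat[, j]
    if (stats::sd(x) < 1e-300) next
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
    rho <- rho + ac / m
  }
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  tau <- 1 + 2 * sum(rho)
  max(n * m / tau, 1)
}

# overlap coefficient between a closed-form normal prior and posterior draws
prior_posterior_overlap <- function(draws, prior_loc, prior_scale) {
  if (stats::sd(draws) < 1e-12) return(0)
  lo <- min(prior_loc - 5 * prior_scale, min(draws))
  hi <- max(prior_loc + 5 * prior_scale, max(draws))
  grid <- seq(lo, hi, length.out = 1024L)
  post <- stats::density(draws, from = lo, to = hi, n = 1024L)$y
  prior <- stats::dnorm(grid, prior_loc, prior_scale)
  sum(pmin(post, prior)) * (grid[2L] - grid[1L])
}

summarise_draws <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  c(median = q[1L], lower = q[2L], upper = q[3L])
}

# ---- main fitting routines -------------------------------------------------

#' Fit the hierarchical plasmid-stability model to loss curves
#'
#' Samples the joint posterior of the population-level means and scales of
#' (logit lambda, log gamma, logit omega), the per-replicate non-centred
#' deviations, and the Beta observation precision, given observed
#' plasmid-loss curves. Sampling uses `n_chains` independent stretch-move
#' ensembles; convergence is assessed by split-Rhat (threshold 1.01) over
#' the population-level quantities and identifiability by the
#' prior-posterior overlap coefficient (parameters whose posterior still
#' overlaps the prior by more than `overlap_threshold` are flagged).
#'
#' @param curves Loss-curve `data.frame` (`replicate_id`, `passage`,
#'   `fraction`, optional `n_events`); at least 2 passages per replicate.
#' @param protocol The [passaging_protocol()] that produced the curves.
#' @param priors A [prior_spec()].
#' @param mechanism Killing mechanism assumed for the fit.
#' @param n_chains Number of independent ensembles (>= 4 recommended).
#' @param n_steps Stretch-move steps per ensemble (half are burn-in).
#' @param n_walkers Walkers per ensemble; default `2 * dim + 8`.
#' @param thin Keep every `thin`-th post-burn-in step.
#' @param seed Integer seed.
#' @param overlap_threshold Overlap above which a parameter is declared
#'   non-identifiable (default 0.35).
#' @return An object of class `psk_posterior`; see Details.
#' @details The returned object contains `draws` (a data.frame of
#'   back-transformed population-level draws: `lambda`, `gamma`, `omega`,
#'   `survival` = 1 - omega, `phi`, the population sds, and the transformed
#'   means), `replicate_draws` (array draws x replicate x parameter),
#'   `summary` (medians, 95% credible intervals, Rhat, ESS, overlap and
#'   identifiability per parameter), `converged` (all Rhat < 1.01), and the
#'   sampler settings and seed.
#' @export
fit_hierarchical <- function(curves, protocol, priors = prior_spec(),
                             mechanism = c("TA", "BACTERIOCIN", "NONE"),
                             n_chains = 4, n_steps = 3000, n_walkers = NULL,
                             thin = 4, seed = 1, overlap_threshold = 0.35) {
  mechanism <- match.arg(mechanism)
  obs <- split_curves(curves)
  R <- length(obs)
  if (R < 1L) stop("need at least one replicate curve")
  pass_list <- lapply(obs, `[[`, "passage")
  if (any(vapply(pass_list, length, 1L) < 2L))
    stop("each replicate needs at least 2 recorded passages")
  shared <- all(vapply(pass_list, identical, TRUE, y = pass_list[[1L]]))
  if (!shared)
    stop("replicates must share a common passage grid")
  passages <- pass_list[[1L]]
  obs_mat <- vapply(obs, `[[`, numeric(length(passages)), "obs")  # P x R
  obs_mat <- matrix(obs_mat, nrow = length(passages))
  eps_mat <- matrix(vapply(obs, `[[`, numeric(length(passages)), "eps"),
                    nrow = length(passages))

  lay <- theta_layout(R, has_omega = mechanism != "NONE")
  log_post <- make_log_post(obs_mat, eps_mat, passages, protocol, priors,
                            mechanism, lay)
  if (is.null(n_walkers)) n_walkers <- 2L * lay$d + 8L
  if (n_walkers %% 2L == 1L) n_walkers <- n_walkers + 1L

  center <- if (lay$has_omega) {
    c(priors$lambda_mu[1], log(priors$lambda_tau / 2),
      priors$gamma_mu[1], log(priors$gamma_tau / 2),
      priors$omega_mu[1], log(priors$omega_tau / 2),
      priors$phi_mu[1], rep(0, lay$d - lay$n_top))
  } else {
    c(priors$lambda_mu[1], log(priors$lambda_tau / 2),
      priors$gamma_mu[1], log(priors$gamma_tau / 2),
      priors$phi_mu[1], rep(0, lay$d - lay$n_top))
  }
  spread <- rep(0.1, lay$d)

  chains <- with_seed(seed, {
    start <- tryCatch(
      hier_init(obs, protocol, priors, mechanism, lay, log_post),
      error = function(e) center)
    if (!is.finite(log_post(start))) start <- center
    lapply(seq_len(n_chains), function(ch) {
      init <- init_walkers(log_post, start, spread, n_walkers)
      run_ensemble(log_post, init, n_steps)
    })
  })

  burn <- n_steps %/% 2L
  keep <- seq(burn + 1L, n_steps, by = thin)

  # per-chain matrices [kept-iter, walker] for each monitored scalar
  monitor <- function(fun) {
    lapply(chains, function(cn) {
      apply(cn$draws[keep, , , drop = FALSE], c(1L, 2L), fun)
    })
  }
  mon_defs <- list(
    lambda = function(th) stats::plogis(th[1L]),
    gamma = function(th) exp(th[3L]),
    sigma_logit_lambda = function(th) exp(th[2L]),
    sigma_log_gamma = function(th) exp(th[4L]),
    phi = function(th) exp(th[if (lay$has_omega) 7L else 5L])
  )
  if (lay$has_omega) {
    mon_defs$omega <- function(th) stats::plogis(th[5L])
    mon_defs$sigma_logit_omega <- function(th) exp(th[6L])
  }
  mon <- lapply(mon_defs, monitor)

  diag_tab <- lapply(names(mon), function(nm) {
    per_chain <- mon[[nm]]
    data.frame(parameter = nm,
               rhat = split_rhat(per_chain),
               ess = ess_basic(do.call(cbind, per_chain)))
  })
  diag_tab <- do.call(rbind, diag_tab)

  pooled <- lapply(mon, function(per_chain) as.numeric(do.call(cbind, per_chain)))
  draws_pop <- as.data.frame(pooled)
  if (lay$has_omega) draws_pop$survival <- 1 - draws_pop$omega

  # transformed-scale population means for the overlap diagnostic
  tr_defs <- list(mu_logit_lambda = list(i = 1L, prior = priors$lambda_mu),
                  mu_log_gamma = list(i = 3L, prior = priors$gamma_mu))
  if (lay$has_omega)
    tr_defs$mu_logit_omega <- list(i = 5L, prior = priors$omega_mu)
  overlaps <- vapply(tr_defs, function(td) {
    dr <- as.numeric(vapply(chains, function(cn) cn$draws[keep, , td$i],
                            matrix(0, length(keep), n_walkers)))
    prior_posterior_overlap(dr, td$prior[1L], td$prior[2L])
  }, numeric(1))
  overlap_tab <- data.frame(
    parameter = c("lambda", "gamma", if (lay$has_omega) "omega"),
    overlap = unname(overlaps),
    identifiable = unname(overlaps) < overlap_threshold)

  # per-replicate back-transformed draws
  n_kept_total <- length(keep) * n_walkers * n_chains
  rep_names <- names(obs)
  rep_pars <- if (lay$has_omega) c("lambda", "gamma", "omega") else
    c("lambda", "gamma")
  replicate_draws <- array(
    NA_real_, c(n_kept_total, R, length(rep_pars)),
    dimnames = list(NULL, rep_names, rep_pars))
  off <- lay$n_top
  pull <- function(i) {
    as.numeric(vapply(chains, function(cn) cn$draws[keep, , i],
                      matrix(0, length(keep), n_walkers)))
  }
  for (r in seq_len(R)) {
    mu_l <- pull(1L); sl <- exp(pull(2L)); zl <- pull(off + r)
    replicate_draws[, r, "lambda"] <- stats::plogis(mu_l + sl * zl)
    mu_g <- pull(3L); sg <- exp(pull(4L)); zg <- pull(off + R + r)
    replicate_draws[, r, "gamma"] <- exp(mu_g + sg * zg)
    if (lay$has_omega) {
      mu_w <- pull(5L); sw <- exp(pull(6L)); zw <- pull(off + 2L * R + r)
      replicate_draws[, r, "omega"] <- stats::plogis(mu_w + sw * zw)
    }
  }

  sum_rows <- lapply(names(draws_pop), function(nm) {
    s <- summarise_draws(draws_pop[[nm]])
    base <- diag_tab[diag_tab$parameter == nm, ]
    ov <- overlap_tab[overlap_tab$parameter == nm, ]
    data.frame(parameter = nm, median = s["median"], lower = s["lower"],
               upper = s["upper"],
               rhat = if (nrow(base)) base$rhat else NA_real_,
               ess = if (nrow(base)) base$ess else NA_real_,
               overlap = if (nrow(ov)) ov$overlap else NA_real_,
               identifiable = if (nrow(ov)) ov$identifiable else NA,
               row.names = NULL)
  })
  summary_tab <- do.call(rbind, sum_rows)

  accept <- mean(vapply(chains, `[[`, numeric(1), "accept_rate"))
  structure(
    list(draws = draws_pop,
         replicate_draws = replicate_draws,
         summary = summary_tab,
         overlap = overlap_tab,
         converged = all(is.finite(diag_tab$rhat)) && all(diag_tab$rhat < 1.01),
         rhat = stats::setNames(diag_tab$rhat, diag_tab$parameter),
         mechanism = mechanism, protocol = protocol, priors = priors,
         replicate_ids = rep_names,
         settings = list(n_chains = n_chains, n_steps = n_steps,
                         n_walkers = n_walkers, thin = thin,
                         overlap_threshold = overlap_threshold,
                         accept_rate = accept),
         seed = seed),
    class = "psk_posterior"
  )
}

#' @export
print.psk_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical PSK posterior [%s]%s\n", x$mechanism,
              if (x$converged) "" else "  [NOT CONVERGED: Rhat >= 1.01]"))
  tab <- x$summary
  tab[, c("median", "lower", "upper")] <-
    signif(tab[, c("median", "lower", "upper")], 4)
  print(tab, row.names = FALSE)
  bad <- x$overlap$parameter[!x$overlap$identifiable]
  if (length(bad))
    cat("Non-identifiable (high prior-posterior overlap):",
        paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior-predictive loss-curve envelope
#'
#' Simulates loss curves for a sample of posterior draws — each draw
#' generating a fresh replicate from the fitted hierarchy — and returns the
#' pointwise mean and central 95% band per passage, the model-fit envelope
#' usually overlaid on observed loss curves.
#'
#' @param fit A [fit_hierarchical()] result.
#' @param protocol A [passaging_protocol()] (defaults to the fitted one).
#' @param n_draws Number of posterior draws to simulate.
#' @param seed Integer seed for the draw selection and new-replicate noise.
#' @param force Set `TRUE` to use a non-converged fit.
#' @return A `data.frame` with columns `passage`, `mean`, `lower`, `upper`.
#' @export
posterior_predictive <- function(fit, protocol = fit$protocol, n_draws = 200,
                                 seed = 1, force = FALSE) {
  stopifnot(inherits(fit, "psk_posterior"))
  if (!fit$converged && !force)
    stop("fit did not converge; pass force = TRUE to override")
  n_avail <- nrow(fit$draws)
  if (n_draws > n_avail)
    stop("n_draws (", n_draws, ") exceeds available draws (", n_avail, ")")
  has_w <- fit$mechanism != "NONE"
  passages <- 0:protocol$n_passages
  sims <- with_seed(seed, {
    idx <- sample.int(n_avail, n_draws)
    vapply(idx, function(i) {
      d <- fit$draws[i, ]
      lam <- stats::plogis(stats::qlogis(min(max(d$lambda, 1e-12), 1 - 1e-12)) +
                           d$sigma_logit_lambda * stats::rnorm(1))
      gam <- exp(log(d$gamma) + d$sigma_log_gamma * stats::rnorm(1))
      ome <- if (has_w)
        stats::plogis(stats::qlogis(min(max(d$omega, 1e-12), 1 - 1e-12)) +
                      d$sigma_logit_omega * stats::rnorm(1)) else 0
      p <- psk_params(lam, gam, ome, mechanism = fit$mechanism)
      fraction_at_passages(p, protocol, passages)
    }, numeric(length(passages)))
  })
  data.frame(passage = passages,
             mean = rowMeans(sims),
             lower = apply(sims, 1L, stats::quantile, 0.025, names = FALSE),
             upper = apply(sims, 1L, stats::quantile, 0.975, names = FALSE))
}

#' Fit the model to a single-passage competition dilution series
#'
#' Non-hierarchical counterpart of [fit_hierarchical()] for the restoration
#' experiment: cultures started at a series of plasmid-bearing fractions are
#' regrown for one passage and the final fractions observed. The forward map
#' is [predict_competition()]; the observation model is the same Beta
#' likelihood. Posterior concentration of `lambda` at its lower boundary
#' (median below `1e-4`, i.e. loss indistinguishable from zero at this
#' design's resolution) is flagged.
#'
#' @param observed `data.frame` with columns `initial_fraction` and
#'   `final_fraction` (plus optional `replicate_id`); >= 3 rows.
#' @param priors A [prior_spec()]; the population-mean priors act directly on
#'   the (single) parameter set.
#' @param mechanism Killing mechanism.
#' @param tau Regrowth time of the passage (default `log(1000)`).
#' @param n_chains,n_steps,thin,seed,overlap_threshold As in
#'   [fit_hierarchical()].
#' @return An object of class `psk_posterior` (no replicate level) with an
#'   additional `flags$lambda_boundary`.
#' @export
fit_competition <- function(observed, priors = prior_spec(),
                            mechanism = c("BACTERIOCIN", "TA", "NONE"),
                            tau = log(1000), n_chains = 4, n_steps = 2000,
                            thin = 2, seed = 1, overlap_threshold = 0.35) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.data.frame(observed),
            all(c("initial_fraction", "final_fraction") %in% names(observed)))
  if (nrow(observed) < 3L) stop("need at least 3 dilution points")
  if (any(observed$initial_fraction < 0 | observed$initial_fraction > 1))
    stop("initial fractions outside [0, 1]")
  if (any(observed$final_fraction < 0 | observed$final_fraction > 1))
    stop("final fractions outside [0, 1]")
  has_w <- mechanism != "NONE"
  d <- if (has_w) 4L else 3L
  f0 <- observed$initial_fraction
  eps <- 1e-4
  obs <- pmin(pmax(observed$final_fraction, eps), 1 - eps)

  log_post1 <- function(theta) {
    if (any(!is.finite(theta))) return(-Inf)
    lam <- stats::plogis(theta[1L])
    gam <- exp(theta[2L])
    ome <- if (has_w) stats::plogis(theta[3L]) else 0
    phi <- exp(theta[if (has_w) 4L else 3L])
    if (!is.finite(gam) || gam <= 0 || !is.finite(phi) || phi > 1e8)
      return(-Inf)
    p <- psk_params(lam, gam, ome, mechanism = mechanism)
    f <- predict_competition(p, f0, tau)
    f <- pmin(pmax(f, eps), 1 - eps)
    ll <- sum(stats::dbeta(obs, f * phi, (1 - f) * phi, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    lp <- stats::dnorm(theta[1L], priors$lambda_mu[1], priors$lambda_mu[2], log = TRUE) +
      stats::dnorm(theta[2L], priors$gamma_mu[1], priors$gamma_mu[2], log = TRUE) +
      stats::dnorm(theta[if (has_w) 4L else 3L], priors$phi_mu[1],
                   priors$phi_mu[2], log = TRUE)
    if (has_w)
      lp <- lp + stats::dnorm(theta[3L], priors$omega_mu[1],
                              priors$omega_mu[2], log = TRUE)
    ll + lp
  }
  log_post <- function(theta) {
    if (is.null(dim(theta))) return(log_post1(theta))
    apply(theta, 1L, log_post1)
  }

  n_walkers <- 2L * d + 10L
  center <- if (has_w)
    c(priors$lambda_mu[1], priors$gamma_mu[1], priors$omega_mu[1], priors$phi_mu[1])
  else c(priors$lambda_mu[1], priors$gamma_mu[1], priors$phi_mu[1])
  chains <- with_seed(seed, {
    start <- profile_map(log_post, center, seq_len(d))
    lapply(seq_len(n_chains), function(ch) {
      init <- init_walkers(log_post, start, rep(0.25, d), n_walkers)
      run_ensemble(log_post, init, n_steps)
    })
  })
  burn <- n_steps %/% 2L
  keep <- seq(burn + 1L, n_steps, by = thin)

  pull <- function(i) {
    as.numeric(vapply(chains, function(cn) cn$draws[keep, , i],
                      matrix(0, length(keep), n_walkers)))
  }
  per_chain <- function(i) lapply(chains, function(cn) {
    matrix(cn$draws[keep, , i], nrow = length(keep))
  })

  draws_pop <- data.frame(lambda = stats::plogis(pull(1L)),
                          gamma = exp(pull(2L)))
  if (has_w) {
    draws_pop$omega <- stats::plogis(pull(3L))
    draws_pop$survival <- 1 - draws_pop$omega
    draws_pop$phi <- exp(pull(4L))
  } else draws_pop$phi <- exp(pull(3L))

  trans <- list(lambda = list(i = 1L, f = stats::plogis, prior = priors$lambda_mu),
                gamma = list(i = 2L, f = exp, prior = priors$gamma_mu))
  if (has_w)
    trans$omega <- list(i = 3L, f = stats::plogis, prior = priors$omega_mu)
  overlaps <- vapply(trans, function(td)
    prior_posterior_overlap(pull(td$i), td$prior[1L], td$prior[2L]), numeric(1))
  overlap_tab <- data.frame(parameter = names(trans),
                            overlap = unname(overlaps),
                            identifiable = unname(overlaps) < overlap_threshold,
                            row.names = NULL)

  sum_rows <- lapply(names(draws_pop), function(nm) {
    s <- summarise_draws(draws_pop[[nm]])
    i_tr <- switch(nm, lambda = 1L, gamma = 2L,
                   omega = if (has_w) 3L else NA_integer_,
                   phi = if (has_w) 4L else 3L, NA_integer_)
    rh <- if (!is.na(i_tr)) split_rhat(per_chain(i_tr)) else NA_real_
    es <- if (!is.na(i_tr)) ess_basic(do.call(cbind, per_chain(i_tr))) else NA_real_
    ov <- overlap_tab[overlap_tab$parameter == nm, ]
    data.frame(parameter = nm, median = s["median"], lower = s["lower"],
               upper = s["upper"], rhat = rh, ess = es,
               overlap = if (nrow(ov)) ov$overlap else NA_real_,
               identifiable = if (nrow(ov)) ov$identifiable else NA,
               row.names = NULL)
  })
  summary_tab <- do.call(rbind, sum_rows)
  rhats <- stats::setNames(summary_tab$rhat, summary_tab$parameter)
  rhats <- rhats[!is.na(rhats)]

  structure(
    list(draws = draws_pop, summary = summary_tab, overlap = overlap_tab,
         converged = all(rhats < 1.01),
         rhat = rhats,
         flags = list(lambda_boundary =
                        stats::median(draws_pop$lambda) < 1e-4),
         mechanism = mechanism, tau = tau, priors = priors,
         settings = list(n_chains = n_chains, n_steps = n_steps,
                         n_walkers = n_walkers, thin = thin,
                         overlap_threshold = overlap_threshold),
         seed = seed),
    class = "psk_posterior"
  )
}
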