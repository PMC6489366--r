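# Seeded generators for every input the pipeline consumes, with ground truth.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Hierarchical ground truth for synthetic loss-curve experiments
#'
#' Defines a population of replicate cultures whose model parameters vary
#' around shared means, mirroring day-to-day and lineage variation between
#' replicates of a passaging assay. The hierarchy lives on transformed scales
#' (logit for the bounded `lambda` and `omega`, log for the positive `gamma`)
#' with normal replicate deviations, so back-transformed draws always respect
#' the parameter bounds.
#'
#' @param mechanism Killing mechanism, as in [psk_params()].
#' @param mean_lambda,mean_gamma,mean_omega Population means on the natural
#'   scale.
#' @param sd_logit_lambda,sd_log_gamma,sd_logit_omega Replicate-to-replicate
#'   standard deviations on the transformed scales.
#' @param n_replicates Number of replicate cultures (default 9).
#' @param seed Integer seed for the replicate draws.
#' @return An object of class `psk_truth`: the population-level settings plus
#'   a `replicates` data.frame of per-replicate parameter draws.
#' @export
hierarchical_truth <- function(mechanism = "TA",
                               mean_lambda = 0.01, mean_gamma = 0.9,
                               mean_omega = 0.95,
                               sd_logit_lambda = 0.3, sd_log_gamma = 0.05,
                               sd_logit_omega = 0.3,
                               n_replicates = 9, seed = 1) {
  stopifnot(n_replicates >= 1)
  mechanism <- match.arg(mechanism, c("NONE", "TA", "BACTERIOCIN"))
  if (mechanism == "NONE") mean_omega <- 0
  draws <- with_seed(seed, {
    zl <- stats::rnorm(n_replicates)
    zg <- stats::rnorm(n_replicates)
    zw <- stats::rnorm(n_replicates)
    lambda <- if (mean_lambda == 0) rep(0, n_replicates)
              else stats::plogis(stats::qlogis(mean_lambda) + sd_logit_lambda * zl)
    gamma <- exp(log(mean_gamma) + sd_log_gamma * zg)
    omega <- if (mechanism == "NONE" || mean_omega == 0) rep(0, n_replicates)
             else if (mean_omega == 1) rep(1, n_replicates)
             else stats::plogis(stats::qlogis(mean_omega) + sd_logit_omega * zw)
    data.frame(replicate_id = paste0("r", seq_len(n_replicates)),
               lambda_loss = lambda, gamma = gamma, omega = omega)
  })
  structure(
    list(mechanism = mechanism,
         mean_lambda = mean_lambda, mean_gamma = mean_gamma,
         mean_omega = mean_omega,
         sd_logit_lambda = sd_logit_lambda, sd_log_gamma = sd_log_gamma,
         sd_logit_omega = sd_logit_omega,
         n_replicates = as.integer(n_replicates), seed = seed,
         replicates = draws),
    class = "psk_truth"
  )
}

#' @export
print.psk_truth <- function(x, ...) {
  cat(sprintf(
    "Hierarchical truth [%s]: %d replicates\n  population lambda %.4g, gamma %.4g, omega %.4g (seed %s)\n",
    x$mechanism, x$n_replicates, x$mean_lambda, x$mean_gamma, x$mean_omega,
    format(x$seed)))
  invisible(x)
}

#' Generate noisy synthetic plasmid-loss curves with known truth
#'
#' For each replicate in `truth`, simulates the deterministic loss curve under
#' the replicate's drawn parameters and corrupts every per-passage fraction
#' with a bounded observation model: `"binomial"` resamples the fraction as a
#' binomial count over `n_events` cytometry events; `"beta"` draws from a Beta
#' with the model fraction as mean and precision `phi`, emulating
#' overdispersed day effects. Optionally a binomial bottleneck resamples the
#' culture composition at each dilution.
#'
#' @param truth A [hierarchical_truth()].
#' @param protocol A [passaging_protocol()].
#' @param n_events Events per cytometry sample underlying each fraction.
#' @param noise `"binomial"` or `"beta"`.
#' @param phi Beta precision (used when `noise = "beta"`).
#' @param bottleneck Logical; apply binomial sampling of
#'   `initial_total / dilution_factor` cells at each dilution.
#' @param seed Integer seed.
#' @return A list of class `psk_synth_loss` with elements `curves` (long
#'   loss-curve data.frame across replicates) and `truth` (the per-replicate
#'   parameter table), plus the generator settings.
#' @export
generate_loss_curves <- function(truth, protocol, n_events = 10000,
                                 noise = c("binomial", "beta"), phi = 500,
                                 bottleneck = FALSE, seed = 1) {
  stopifnot(inherits(truth, "psk_truth"), inherits(protocol, "psk_protocol"),
            n_events >= 1)
  noise <- match.arg(noise)
  curves <- with_seed(seed, {
    out <- vector("list", truth$n_replicates)
    for (i in seq_len(truth$n_replicates)) {
      row <- truth$replicates[i, ]
      params <- psk_params(row$lambda_loss, row$gamma, row$omega,
                           mechanism = truth$mechanism)
      latent <- if (bottleneck) {
        lat <- numeric(protocol$n_passages + 1L)
        lat[1L] <- protocol$initial_fraction
        state <- population_state(
          protocol$initial_total * protocol$initial_fraction,
          protocol$initial_total * (1 - protocol$initial_fraction))
        n_keep <- max(1, round(protocol$initial_total / protocol$dilution_factor))
        for (p in seq_len(protocol$n_passages)) {
          state <- closed_form_solution(state, params, protocol$tau_per_passage)
          f <- psk_fraction(state)
          lat[p + 1L] <- f
          k <- stats::rbinom(1L, n_keep, f)
          state <- population_state(k, n_keep - k, state$tau)
          if (n_keep == 0) stop("bottleneck removed all cells; increase 'initial_total'")
        }
        lat
      } else {
        fraction_at_passages(params, protocol, 0:protocol$n_passages)
      }
      obs <- switch(noise,
        binomial = stats::rbinom(length(latent), n_events, latent) / n_events,
        beta = {
          fc <- pmin(pmax(latent, 1e-6), 1 - 1e-6)
          stats::rbeta(length(fc), fc * phi, (1 - fc) * phi)
        })
      out[[i]] <- data.frame(replicate_id = row$replicate_id,
                             passage = 0:protocol$n_passages,
                             fraction = obs,
                             n_events = n_events)
    }
    do.call(rbind, out)
  })
  structure(list(curves = curves, truth = truth$replicates,
                 mechanism = truth$mechanism, noise = noise, phi = phi,
                 n_events = n_events, bottleneck = bottleneck,
                 protocol = protocol, seed = seed),
            class = "psk_synth_loss")
}

#' Generate a synthetic flow-cytometry event table
#'
#' Emulates a cytometer sample from a mixed culture: log10 fluorescence is a
#' two-component location-scale mixture (plasmid-free autofluorescence mode
#' and a reporter mode `separation_decades` higher), scatter channels are
#' log-normal cell-sized clouds, and a debris component sits at low scatter
#' and low fluorescence. True labels are attached for benchmarking gates.
#'
#' @param fraction_bearing True plasmid-bearing fraction among cells, `[0,1]`.
#' @param n_events Number of events (>= 1).
#' @param separation_decades log10 distance between the free and bearing
#'   fluorescence modes (default 2).
#' @param debris_fraction Fraction of events that are debris, `[0, 1)`.
#' @param seed Integer seed.
#' @param mu_free_log10 Autofluorescence mode, log10 arbitrary units.
#' @param sigma_log10 Within-component sd of log10 fluorescence.
#' @return A `data.frame` with positive columns `fsc`, `ssc`, `fl1` and a
#'   `label` column in `{bearing, free, debris}`.
#' @export
generate_events <- function(fraction_bearing, n_events = 10000,
                            separation_decades = 2, debris_fraction = 0.05,
                            seed = 1, mu_free_log10 = 2, sigma_log10 = 0.25) {
  stopifnot(n_events >= 1,
            fraction_bearing >= 0, fraction_bearing <= 1,
            debris_fraction >= 0, debris_fraction < 1)
  with_seed(seed, {
    pr <- c(debris = debris_fraction,
            bearing = (1 - debris_fraction) * fraction_bearing,
            free = (1 - debris_fraction) * (1 - fraction_bearing))
    label <- sample(names(pr), n_events, replace = TRUE, prob = pr)
    n <- n_events
    fsc <- ssc <- fl1 <- numeric(n)
    cell <- label != "debris"
    fsc[cell] <- 10^stats::rnorm(sum(cell), 2.5, 0.15)
    ssc[cell] <- 10^stats::rnorm(sum(cell), 2.2, 0.15)
    deb <- !cell
    fsc[deb] <- 10^stats::rnorm(sum(deb), 1.3, 0.2)
    ssc[deb] <- 10^stats::rnorm(sum(deb), 1.0, 0.2)
    mu <- ifelse(label == "bearing", mu_free_log10 + separation_decades,
                 ifelse(label == "free", mu_free_log10, mu_free_log10 - 0.3))
    sdv <- ifelse(deb, 0.3, sigma_log10)
    fl1 <- 10^stats::rnorm(n, mu, sdv)
    data.frame(fsc = fsc, ssc = ssc, fl1 = fl1, label = label)
  })
}

#' Generate a synthetic optical-density growth curve
#'
#' Logistic growth after a lag phase, observed at regular intervals with
#' multiplicative log-normal noise (sd on the log-OD scale). The exit from
#' lag is smoothed over `lag_smooth` minutes (softplus effective time), as
#' cultures resume growth gradually rather than at a sharp corner. The true
#' maximal specific growth rate is attached for benchmarking estimators.
#'
#' @param mu_max True maximal specific growth rate, per minute (> 0).
#' @param lag Lag time before growth starts, minutes.
#' @param lag_smooth Width of the lag-to-growth transition, minutes.
#' @param capacity Carrying capacity, OD units.
#' @param noise_sd Standard deviation of log-OD noise (0 for noiseless).
#' @param sampling Sampling interval, minutes.
#' @param duration Total duration, minutes.
#' @param od0 Inoculum optical density.
#' @param label Metadata label carried in the output.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `time_min`, `od`, `label`, and
#'   attributes `mu_max`, `lag`, `capacity` recording the truth.
#' @export
generate_growth_curve <- function(mu_max, lag = 120, capacity = 1,
                                  noise_sd = 0.01, sampling = 10,
                                  duration = 1440, od0 = 0.01,
                                  lag_smooth = 15, label = "sample", seed = 1) {
  stopifnot(mu_max > 0, od0 > 0, capacity > od0, sampling > 0)
  time <- seq(0, duration, by = sampling)
  t_eff <- if (lag_smooth > 0) {
    # softplus: ~0 well before the lag ends, ~(t - lag) well after
    lag_smooth * log1p(exp((time - lag) / lag_smooth))
  } else pmax(time - lag, 0)
  det <- od0 * capacity / (od0 + (capacity - od0) * exp(-mu_max * t_eff))
  od <- if (noise_sd > 0) {
    with_seed(seed, det * exp(stats::rnorm(length(det), 0, noise_sd)))
  } else det
  structure(data.frame(time_min = time, od = od, label = label),
            mu_max = mu_max, lag = lag, capacity = capacity)
}
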