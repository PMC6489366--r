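# Automated gating: event tables -> plasmid-bearing fractions.
#
# Pipeline: debris exclusion on the scatter channels, log10 transform of the
# fluorescence channel, then a 1- vs 2-component Gaussian mixture chosen by
# BIC. With two resolvable components the higher-mean one is "bearing" and
# the fraction is its responsibility-weighted share; with one component the
# whole sample is assigned by comparing its mode to a reference
# autofluorescence level.

check_event_table <- function(events) {
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("'events' must be a non-empty data.frame")
  need <- c("fsc", "ssc", "fl1")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(events)
}

#' Remove debris events by scatter gating
#'
#' Drops events that fall below the `scatter_quantile` sample quantile on
#' both scatter channels (debris is small and low-complexity, hence low on
#' both). An optional absolute floor `min_scatter` (linear units, recycled to
#' the two channels) additionally removes events below the instrument noise
#' floor on both channels; unlike a sample quantile, the floor can empty an
#' all-debris sample.
#'
#' @param events Event `data.frame` with columns `fsc`, `ssc`, `fl1`.
#' @param scatter_quantile Quantile in `[0, 1)` under which (on both
#'   channels) events are removed; 0 disables the quantile gate.
#' @param min_scatter Optional numeric floor(s) for `fsc`/`ssc`.
#' @return The gated event table, with attribute `n_removed`.
#' @export
remove_debris <- function(events, scatter_quantile = 0.05,
                          min_scatter = NULL) {
  check_event_table(events)
  if (scatter_quantile < 0 || scatter_quantile >= 1)
    stop("'scatter_quantile' must lie in [0, 1)")
  drop <- rep(FALSE, nrow(events))
  if (scatter_quantile > 0) {
    qf <- stats::quantile(events$fsc, scatter_quantile, names = FALSE)
    qs <- stats::quantile(events$ssc, scatter_quantile, names = FALSE)
    drop <- events$fsc < qf & events$ssc < qs
  }
  if (!is.null(min_scatter)) {
    ms <- rep_len(min_scatter, 2L)
    drop <- drop | (events$fsc < ms[1L] & events$ssc < ms[2L])
  }
  out <- events[!drop, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all events removed as debris")
  else if (mean(drop) > 0.5)
    warning("more than half of the events were gated out as debris")
  attr(out, "n_removed") <- sum(drop)
  out
}

# EM for a k-component univariate Gaussian mixture (k = 1 or 2)
gmm_fit <- function(x, k, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x); sd <- stats::sd(x)
    if (!is.finite(sd) || sd < 1e-6) sd <- 1e-6
    ll <- sum(stats::dnorm(x, mu, sd, log = TRUE))
    return(list(k = 1L, pi = 1, mu = mu, sd = sd, loglik = ll,
                resp = matrix(1, n, 1), npar = 2L))
  }
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(mu) < 1e-8) mu <- mu + c(-1e-3, 1e-3)
  sd <- rep(max(stats::sd(x) / 2, 1e-4), 2L)
  pi <- c(0.5, 0.5)
  ll_old <- -Inf
  resp <- matrix(0, n, 2L)
  for (it in seq_len(max_iter)) {
    d1 <- log(pi[1]) + stats::dnorm(x, mu[1], sd[1], log = TRUE)
    d2 <- log(pi[2]) + stats::dnorm(x, mu[2], sd[2], log = TRUE)
    mx <- pmax(d1, d2)
    den <- mx + log(exp(d1 - mx) + exp(d2 - mx))
    resp[, 1] <- exp(d1 - den)
    resp[, 2] <- exp(d2 - den)
    ll <- sum(den)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break  # component died; keep last estimates
    pi <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sd <- pmax(sd, 1e-4)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(k = 2L, pi = pi, mu = mu, sd = sd, loglik = ll, resp = resp, npar = 5L)
}

#' Classify fluorescence events into plasmid-bearing and plasmid-free
#'
#' Runs the automated gating pipeline on one sample: debris exclusion, log10
#' transform of `fl1`, then 1- and 2-component Gaussian-mixture fits compared
#' by BIC. With two components whose means differ by at least
#' `resolve_decades` the higher-mean component is "bearing" and the reported
#' fraction is its mean responsibility; components closer than that are
#' deemed unresolvable and the sample is treated as unimodal. A unimodal
#' sample is assigned wholly to bearing or free by comparing its mode to the
#' `reference` autofluorescence level.
#'
#' @param events Event `data.frame` (`fsc`, `ssc`, `fl1`).
#' @param reference Reference autofluorescence level in log10 units; modes
#'   above it are called plasmid-bearing. Default 3. Derive from a
#'   plasmid-free control with [reference_from_control()].
#' @param scatter_quantile Debris gate passed to [remove_debris()].
#' @param min_events Minimum events required after debris removal.
#' @param resolve_decades Minimum separation (log10) for two components to
#'   count as resolved.
#' @return An object of class `psk_gating`: `fraction_bearing`,
#'   `n_events_used`, `n_debris_removed`, `n_components_selected`,
#'   `component_means`, `component_sds`, `component_weights`, `threshold`
#'   (log10 units; `NA` for unimodal samples) and `unresolved` flag.
#' @export
classify_events <- function(events, reference = 3, scatter_quantile = 0.05,
                            min_events = 50, resolve_decades = 0.2) {
  check_event_table(events)
  gated <- remove_debris(events, scatter_quantile)
  n_debris <- attr(gated, "n_removed")
  if (nrow(gated) < min_events)
    stop("too few events after debris removal (", nrow(gated), " < ",
         min_events, ")")
  if (any(gated$fl1 <= 0))
    stop("non-positive fluorescence values; cannot log-transform")
  x <- log10(gated$fl1)
  f1 <- gmm_fit(x, 1L)
  f2 <- gmm_fit(x, 2L)
  n <- length(x)
  bic <- c(-2 * f1$loglik + f1$npar * log(n),
           -2 * f2$loglik + f2$npar * log(n))
  use2 <- bic[2] < bic[1]
  unresolved <- FALSE
  if (use2 && abs(diff(f2$mu)) < resolve_decades) {
    use2 <- FALSE
    unresolved <- TRUE
  }
  if (use2) {
    hi <- which.max(f2$mu)
    frac <- mean(f2$resp[, hi])
    # decision boundary: fluorescence where the posterior odds flip, searched
    # between the two means
    thr <- tryCatch(
      stats::uniroot(function(z) {
        (log(f2$pi[hi]) + stats::dnorm(z, f2$mu[hi], f2$sd[hi], log = TRUE)) -
          (log(f2$pi[3 - hi]) + stats::dnorm(z, f2$mu[3 - hi], f2$sd[3 - hi],
                                             log = TRUE))
      }, range(f2$mu))$root,
      error = function(e) mean(f2$mu))
    res <- list(fraction_bearing = frac, n_components_selected = 2L,
                component_means = f2$mu, component_sds = f2$sd,
                component_weights = f2$pi, threshold = thr)
  } else {
    frac <- if (f1$mu > reference) 1 else 0
    res <- list(fraction_bearing = frac, n_components_selected = 1L,
                component_means = f1$mu, component_sds = f1$sd,
                component_weights = 1, threshold = NA_real_)
  }
  structure(c(res, list(n_events_used = nrow(gated),
                        n_debris_removed = n_debris,
                        unresolved = unresolved, reference = reference)),
            class = "psk_gating")
}

#' @export
print.psk_gating <- function(x, ...) {
  cat(sprintf(
    "Gating result: fraction bearing %.4f (%d events used, %d debris removed)\n  components: %d%s\n",
    x$fraction_bearing, x$n_events_used, x$n_debris_removed,
    x$n_components_selected,
    if (x$unresolved) " [populations unresolvable]" else ""))
  invisible(x)
}

#' Reference autofluorescence level from a plasmid-free control
#'
#' Upper bound of the control sample's log10 fluorescence distribution
#' (mean + 2 sd after debris removal), for use as the `reference` argument of
#' [classify_events()].
#'
#' @param control_events Event table from a plasmid-free control sample.
#' @param scatter_quantile Debris gate quantile.
#' @return Reference level in log10 fluorescence units.
#' @export
reference_from_control <- function(control_events, scatter_quantile = 0.05) {
  gated <- remove_debris(control_events, scatter_quantile)
  x <- log10(gated$fl1[gated$fl1 > 0])
  mean(x) + 2 * stats::sd(x)
}

#' Assemble per-sample gating results into loss curves
#'
#' Gates each sample of a passaging experiment and assembles the
#' plasmid-bearing fractions into loss-curve records ordered by passage.
#' Sample names must have the form `<replicate>_<passage>` (the text after
#' the final underscore is the passage index).
#'
#' @param samples Named list of event tables, keyed `<replicate>_<passage>`.
#' @param ... Further arguments passed to [classify_events()].
#' @return A loss-curve `data.frame` (`replicate_id`, `passage`, `fraction`,
#'   `n_events`), sorted by replicate then passage.
#' @export
batch_fractions <- function(samples, ...) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  keys <- names(samples)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("'samples' must be a named list keyed '<replicate>_<passage>'")
  rep_id <- sub("_[^_]*$", "", keys)
  pass <- suppressWarnings(as.integer(sub("^.*_", "", keys)))
  if (any(is.na(pass)))
    stop("sample keys not parseable into (replicate, passage): ",
         paste(keys[is.na(pass)], collapse = ", "))
  if (anyDuplicated(paste(rep_id, pass)))
    stop("duplicate (replicate, passage) keys in 'samples'")
  rows <- lapply(seq_along(samples), function(i) {
    g <- classify_events(samples[[i]], ...)
    data.frame(replicate_id = rep_id[i], passage = pass[i],
               fraction = g$fraction_bearing, n_events = g$n_events_used)
  })
  out <- do.call(rbind, rows)
  out[order(out$replicate_id, out$passage), , drop = FALSE]
}
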