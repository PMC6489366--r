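# Serial dilute-and-regrow passaging on top of the linear model.

#' Serial-passaging protocol
#'
#' Describes a daily dilute-and-regrow plasmid-stability assay. Each passage
#' grows the culture for `tau_per_passage` model time units and then dilutes
#' both populations `dilution_factor`-fold. The default regrowth time
#' `log(dilution_factor)` is the time a culture growing at the plasmid-free
#' rate (1 per model time unit) needs to recover its pre-dilution density,
#' so a passage is self-consistent with the model's time units.
#'
#' @param dilution_factor Fold-dilution applied at each passage (> 1).
#' @param n_passages Number of passages simulated (>= 1).
#' @param tau_per_passage Model time of regrowth per passage (> 0); defaults
#'   to `log(dilution_factor)`.
#' @param initial_fraction Plasmid-bearing fraction at passage 0, in `[0, 1]`.
#' @param initial_total Abundance scale of the culture at passage 0 (> 0).
#' @return An object of class `psk_protocol`.
#' @export
passaging_protocol <- function(dilution_factor = 1000, n_passages = 37,
                               tau_per_passage = log(dilution_factor),
                               initial_fraction = 1, initial_total = 1e9) {
  stopifnot(is.numeric(dilution_factor), is.numeric(n_passages),
            is.numeric(tau_per_passage), is.numeric(initial_fraction),
            is.numeric(initial_total))
  if (dilution_factor <= 1) stop("'dilution_factor' must be > 1")
  if (n_passages < 1 || n_passages != round(n_passages))
    stop("'n_passages' must be a positive integer")
  if (!is.finite(tau_per_passage) || tau_per_passage <= 0)
    stop("'tau_per_passage' must be finite and > 0")
  if (initial_fraction < 0 || initial_fraction > 1)
    stop("'initial_fraction' must lie in [0, 1]")
  if (initial_total <= 0) stop("'initial_total' must be > 0")
  structure(
    list(dilution_factor = dilution_factor,
         n_passages = as.integer(n_passages),
         tau_per_passage = tau_per_passage,
         initial_fraction = initial_fraction,
         initial_total = initial_total),
    class = "psk_protocol"
  )
}

#' @export
print.psk_protocol <- function(x, ...) {
  cat(sprintf(
    "Passaging protocol: %d passages, 1:%g dilution, tau %.3f per passage\n  initial fraction %.4g at total %.3g\n",
    x$n_passages, x$dilution_factor, x$tau_per_passage,
    x$initial_fraction, x$initial_total))
  invisible(x)
}

#' Simulate a deterministic plasmid-loss curve
#'
#' Iterates the passaging protocol: each passage advances the population by
#' the closed-form model solution over `tau_per_passage`, then divides both
#' populations by the dilution factor (deterministic dilution preserves the
#' plasmid-bearing fraction exactly). The fraction is recorded at every
#' passage boundary, starting from passage 0.
#'
#' @param params A [psk_params()].
#' @param protocol A [passaging_protocol()].
#' @param replicate_id Label attached to the output rows.
#' @return A loss-curve `data.frame` with columns `replicate_id`, `passage`
#'   (0 .. `n_passages`), `fraction` and `n_events` (`NA` for deterministic
#'   simulation).
#' @examples
#' simulate_loss_curve(psk_params(0.1, 1, mechanism = "TA"),
#'                     passaging_protocol(n_passages = 10))
#' @export
simulate_loss_curve <- function(params, protocol, replicate_id = "sim") {
  stopifnot(inherits(params, "psk_params"), inherits(protocol, "psk_protocol"))
  state <- population_state(
    protocol$initial_total * protocol$initial_fraction,
    protocol$initial_total * (1 - protocol$initial_fraction))
  frac <- numeric(protocol$n_passages + 1L)
  frac[1L] <- protocol$initial_fraction
  for (p in seq_len(protocol$n_passages)) {
    state <- closed_form_solution(state, params, protocol$tau_per_passage)
    frac[p + 1L] <- psk_fraction(state)
    state$x_plus <- state$x_plus / protocol$dilution_factor
    state$x_minus <- state$x_minus / protocol$dilution_factor
    if ((state$x_plus + state$x_minus) < .Machine$double.xmin * 1e8)
      stop("population underflow during passaging; increase 'initial_total'")
  }
  data.frame(replicate_id = replicate_id,
             passage = 0:protocol$n_passages,
             fraction = frac,
             n_events = NA_real_)
}

# Plasmid-bearing fraction at given passage indices, evaluated directly from
# the closed form (deterministic dilution is fraction-preserving and the flow
# is linear, so the fraction at passage p equals the fraction of the undiluted
# solution at time p * tau_per_passage). Everything is computed relative to
# the dominant exponent, so no intermediate can overflow however extreme the
# parameters; the resonant a = b limit is the continuous g -> 1 limit.
# Vectorised over passages. Used as the inference forward model.
fraction_at_passages <- function(params, protocol, passages) {
  r <- psk_rates(params)
  f0 <- protocol$initial_fraction
  t <- passages * protocol$tau_per_passage
  dt <- (r$a - r$b) * t
  adt <- abs(dt)
  g <- ifelse(adt < 1e-12, 1, -expm1(-adt) / pmax(adt, 1e-300))
  u <- f0 * exp(pmin(dt, 0))
  v <- (1 - f0) * exp(pmin(-dt, 0)) + r$cc * f0 * t * g
  u / (u + v)
}

#' Predict single-passage competition outcomes over a dilution series
#'
#' Models the restoration experiment in which a plasmid-bearing culture is
#' deliberately diluted with plasmid-free cells at a series of ratios and
#' sampled after one passage of regrowth. For each starting fraction the
#' closed-form model fraction after time `tau` is returned.
#'
#' @param params A [psk_params()].
#' @param initial_fractions Numeric vector of starting plasmid-bearing
#'   fractions in `[0, 1]`.
#' @param tau Regrowth time for the passage (default `log(1000)`, one
#'   thousand-fold regrowth).
#' @return Numeric vector of predicted plasmid-bearing fractions after the
#'   passage, same length as `initial_fractions`.
#' @examples
#' p <- psk_params(1e-4, 0.9, omega = 0.9, mechanism = "BACTERIOCIN")
#' predict_competition(p, seq(0.1, 0.9, by = 0.2))
#' @export
predict_competition <- function(params, initial_fractions, tau = log(1000)) {
  stopifnot(inherits(params, "psk_params"), is.numeric(initial_fractions))
  if (any(is.na(initial_fractions)) ||
      any(initial_fractions < 0 | initial_fractions > 1))
    stop("'initial_fractions' must lie in [0, 1]")
  if (!is.finite(tau) || tau < 0) stop("'tau' must be >= 0 and finite")
  r <- psk_rates(params)
  dt <- (r$a - r$b) * tau
  g <- if (abs(dt) < 1e-12) 1 else -expm1(-abs(dt)) / abs(dt)
  u <- initial_fractions * exp(min(dt, 0))
  v <- (1 - initial_fractions) * exp(min(-dt, 0)) +
    r$cc * initial_fractions * tau * g
  ifelse(u + v == 0, NA_real_, u / (u + v))
}

#' Sweep one model parameter across a set of values
#'
#' Simulates one loss curve per value of the swept parameter, holding the
#' others at their values in `base`. Useful for sensitivity displays of how
#' loss probability, burden and killing efficacy shape the loss curve.
#'
#' @param base A [psk_params()] supplying the non-swept parameters.
#' @param protocol A [passaging_protocol()].
#' @param parameter One of `"lambda_loss"`, `"gamma"`, `"omega"`.
#' @param values Numeric vector of values to sweep.
#' @return A long `data.frame` with columns `parameter`, `value`, `passage`,
#'   `fraction`.
#' @export
parameter_sweep <- function(base, protocol, parameter, values) {
  stopifnot(inherits(base, "psk_params"), is.numeric(values),
            length(values) >= 1L)
  if (!parameter %in% c("lambda_loss", "gamma", "omega"))
    stop("unknown parameter '", parameter,
         "'; must be one of lambda_loss, gamma, omega")
  out <- lapply(values, function(v) {
    args <- base[c("lambda_loss", "gamma", "omega", "mechanism")]
    args[[parameter]] <- v
    cur <- simulate_loss_curve(do.call(psk_params, args), protocol,
                               replicate_id = paste0(parameter, "=", v))
    data.frame(parameter = parameter, value = v,
               passage = cur$passage, fraction = cur$fraction)
  })
  do.call(rbind, out)
}
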