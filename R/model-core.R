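# Core two-population dynamics.
#
# In plasmid-free e-folding time units the model is linear:
#   dX+/dtau = gamma*(1 - lambda) * X+
#   dX-/dtau = b * X- + c * X+
# with, for TA/NONE:       b = 1,            c = (1 - omega) * lambda * gamma
# and for BACTERIOCIN:     b = 1 - 2*omega,  c = lambda * gamma
# (the toxin-antitoxin system kills newly plasmid-free daughters at birth,
# the bacteriocin kills the standing plasmid-free population).

# growth exponents and influx coefficient for a parameter set
psk_rates <- function(params) {
  a <- params$gamma * (1 - params$lambda_loss)
  if (params$mechanism == "BACTERIOCIN") {
    b <- 1 - 2 * params$omega
    cc <- params$lambda_loss * params$gamma
  } else {
    b <- 1
    cc <- (1 - params$omega) * params$lambda_loss * params$gamma
  }
  list(a = a, b = b, cc = cc)
}

#' Instantaneous rates of the plasmid-stability model
#'
#' Right-hand side of the two-population linear system. For `TA`/`NONE` the
#' plasmid-free population gains `(1 - omega)` of the loss influx
#' `lambda * gamma * X+` (killing intercepts newly plasmid-free daughters);
#' for `BACTERIOCIN` the full influx arrives but the standing plasmid-free
#' population is killed at rate `2 * omega`.
#'
#' @param state A [population_state()].
#' @param params A [psk_params()].
#' @return Named numeric vector `c(dx_plus, dx_minus)` of rates per unit
#'   model time.
#' @examples
#' psk_derivatives(population_state(1, 0),
#'                 psk_params(0.1, 1, omega = 1, mechanism = "TA"))
#' @export
psk_derivatives <- function(state, params) {
  if (state$x_plus < 0 || state$x_minus < 0)
    stop("invalid state: negative abundances")
  r <- psk_rates(params)
  c(dx_plus = r$a * state$x_plus,
    dx_minus = r$b * state$x_minus + r$cc * state$x_plus)
}

# stable (exp(a*t) - exp(b*t)) / (a - b), resonant limit t*exp(a*t) as a -> b
psk_phi <- function(a, b, tau) {
  d <- a - b
  if (abs(d * tau) < 1e-12) {
    tau * exp(a * tau)
  } else {
    exp(b * tau) * expm1(d * tau) / d
  }
}

#' Closed-form solution of the plasmid-stability model
#'
#' Exact analytic solution of the linear two-population system after elapsed
#' model time `tau`. The plasmid-bearing population grows as
#' `exp(gamma * (1 - lambda) * tau)`; the plasmid-free population is the
#' matching forced-linear solution. When the two growth exponents coincide the
#' resonant `tau * exp(a * tau)` form is used exactly rather than perturbing
#' the parameters.
#'
#' @param state0 Initial [population_state()].
#' @param params A [psk_params()].
#' @param tau Elapsed model time (>= 0, plasmid-free e-folding units).
#' @return The [population_state()] after time `tau` (its `tau` field is
#'   advanced by the elapsed time).
#' @examples
#' p <- psk_params(0.1, 1, mechanism = "TA")
#' closed_form_solution(population_state(1, 0), p, log(1000))
#' @export
closed_form_solution <- function(state0, params, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  if (is.na(tau) || tau < 0) stop("'tau' must be >= 0")
  if (state0$x_plus < 0 || state0$x_minus < 0)
    stop("invalid state: negative abundances")
  r <- psk_rates(params)
  xp <- state0$x_plus * exp(r$a * tau)
  xm <- state0$x_minus * exp(r$b * tau) +
    r$cc * state0$x_plus * psk_phi(r$a, r$b, tau)
  # the analytic form is non-negative for valid inputs; clamp roundoff only
  population_state(max(xp, 0), max(xm, 0), state0$tau + tau)
}

#' Long-run plasmid-bearing fraction
#'
#' Limit of `X+ / (X+ + X-)` as model time grows, starting from a population
#' with plasmid-bearing cells present. When the plasmid-free growth exponent
#' (1 for `TA`/`NONE`, `1 - 2*omega` for `BACTERIOCIN`) exceeds the
#' plasmid-bearing exponent `gamma * (1 - lambda)` the plasmid is lost
#' (limit 0). Otherwise the populations coexist at the fraction set by the
#' forced-mode amplitude ratio; with no loss influx and no initial
#' plasmid-free cells the limit is 1. An exact tie of the two exponents with
#' a nonzero influx decays resonantly to 0 and is flagged.
#'
#' @param params A [psk_params()].
#' @param x_minus_present Logical; whether plasmid-free cells are present
#'   initially (matters only when the loss influx is zero). Default `FALSE`.
#' @return The limiting fraction in `[0, 1]`, with attribute `degenerate`
#'   set to `TRUE` when the growth exponents tie exactly.
#' @examples
#' asymptotic_fraction(psk_params(0.1, 1, omega = 0.5, mechanism = "BACTERIOCIN"))
#' @export
asymptotic_fraction <- function(params, x_minus_present = FALSE) {
  r <- psk_rates(params)
  degenerate <- FALSE
  if (r$cc == 0 && !x_minus_present) {
    f <- 1
  } else if (r$a > r$b) {
    # X-/X+ -> cc / (a - b) whatever the initial composition
    f <- (r$a - r$b) / ((r$a - r$b) + r$cc)
  } else if (r$a < r$b) {
    f <- 0
  } else {
    # exact tie: with influx the resonant mode wins; without, the fraction is
    # frozen at its initial value and no state-free limit exists
    degenerate <- TRUE
    f <- if (r$cc > 0) 0 else NA_real_
  }
  structure(f, degenerate = degenerate)
}
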