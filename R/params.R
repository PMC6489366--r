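#' Model parameters for plasmid loss with post-segregational killing
#'
#' Bundles the three parameters of the two-population plasmid-stability model
#' together with the killing mechanism.
#'
#' @param lambda_loss Probability that a dividing plasmid-bearing cell produces
#'   a plasmid-free daughter, in `[0, 1]`. Related to mean plasmid copy number
#'   `n` by `lambda = 2^(1 - n)` (see [copy_number_to_loss_prob()]).
#' @param gamma Ratio of the plasmid-free doubling time to the plasmid-bearing
#'   doubling time (> 0). Values below 1 mean the plasmid burdens growth.
#' @param omega Probability of successful post-segregational killing, in
#'   `[0, 1]`. `1 - omega` is the survival probability of a plasmid-free cell
#'   (TA) or the per-unit-time escape from bacteriocin policing.
#' @param mechanism One of `"NONE"`, `"TA"` (toxin-antitoxin: killing acts on
#'   newly plasmid-free daughters only) or `"BACTERIOCIN"` (secreted toxin:
#'   constant killing pressure on the whole plasmid-free population).
#'   `"NONE"` forces `omega = 0`.
#' @return An object of class `psk_params`.
#' @examples
#' psk_params(lambda_loss = 0.01, gamma = 0.9, omega = 0.95, mechanism = "TA")
#' @export
psk_params <- function(lambda_loss, gamma, omega = 0,
                       mechanism = c("NONE", "TA", "BACTERIOCIN")) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(lambda_loss), length(lambda_loss) == 1L,
            is.numeric(gamma), length(gamma) == 1L,
            is.numeric(omega), length(omega) == 1L)
  if (is.na(lambda_loss) || lambda_loss < 0 || lambda_loss > 1)
    stop("'lambda_loss' must lie in [0, 1]")
  if (is.na(gamma) || gamma <= 0)
    stop("'gamma' must be > 0")
  if (is.na(omega) || omega < 0 || omega > 1)
    stop("'omega' must lie in [0, 1]")
  if (mechanism == "NONE") omega <- 0
  structure(
    list(lambda_loss = lambda_loss, gamma = gamma, omega = omega,
         mechanism = mechanism),
    class = "psk_params"
  )
}

#' @export
print.psk_params <- function(x, ...) {
  cat(sprintf(
    "PSK model parameters [%s]\n  lambda (loss probability) = %g\n  gamma  (burden ratio)     = %g\n  omega  (killing efficacy) = %g\n",
    x$mechanism, x$lambda_loss, x$gamma, x$omega))
  invisible(x)
}

#' Population state of the two-population plasmid model
#'
#' @param x_plus Plasmid-bearing abundance (>= 0, arbitrary scale).
#' @param x_minus Plasmid-free abundance (>= 0).
#' @param tau Elapsed model time in plasmid-free e-folding units (>= 0).
#' @return An object of class `psk_state`.
#' @seealso [psk_fraction()]
#' @export
population_state <- function(x_plus, x_minus = 0, tau = 0) {
  stopifnot(is.numeric(x_plus), is.numeric(x_minus), is.numeric(tau))
  if (is.na(x_plus) || x_plus < 0) stop("'x_plus' must be >= 0")
  if (is.na(x_minus) || x_minus < 0) stop("'x_minus' must be >= 0")
  if (is.na(tau) || tau < 0) stop("'tau' must be >= 0")
  structure(list(x_plus = x_plus, x_minus = x_minus, tau = tau),
            class = "psk_state")
}

#' @export
print.psk_state <- function(x, ...) {
  cat(sprintf("Population state at tau = %g\n  X+ = %g, X- = %g (fraction %s)\n",
              x$tau, x$x_plus, x$x_minus,
              format(psk_fraction(x), digits = 6)))
  invisible(x)
}

#' Plasmid-bearing fraction of a population state
#'
#' @param state A [population_state()].
#' @return `x_plus / (x_plus + x_minus)`, or `NA` when the total is zero.
#' @export
psk_fraction <- function(state) {
  tot <- state$x_plus + state$x_minus
  if (tot <= 0) return(NA_real_)
  state$x_plus / tot
}

#' Convert mean plasmid copy number to the per-division loss probability
#'
#' Under independent random segregation of `n` plasmid copies at division the
#' probability that one daughter receives no copy is `2^(1 - n)`; values are
#' clipped to `[0, 1]` (copy numbers below 1 would exceed certainty).
#'
#' @param n Mean plasmid copy number per cell (> 0); may be a vector.
#' @return Loss probability `lambda` in `[0, 1]`.
#' @examples
#' copy_number_to_loss_prob(1)    # 1: a single copy is lost every division
#' copy_number_to_loss_prob(4.8)  # a low-copy origin such as SC101
#' @export
copy_number_to_loss_prob <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n <= 0))
    stop("copy number 'n' must be > 0")
  pmin(1, 2^(1 - n))
}

#' Convert a loss probability back to an equivalent mean copy number
#'
#' Inverse of [copy_number_to_loss_prob()] on its unclipped branch.
#'
#' @param lambda_loss Loss probability in `(0, 1]`.
#' @return Mean copy number `n = 1 - log2(lambda)`.
#' @export
loss_prob_to_copy_number <- function(lambda_loss) {
  if (!is.numeric(lambda_loss) || any(is.na(lambda_loss)) ||
      any(lambda_loss <= 0) || any(lambda_loss > 1))
    stop("'lambda_loss' must lie in (0, 1]")
  1 - log2(lambda_loss)
}

#' Convert model time to plasmid-free generations (doublings)
#'
#' Model time `tau` is measured in plasmid-free e-folding units, so one
#' doubling corresponds to `ln 2` units. These helpers rescale for reporting.
#'
#' @param tau Model time in e-folding units.
#' @return Time in plasmid-free generations.
#' @export
tau_to_generations <- function(tau) tau / log(2)

#' @rdname tau_to_generations
#' @param generations Time in plasmid-free generations.
#' @export
generations_to_tau <- function(generations) generations * log(2)
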