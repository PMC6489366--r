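# Independent numerical oracle for the linear two-population model:
# fixed-step classical RK4 over psk_derivatives, vectorised across a batch
# of parameter draws (each column of `state` is one system). Step counts are
# chosen so the global error is far below the tolerances asserted against it.

rk4_integrate <- function(state0, params_list, tau, n_steps = 4000) {
  stopifnot(length(params_list) == ncol(state0), length(tau) == ncol(state0))
  a <- vapply(params_list, function(p) pskstab:::psk_rates(p)$a, numeric(1))
  b <- vapply(params_list, function(p) pskstab:::psk_rates(p)$b, numeric(1))
  cc <- vapply(params_list, function(p) pskstab:::psk_rates(p)$cc, numeric(1))
  h <- tau / n_steps
  x <- state0  # 2 x n matrix: rows X+, X-
  deriv <- function(x) rbind(a * x[1, ], b * x[2, ] + cc * x[1, ])
  for (i in seq_len(n_steps)) {
    k1 <- deriv(x)
    k2 <- deriv(x + sweep(k1, 2, h / 2, "*"))
    k3 <- deriv(x + sweep(k2, 2, h / 2, "*"))
    k4 <- deriv(x + sweep(k3, 2, h, "*"))
    x <- x + sweep(k1 + 2 * k2 + 2 * k3 + k4, 2, h / 6, "*")
  }
  x
}

# random valid parameter set for property tests
random_params <- function(mechanism = NULL) {
  if (is.null(mechanism)) mechanism <- sample(c("NONE", "TA", "BACTERIOCIN"), 1)
  psk_params(lambda_loss = runif(1, 0, 0.5),
             gamma = runif(1, 0.5, 1.5),
             omega = runif(1, 0, 1),
             mechanism = mechanism)
}
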