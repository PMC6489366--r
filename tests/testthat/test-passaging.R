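test_that("protocol constructor validates its fields", {
  expect_error(passaging_protocol(dilution_factor = 1), "> 1")
  expect_error(passaging_protocol(n_passages = 0), "positive integer")
  expect_error(passaging_protocol(initial_fraction = 1.5), "initial_fraction")
  p <- passaging_protocol(dilution_factor = 100)
  expect_equal(p$tau_per_passage, log(100))
})

test_that("simulated loss curves follow the closed-form per-passage decay", {
  prot <- passaging_protocol(dilution_factor = 1000, n_passages = 12)
  # lambda = 0 keeps a pure culture pure
  c0 <- simulate_loss_curve(psk_params(0, 0.8), prot)
  expect_equal(c0$fraction, rep(1, 13))
  # perfect TA killing also keeps it pure
  c1 <- simulate_loss_curve(psk_params(0.2, 0.9, omega = 1, mechanism = "TA"),
                            prot)
  expect_equal(c1$fraction, rep(1, 13))
  # gamma = 1, omega = 0: fraction(p) = exp(-lambda * p * ln D)
  c2 <- simulate_loss_curve(psk_params(0.1, 1, mechanism = "TA"), prot)
  expect_equal(c2$fraction, exp(-0.1 * (0:12) * log(1000)), tolerance = 1e-9)
  expect_equal(c2$passage, 0:12)
})

test_that("dilution preserves the fraction and the flow is a semigroup", {
  params <- psk_params(0.05, 0.85, omega = 0.6, mechanism = "BACTERIOCIN")
  base <- passaging_protocol(n_passages = 8, tau_per_passage = 4)
  double_tau <- passaging_protocol(n_passages = 4, tau_per_passage = 8)
  f1 <- simulate_loss_curve(params, base)$fraction[9]
  f2 <- simulate_loss_curve(params, double_tau)$fraction[5]
  expect_equal(f1, f2, tolerance = 1e-10)
  # direct closed-form evaluation agrees with the passage iteration
  expect_equal(
    simulate_loss_curve(params, base)$fraction,
    pskstab:::fraction_at_passages(params, base, 0:8),
    tolerance = 1e-10)
})

test_that("underflowing cultures raise an informative error", {
  prot <- passaging_protocol(dilution_factor = 1000, n_passages = 37,
                             initial_total = 1e-300)
  expect_error(
    simulate_loss_curve(psk_params(0.01, 0.1, mechanism = "NONE"), prot),
    "initial_total")
})

test_that("bacteriocin passaging converges to the asymptotic fraction", {
  params <- psk_params(0.1, 1, omega = 0.5, mechanism = "BACTERIOCIN")
  prot <- passaging_protocol(n_passages = 200, initial_fraction = 0.5)
  curve <- simulate_loss_curve(params, prot)
  expect_equal(curve$fraction[201], as.numeric(asymptotic_fraction(params)),
               tolerance = 1e-6)
})

test_that("competition predictions reproduce the restoration contrast", {
  f0 <- seq(0.1, 0.9, by = 0.1)
  # bacteriocin policing pushes every dilution back toward all-bearing
  bcn <- predict_competition(
    psk_params(1e-4, 0.9, omega = 0.9, mechanism = "BACTERIOCIN"), f0)
  expect_true(all(bcn > 0.99))
  # TA offers no rescue: the faster plasmid-free growth dilutes further
  ta <- predict_competition(
    psk_params(1e-4, 0.9, omega = 0.99, mechanism = "TA"), f0)
  expect_true(all(ta < f0))
  # half-and-half mix under burden alone drops below half
  expect_lt(predict_competition(psk_params(1e-4, 0.8, mechanism = "TA"), 0.5),
            0.5)
  # no loss, no burden: nothing changes
  expect_equal(predict_competition(psk_params(0, 1), c(0, 0.3, 1)),
               c(0, 0.3, 1), tolerance = 1e-12)
  expect_error(predict_competition(psk_params(0, 1), c(-0.1)), "\\[0, 1\\]")
})

test_that("parameter sweeps order curves per the model monotonicities", {
  prot <- passaging_protocol(n_passages = 10)
  base <- psk_params(0.01, 0.95, omega = 0.5, mechanism = "TA")
  sw_o <- parameter_sweep(base, prot, "omega", c(0, 0.5, 1))
  finals_o <- vapply(split(sw_o, sw_o$value), function(d)
    d$fraction[d$passage == 10], numeric(1))
  expect_true(all(diff(finals_o) > 0))
  sw_l <- parameter_sweep(base, prot, "lambda_loss", c(0.001, 0.01, 0.1))
  finals_l <- vapply(split(sw_l, sw_l$value), function(d)
    d$fraction[d$passage == 10], numeric(1))
  expect_true(all(diff(finals_l) < 0))
  sw_g <- parameter_sweep(psk_params(0.01, 1, mechanism = "NONE"), prot,
                          "gamma", c(0.8, 0.9, 1))
  finals_g <- vapply(split(sw_g, sw_g$value), function(d)
    d$fraction[d$passage == 10], numeric(1))
  expect_true(all(diff(finals_g) > 0))
  expect_error(parameter_sweep(base, prot, "nope", 1), "unknown parameter")
})
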