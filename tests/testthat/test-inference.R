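# Small fixtures keep the sampler runs in these tests at tens of seconds;
# the full-scale experiment designs are exercised in test-acceptance.R.

make_fixture <- function(n_replicates = 5, n_passages = 15, seed = 2,
                         noise_seed = 3, ...) {
  truth <- hierarchical_truth(n_replicates = n_replicates, seed = seed, ...)
  prot <- passaging_protocol(n_passages = n_passages)
  synth <- generate_loss_curves(truth, prot, noise = "beta", phi = 500,
                                seed = noise_seed)
  list(truth = truth, protocol = prot, synth = synth)
}

test_that("log-likelihood equals a termwise Beta-density oracle", {
  prot <- passaging_protocol(n_passages = 3)
  params <- psk_params(0.05, 0.9, 0.5, "TA")
  curve <- data.frame(replicate_id = "r1", passage = 0:3,
                      fraction = c(1, 0.95, 0.6, 0.21),
                      n_events = c(5000, 5000, NA, 5000))
  phi <- 350
  got <- psk_log_likelihood(curve, list(params), prot, phi)
  # independent oracle: closed-form state iteration and explicit dbeta terms
  oracle <- 0
  st <- population_state(1, 0)
  f_model <- 1
  for (p in 0:3) {
    if (p > 0) {
      st <- closed_form_solution(st, params, prot$tau_per_passage)
      f_model <- st$x_plus / (st$x_plus + st$x_minus)
    }
    eps <- if (is.na(curve$n_events[p + 1])) 1e-4 else 1 / (2 * curve$n_events[p + 1])
    f_o <- min(max(curve$fraction[p + 1], eps), 1 - eps)
    f_m <- min(max(f_model, eps), 1 - eps)
    oracle <- oracle + dbeta(f_o, f_m * phi, (1 - f_m) * phi, log = TRUE)
  }
  expect_lt(abs(got - oracle), 1e-10)
  # additivity over identical replicates
  two <- rbind(curve, transform(curve, replicate_id = "r2"))
  expect_equal(psk_log_likelihood(two, list(params, params), prot, phi),
               2 * got, tolerance = 1e-12)
  expect_error(psk_log_likelihood(two, list(params), prot, phi),
               "parameter sets")
})

fx <- make_fixture()
fit <- fit_hierarchical(fx$synth$curves, fx$protocol, n_steps = 1500,
                        seed = 11)

test_that("hierarchical recovery: gamma pinned, lambda bounded on its ridge", {
  s <- fit$summary
  gamma_row <- s[s$parameter == "gamma", ]
  expect_lt(gamma_row$lower, 0.9)
  expect_gt(gamma_row$upper, 0.9)
  # the data identify gamma(1 - lambda); the fitted combination must match
  comb <- median(fit$draws$gamma * (1 - fit$draws$lambda))
  expect_equal(comb, 0.9 * (1 - 0.01), tolerance = 0.03)
  # survival probability reported alongside omega
  expect_equal(fit$draws$survival, 1 - fit$draws$omega)
  # population-level lambda overlap must show the data constrained it
  expect_lt(s$overlap[s$parameter == "lambda"], 0.35)
})

test_that("posterior draws respect parameter bounds after back-transform", {
  expect_true(all(fit$draws$lambda >= 0 & fit$draws$lambda <= 1))
  expect_true(all(fit$draws$gamma > 0))
  expect_true(all(fit$draws$omega >= 0 & fit$draws$omega <= 1))
  expect_true(all(fit$draws$phi > 0))
  rd <- fit$replicate_draws
  expect_true(all(rd[, , "lambda"] >= 0 & rd[, , "lambda"] <= 1))
  expect_true(all(rd[, , "gamma"] > 0))
  # credible bounds ordered
  expect_true(all(fit$summary$lower <= fit$summary$median &
                    fit$summary$median <= fit$summary$upper))
})

test_that("posterior-predictive envelope behaves and covers held-out data", {
  env <- posterior_predictive(fit, fx$protocol, n_draws = 150, seed = 9,
                              force = TRUE)
  expect_equal(env$passage, 0:15)
  expect_true(all(env$lower <= env$upper))
  # envelope contains the posterior-mean curve pointwise
  expect_true(all(env$mean >= env$lower - 1e-12 & env$mean <= env$upper + 1e-12))
  # fresh noisy data from the same truth falls inside the 95% band
  held <- generate_loss_curves(fx$truth, fx$protocol, noise = "beta",
                               phi = 500, seed = 77)
  inside <- mapply(function(p, f) {
    f >= env$lower[env$passage == p] - 0.01 &
      f <= env$upper[env$passage == p] + 0.01
  }, held$curves$passage, held$curves$fraction)
  expect_gte(mean(inside), 0.9)
  expect_error(posterior_predictive(fit, fx$protocol, n_draws = 1e7,
                                    force = TRUE), "exceeds")
})

test_that("a single replicate degrades gracefully to prior-dominated scales", {
  one <- fx$synth$curves[fx$synth$curves$replicate_id == "r1", ]
  f1 <- fit_hierarchical(one, fx$protocol, n_steps = 800, seed = 3)
  expect_s3_class(f1, "psk_posterior")
  expect_equal(dim(f1$replicate_draws)[2], 1L)
  expect_true(all(is.finite(f1$summary$median)))
})

test_that("omega is inert when no killing shaped the data (NONE vs TA)", {
  truth0 <- hierarchical_truth(mechanism = "NONE", mean_lambda = 0.02,
                               mean_omega = 0, n_replicates = 4, seed = 6)
  prot <- passaging_protocol(n_passages = 12)
  synth0 <- generate_loss_curves(truth0, prot, noise = "beta", phi = 500,
                                 seed = 7)
  f_none <- fit_hierarchical(synth0$curves, prot, mechanism = "NONE",
                             n_steps = 1000, seed = 8)
  f_ta <- fit_hierarchical(synth0$curves, prot, mechanism = "TA",
                           n_steps = 1000, seed = 8)
  g_none <- f_none$summary[f_none$summary$parameter == "gamma", ]
  g_ta <- f_ta$summary[f_ta$summary$parameter == "gamma", ]
  # gamma estimates agree within the posterior uncertainty
  expect_lt(abs(g_none$median - g_ta$median),
            (g_none$upper - g_none$lower))
  expect_false("omega" %in% names(f_none$draws))
})

test_that("fit input contracts are enforced", {
  expect_error(fit_hierarchical(fx$synth$curves[1, ], fx$protocol),
               "at least 2")
  bad <- fx$synth$curves
  bad$fraction[3] <- 1.5
  expect_error(fit_hierarchical(bad, fx$protocol), "outside")
  ragged <- fx$synth$curves[-5, ]
  expect_error(fit_hierarchical(ragged, fx$protocol), "common passage grid")
})

test_that("competition fit recovers omega and flags boundary loss", {
  set.seed(8)
  p_true <- psk_params(1e-4, 0.9, 0.9, "BACTERIOCIN")
  f0 <- c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8)
  pred <- predict_competition(p_true, f0)
  obs <- data.frame(initial_fraction = f0,
                    final_fraction = rbeta(6, pred * 200, (1 - pred) * 200))
  cf <- fit_competition(obs, mechanism = "BACTERIOCIN", n_steps = 1500,
                        seed = 4)
  w <- cf$summary[cf$summary$parameter == "omega", ]
  expect_lt(w$lower, 0.9)
  expect_gt(w$upper, 0.9)
  expect_false(cf$flags$lambda_boundary)
  # identity outputs with no loss concentrate lambda at its boundary
  ident <- data.frame(initial_fraction = f0, final_fraction = f0)
  cf2 <- fit_competition(ident, mechanism = "NONE", n_steps = 1000, seed = 4)
  expect_true(cf2$flags$lambda_boundary)
  expect_lt(cf2$summary$median[cf2$summary$parameter == "lambda"], 1e-4)
  expect_error(fit_competition(obs[1:2, ]), "at least 3")
  expect_error(fit_competition(transform(obs, initial_fraction = initial_fraction + 1)),
               "outside")
})
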