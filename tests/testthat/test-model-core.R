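test_that("parameter and state constructors enforce their bounds", {
  expect_error(psk_params(-0.1, 1), "lambda_loss")
  expect_error(psk_params(0.1, 0), "gamma")
  expect_error(psk_params(0.1, 1, omega = 1.2), "omega")
  expect_error(population_state(-1, 0), "x_plus")
  # NONE forces omega to zero
  expect_equal(psk_params(0.1, 1, omega = 0.7, mechanism = "NONE")$omega, 0)
})

test_that("derivatives match the printed model term by term", {
  # TA with perfect killing: loss influx exactly cancels, X- stays empty
  d <- psk_derivatives(population_state(1, 0),
                       psk_params(0.3, 0.7, omega = 1, mechanism = "TA"))
  expect_equal(unname(d), c(0.7 * (1 - 0.3), 0))
  # no loss: independent exponential growth at rates gamma and 1
  d <- psk_derivatives(population_state(2, 3),
                       psk_params(0, 0.8, mechanism = "NONE"))
  expect_equal(unname(d), c(1.6, 3))
  # bacteriocin at omega = 0.5: policing removes X- at rate 1, leaving
  # exactly the loss influx
  d <- psk_derivatives(population_state(1, 5),
                       psk_params(0.1, 1, omega = 0.5,
                                  mechanism = "BACTERIOCIN"))
  expect_equal(unname(d), c(0.9, 0.1), tolerance = 1e-12)
  expect_error(
    psk_derivatives(structure(list(x_plus = -1, x_minus = 0, tau = 0),
                              class = "psk_state"),
                    psk_params(0.1, 1)),
    "negative")
})

test_that("closed form matches the RK4 integration oracle across random draws", {
  set.seed(42)
  n <- 500
  params_list <- replicate(n, random_params(), simplify = FALSE)
  tau <- runif(n, 0.01, 5)
  x0 <- rbind(runif(n, 0.1, 10), runif(n, 0, 10))
  oracle <- rk4_integrate(x0, params_list, tau)
  for (i in seq_len(n)) {
    s <- closed_form_solution(population_state(x0[1, i], x0[2, i]),
                              params_list[[i]], tau[i])
    expect_lt(abs(s$x_plus - oracle[1, i]) / max(abs(oracle[1, i]), 1e-12),
              1e-8)
    expect_lt(abs(s$x_minus - oracle[2, i]) / max(abs(oracle[2, i]), 1e-12),
              1e-8)
    expect_gte(s$x_plus, 0)
    expect_gte(s$x_minus, 0)
  }
})

test_that("closed form reproduces hand-derived trajectories", {
  # TA, gamma = 1: fraction decays as exp(-lambda * tau)
  tau <- log(1000)
  s <- closed_form_solution(population_state(1, 0),
                            psk_params(0.1, 1, mechanism = "TA"), tau)
  expect_equal(psk_fraction(s), exp(-0.1 * tau), tolerance = 1e-10)
  # bacteriocin: X-(tau) = (lambda/0.9) * (exp(0.9 tau) - 1) when b = 0
  sb <- closed_form_solution(population_state(1, 0),
                             psk_params(0.1, 1, omega = 0.5,
                                        mechanism = "BACTERIOCIN"), tau)
  expect_equal(sb$x_minus, (0.1 / 0.9) * (exp(0.9 * tau) - 1),
               tolerance = 1e-10)
  expect_equal(psk_fraction(sb), 0.9002, tolerance = 1e-3)
  # identity at zero elapsed time
  s0 <- closed_form_solution(population_state(2, 3),
                             psk_params(0.2, 0.9, 0.5, "TA"), 0)
  expect_equal(c(s0$x_plus, s0$x_minus), c(2, 3))
})

test_that("resonant equal-exponent case is exact, not perturbed", {
  # gamma = 1, lambda = 0 makes both exponents 1: X- picks up tau*exp(tau)
  p <- psk_params(0, 1, mechanism = "TA")
  s <- closed_form_solution(population_state(1, 1), p, 2)
  expect_equal(s$x_plus, exp(2), tolerance = 1e-12)
  expect_equal(s$x_minus, exp(2), tolerance = 1e-12)
  # engineered tie with influx: a = b = 1 via gamma = 1/(1-lambda)
  lam <- 0.2
  p2 <- psk_params(lam, 1 / (1 - lam), mechanism = "TA")
  s2 <- closed_form_solution(population_state(1, 0), p2, 3)
  cc <- lam * (1 / (1 - lam))
  expect_equal(s2$x_minus, cc * 3 * exp(3), tolerance = 1e-9)
})

test_that("perfect TA killing keeps an initially pure culture pure", {
  p <- psk_params(0.3, 0.8, omega = 1, mechanism = "TA")
  for (tau in c(0.5, 2, 10, 40)) {
    s <- closed_form_solution(population_state(1, 0), p, tau)
    expect_equal(s$x_minus, 0)
    expect_equal(psk_fraction(s), 1)
  }
})

test_that("copy-number relation lambda = 2^(1-n) behaves and inverts", {
  expect_identical(copy_number_to_loss_prob(1), 1)
  expect_equal(copy_number_to_loss_prob(4.8), 2^(-3.8), tolerance = 1e-12)
  expect_equal(copy_number_to_loss_prob(21), 2^(-20), tolerance = 1e-12)
  # clipped to 1 below one copy
  expect_identical(copy_number_to_loss_prob(0.5), 1)
  expect_error(copy_number_to_loss_prob(0), "> 0")
  # strictly decreasing in n
  n_grid <- seq(1, 25, length.out = 50)
  expect_true(all(diff(copy_number_to_loss_prob(n_grid)) < 0))
  # round trip on the unclipped branch
  expect_equal(loss_prob_to_copy_number(copy_number_to_loss_prob(7)), 7)
})

test_that("asymptotic fraction covers loss, coexistence and degenerate cases", {
  # plasmid-free outgrows: burden too high for TA to rescue
  expect_equal(as.numeric(asymptotic_fraction(
    psk_params(0.1, 0.9, omega = 0.99, mechanism = "TA"))), 0)
  # no loss, no initial plasmid-free cells
  expect_equal(as.numeric(asymptotic_fraction(psk_params(0, 0.8))), 1)
  # bacteriocin coexistence value
  f <- asymptotic_fraction(psk_params(0.1, 1, omega = 0.5,
                                      mechanism = "BACTERIOCIN"))
  expect_equal(as.numeric(f), 0.9)
  expect_false(attr(f, "degenerate"))
  # matches the long-time limit of the closed form
  s <- closed_form_solution(population_state(1, 0),
                            psk_params(0.1, 1, omega = 0.5,
                                       mechanism = "BACTERIOCIN"), 60)
  expect_equal(psk_fraction(s), 0.9, tolerance = 1e-6)
  # exact exponent tie with influx decays resonantly and is flagged
  lam <- 0.2
  tie <- asymptotic_fraction(psk_params(lam, 1 / (1 - lam), mechanism = "TA"))
  expect_equal(as.numeric(tie), 0)
  expect_true(attr(tie, "degenerate"))
})

test_that("final fraction is monotone in lambda and omega", {
  tau <- 3 * log(1000)
  for (mech in c("TA", "BACTERIOCIN")) {
    for (gamma in c(0.8, 1, 1.2)) {
      for (omega in c(0.2, 0.8)) {
        fr <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5), function(l) {
          psk_fraction(closed_form_solution(
            population_state(0.9, 0.1), psk_params(l, gamma, omega, mech), tau))
        }, numeric(1))
        expect_true(all(diff(fr) <= 1e-12),
                    label = paste("lambda monotone", mech, gamma, omega))
      }
      for (lambda in c(0.01, 0.1)) {
        fr <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
          psk_fraction(closed_form_solution(
            population_state(0.9, 0.1), psk_params(lambda, gamma, w, mech), tau))
        }, numeric(1))
        expect_true(all(diff(fr) >= -1e-12),
                    label = paste("omega monotone", mech, gamma, lambda))
      }
    }
  }
})
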