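test_that("generators are bit-reproducible under a fixed seed", {
  tr1 <- hierarchical_truth(seed = 5)
  tr2 <- hierarchical_truth(seed = 5)
  expect_identical(tr1$replicates, tr2$replicates)
  prot <- passaging_protocol(n_passages = 6)
  s1 <- generate_loss_curves(tr1, prot, seed = 9)
  s2 <- generate_loss_curves(tr2, prot, seed = 9)
  expect_identical(s1$curves, s2$curves)
  e1 <- generate_events(0.4, 500, seed = 3)
  e2 <- generate_events(0.4, 500, seed = 3)
  expect_identical(e1, e2)
  g1 <- generate_growth_curve(0.01, seed = 4)
  g2 <- generate_growth_curve(0.01, seed = 4)
  expect_identical(g1, g2)
})

test_that("loss-curve generator returns truth alongside curves", {
  truth <- hierarchical_truth(n_replicates = 4, seed = 1)
  prot <- passaging_protocol(n_passages = 10)
  synth <- generate_loss_curves(truth, prot, seed = 2)
  expect_s3_class(synth, "psk_synth_loss")
  expect_equal(nrow(synth$truth), 4)
  expect_equal(sort(unique(synth$curves$replicate_id)),
               sort(synth$truth$replicate_id))
  expect_true(all(synth$curves$fraction >= 0 & synth$curves$fraction <= 1))
  # per-replicate draws respect parameter bounds
  expect_true(all(synth$truth$lambda_loss >= 0 & synth$truth$lambda_loss <= 1))
  expect_true(all(synth$truth$gamma > 0))
  expect_true(all(synth$truth$omega >= 0 & synth$truth$omega <= 1))
})

test_that("zero loss probability yields all-ones curves under binomial noise", {
  truth <- hierarchical_truth(mean_lambda = 0, n_replicates = 3, seed = 1)
  prot <- passaging_protocol(n_passages = 8)
  synth <- generate_loss_curves(truth, prot, noise = "binomial", seed = 2)
  expect_true(all(synth$curves$fraction == 1))
})

test_that("vanishing noise recovers the deterministic curves", {
  truth <- hierarchical_truth(n_replicates = 3, seed = 6)
  prot <- passaging_protocol(n_passages = 12)
  synth_b <- generate_loss_curves(truth, prot, n_events = 1e8,
                                  noise = "binomial", seed = 3)
  synth_bb <- generate_loss_curves(truth, prot, noise = "beta", phi = 1e8,
                                   seed = 3)
  for (i in 1:3) {
    row <- truth$replicates[i, ]
    det <- pskstab:::fraction_at_passages(
      psk_params(row$lambda_loss, row$gamma, row$omega, truth$mechanism),
      prot, 0:12)
    ob <- synth_b$curves$fraction[synth_b$curves$replicate_id == row$replicate_id]
    obb <- synth_bb$curves$fraction[synth_bb$curves$replicate_id == row$replicate_id]
    expect_lt(max(abs(ob - det)), 1e-3)
    expect_lt(max(abs(obb - det)), 1e-3)
  }
})

test_that("event generator composition matches its label bookkeeping", {
  ev <- generate_events(0.7, n_events = 10000, separation_decades = 2,
                        debris_fraction = 0, seed = 8)
  expect_true(all(ev$fsc > 0 & ev$ssc > 0 & ev$fl1 > 0))
  n_bearing <- sum(ev$label == "bearing")
  # within 3 sigma of Binomial(1e4, 0.7)
  expect_lt(abs(n_bearing - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
  # pure sample is unimodal in labels
  pure <- generate_events(1, 2000, debris_fraction = 0, seed = 2)
  expect_true(all(pure$label == "bearing"))
})

test_that("growth-curve generator hits its stated exponential-phase slope", {
  # noiseless: exact logistic-with-smoothed-lag values, positive and sorted
  g0 <- generate_growth_curve(0.012, noise_sd = 0, seed = 1)
  expect_true(all(diff(g0$time_min) > 0))
  expect_true(all(g0$od > 0))
  # near-unbounded capacity: log-od slope in the exponential window ~ mu_max
  g <- generate_growth_curve(0.01, lag = 60, capacity = 1e6, noise_sd = 0,
                             duration = 600, seed = 1)
  win <- g$time_min >= 300 & g$time_min <= 500
  slope <- diff(range(log(g$od[win]))) / diff(range(g$time_min[win]))
  expect_equal(slope, 0.01, tolerance = 0.01)
  expect_equal(attr(g, "mu_max"), 0.01)
})
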