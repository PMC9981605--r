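test_that("an unadapted bank decodes presented orientations by vector average", {
  bank <- channel_bank()
  # exact on the 30-degree stimulus grid
  for (th in seq(0, 150, 30)) {
    r <- predgain:::channel_response(bank, th)
    d <- vector_average_orientation(r, bank$preferred)$orientation
    expect_equal(ori_dist(d, th), 0, tolerance = 1e-9)
  }
  # small harmonic ripple off the grid
  d37 <- vector_average_orientation(predgain:::channel_response(bank, 37),
                                    bank$preferred)$orientation
  expect_lt(ori_dist(d37, 37), 0.05)
})

test_that("very wide channels respond almost identically to everything", {
  bank <- channel_bank(width = 4000)
  r <- predgain:::channel_response(bank, 73)
  expect_lt(diff(range(r)) / mean(r), 1e-3)
  expect_error(channel_bank(width = 0), "positive")
})

test_that("the response profile to 0 degrees is mirror-symmetric", {
  r <- predgain:::channel_response(channel_bank(), 0)
  expect_equal(r[2], r[6], tolerance = 1e-12)   # 30 vs 150
  expect_equal(r[3], r[5], tolerance = 1e-12)   # 60 vs 120
})

test_that("adaptation maximally reduces the adapted channel, sparing orthogonal ones", {
  bank <- channel_bank()
  g <- compute_gains(bank, prev_orientation = 90, setting = gain_setting(0.5, 0))
  expect_equal(g$adaptation[4], 0.5, tolerance = 1e-12)   # channel at 90
  expect_gt(g$adaptation[1], 0.95)                        # channel at 0
  expect_true(all(g$expectation == 1))

  g0 <- compute_gains(bank, 90, 30, gain_setting(0, 0))
  expect_true(all(g0$adaptation == 1) && all(g0$expectation == 1))
  expect_error(compute_gains(bank, 90, 30, gain_setting(1.2, 0)), "0, 1")
})

test_that("the expectation profile dips exactly at the expected orientation", {
  bank <- channel_bank()
  for (ex in c(0, 47, 120)) {
    prof <- expectation_profile(bank, ex, 0.25)
    expect_equal(prof$orientation[which.min(prof$sensitivity)], ex)
    expect_equal(min(prof$sensitivity), 0.75, tolerance = 1e-12)
  }
})

test_that("with zero gains every trial reproduces the unadapted profile", {
  bank <- channel_bank()
  sq <- generate_sequence("rotating", 200, seed = 2)
  tr <- run_model(bank, sq, gain_setting(0, 0))
  for (t in c(1, 50, 200)) {
    expect_equal(tr$responses[t, ],
                 predgain:::channel_response(bank, sq$orientation[t]),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity state stays in (0, 1] for in-range settings", {
  bank <- channel_bank()
  sq <- generate_sequence("rotating", 500, seed = 3)
  for (s in list(gain_setting(1, 0), gain_setting(0.5, 0.5), gain_setting(0, 1))) {
    tr <- run_model(bank, sq, s)
    expect_true(all(tr$state > 0 & tr$state <= 1))
    expect_true(all(is.finite(tr$responses)))
  }
})

test_that("adaptation repels decoded orientations away from the previous stimulus", {
  bank <- channel_bank()
  sq <- generate_sequence("random", 6000, seed = 4)
  dt <- decode_trace(run_model(bank, sq, gain_setting(0.5, 0)))
  prev_rel <- ori_diff_signed(sq$orientation[-nrow(sq)],
                              sq$orientation[-1])      # prev relative to current
  e <- dt$error[-1]
  expect_lt(mean(e[prev_rel == 30]), -0.2)   # prev above -> pushed below
  expect_gt(mean(e[prev_rel == -30]), 0.2)
})

test_that("gain modulation persists over at least four trials at m = 3", {
  suppress_after <- function(m) {
    bank <- channel_bank(modulation_factor = m)
    ex <- m / (m + 1)
    S <- (1 - 0.5 * predgain:::channel_sensitivity(bank, 90))
    S <- S / max(S)
    for (k in 1:4) { S <- S^ex; S <- S / max(S) }
    1 - S[4]    # residual suppression of the 90-degree channel
  }
  expect_gt(suppress_after(3), 0.05)
  expect_lt(suppress_after(1), 0.05)
  expect_lt(suppress_after(1), suppress_after(3))
})

test_that("with no expectation the model is causal", {
  bank <- channel_bank()
  sq <- generate_sequence("random", 300, seed = 5)
  tr1 <- run_model(bank, sq, gain_setting(0.5, 0))
  sq2 <- sq
  sq2$orientation[201:300] <- rev(sq2$orientation[201:300])
  tr2 <- run_model(bank, label_transitions(sq2), gain_setting(0.5, 0))
  expect_equal(tr1$responses[1:200, ], tr2$responses[1:200, ],
               tolerance = 1e-12)
})

test_that("condition statistics show the expectation-gain ordering", {
  res <- simulate_condition_statistics(n_sessions = 6, trials_per_run = 1200,
                                       n_runs = 1, seed = 9)
  s <- res$summary
  g <- setNames(s$gain_mean, s$condition)
  w <- setNames(s$width_mean, s$condition)
  expect_gt(g["unexpected"], g["expected"])
  expect_gt(g["expected"], g["random"])
  expect_gt(w["expected"], w["random"])
  expect_lt(abs(w["unexpected"] - w["random"]), 1.5)
  expect_equal(nrow(res$per_session), 6 * 3)
})

test_that("zero-gain settings give identical fits in all conditions", {
  res <- simulate_condition_statistics(n_sessions = 2, trials_per_run = 600,
                                       n_runs = 1, seed = 10,
                                       random_setting = gain_setting(0, 0),
                                       rotating_setting = gain_setting(0, 0))
  s <- res$summary
  expect_lt(diff(range(s$gain_mean)), 1e-6)
  expect_lt(diff(range(s$width_mean)), 1e-4)
})

test_that("missing conditions are reported by fit_model_conditions", {
  bank <- channel_bank()
  sq <- generate_sequence("random", 300, seed = 11)
  tr <- run_model(bank, sq, gain_setting(0.5, 0))
  expect_error(fit_model_conditions(list(rotating = tr)), "missing condition")
})

test_that("ridge regression explains a noiseless linear readout perfectly", {
  bank <- channel_bank()
  sq <- generate_sequence("rotating", 600, seed = 6)
  tr <- run_model(bank, sq, gain_setting(0.25, 0.25))
  beta0 <- c(2, 0.5, -1, 0, 1.5, 0.2)
  Y <- tr$responses %*% beta0 + 3
  rg <- regress_to_neurons(tr$responses, cbind(Y), seed = 7)
  expect_gt(rg$r2_cv[1], 0.999)
  expect_equal(rg$best_regressor[1], 1L)
})

test_that("a pure-noise neuron has near-zero cross-validated variance explained", {
  bank <- channel_bank()
  sq <- generate_sequence("rotating", 600, seed = 8)
  tr <- run_model(bank, sq, gain_setting(0.25, 0.25))
  set.seed(12)
  Y <- cbind(rnorm(600))
  rg <- regress_to_neurons(tr$responses, Y, seed = 13)
  expect_lt(abs(rg$r2_cv[1]), 0.03)
  expect_error(regress_to_neurons(matrix(1, 600, 6), Y), "degenerate")
})

test_that("the expectation-gain grid recovers the generative gain level", {
  bank <- channel_bank()
  sq <- generate_sequence("rotating", 900, seed = 14)
  gen <- run_model(bank, sq, gain_setting(0, 0.75))
  set.seed(15)
  Y <- gen$responses %*% matrix(rnorm(6 * 8), 6, 8) + rnorm(900 * 8, 0, 0.1)
  grid <- model_comparison_grid(bank, sq, Y, levels = c(0, 0.25, 0.5, 0.75, 1),
                                types = "expectation", seed = 16)
  m <- tapply(grid$r2_cv, grid$level, mean)
  expect_equal(as.numeric(names(which.max(m))), 0.75)
  expect_gt(m["0.75"], m["0"])
})
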