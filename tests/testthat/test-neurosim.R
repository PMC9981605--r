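test_that("selective-neuron counts and degenerate fractions are exact", {
  specs <- simulate_population(1693, 0.273, seed = 1)
  expect_equal(sum(specs$is_selective), 462L)
  expect_true(all(specs$tuning_gain[!specs$is_selective] == 0))

  flat <- simulate_population(50, 0, seed = 2)
  expect_true(all(flat$tuning_gain == 0))
  expect_error(simulate_population(10, 1.2), "frac_selective")
})

test_that("preferred orientations are uniform over [0, 180)", {
  specs <- simulate_population(1e5, 0.5, seed = 3)
  h <- table(cut(specs$preferred_orientation, seq(0, 180, by = 10)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("responses are deterministic given the seed", {
  session <- make_session(60, 60, seed = 5)
  specs <- simulate_population(8, 0.5, seed = 6)
  r1 <- simulate_responses(specs, session, seed = 7)
  r2 <- simulate_responses(specs, session, seed = 7)
  expect_identical(r1$traces, r2$traces)
})

test_that("without an injected effect, unexpected and random responses match", {
  # isolated readout (near-instant kernel, in-slot window): per-event drives
  # are identical across conditions when the gain factor is 1
  session <- make_session(300, 300, seed = 21)
  specs <- make_specs(preferred = c(0, 30, 60, 90, 120, 150), gain = 50,
                      baseline = 5, factor = 1)
  rec <- simulate_responses(specs, session, kernel_tau_ms = 1, seed = 1,
                            noise = FALSE)
  ep <- isolated_epochs(rec)
  tr <- ep$trials
  for (n in 1:6) {
    pref <- specs$preferred_orientation[n]
    iu <- tr$transition == "unexpected" & tr$orientation == pref
    ir <- tr$transition == "random" & tr$orientation == pref
    expect_equal(mean(ep$scalar[n, iu]), mean(ep$scalar[n, ir]),
                 tolerance = 1e-12)
  }
})

test_that("a 1.3 gain factor appears as exactly 1.3 in isolated tuned responses", {
  session <- make_session(300, 300, seed = 22)
  specs <- make_specs(preferred = c(0, 60, 120), gain = 40, baseline = 0,
                      factor = 1.3)
  rec <- simulate_responses(specs, session, kernel_tau_ms = 1, seed = 1,
                            noise = FALSE)
  ep <- isolated_epochs(rec)
  tr <- ep$trials
  for (n in 1:3) {
    pref <- specs$preferred_orientation[n]
    iu <- tr$transition == "unexpected" & tr$orientation == pref
    ir <- tr$transition == "random" & tr$orientation == pref
    expect_equal(mean(ep$scalar[n, iu]) / mean(ep$scalar[n, ir]), 1.3,
                 tolerance = 1e-12)
  }
})

test_that("a near-zero kernel reproduces per-slot boxcar drives", {
  session <- make_session(30, 0, seed = 23)
  specs <- make_specs(preferred = 45, gain = 30, baseline = 2)
  rec <- simulate_responses(specs, session, kernel_tau_ms = 1e-6, seed = 1,
                            noise = FALSE)
  # during each event's slot the trace equals the event drive exactly
  for (e in c(1, 10, 25)) {
    f0 <- rec$events$frame_index[e] + 1
    d <- 2 + 30 * exp(-ori_dist(45, rec$events$orientation[e])^2 / (2 * 40^2))
    expect_equal(unname(rec$traces[1, f0 + 3]), d, tolerance = 1e-9)
  }
})

test_that("epoching preserves constants and logs the scalar frame count", {
  session <- make_session(60, 0, seed = 24)
  specs <- make_specs(preferred = 10, gain = 0, baseline = 7)
  rec <- simulate_responses(specs, session, seed = 1, noise = FALSE)
  rec$traces[] <- 7   # constant trace
  ep <- quiet_epochs(rec)
  expect_true(all(abs(ep$data - 7) < 1e-12))
  expect_true(all(abs(ep$scalar - 7) < 1e-12))
  # frame-arithmetic oracle for the 250-1000 ms window at 30 Hz
  dt <- 1000 / 30
  ft <- (seq_len(ncol(rec$traces)) - 1) * dt
  oracle <- vapply(rec$events$frame_index, function(f0)
    sum(ft >= f0 * dt + 250 & ft <= f0 * dt + 1000), integer(1))
  expect_identical(ep$scalar_frames, oracle[seq_len(nrow(ep$trials))])
  expect_true(all(ep$scalar_frames %in% c(22L, 23L)))
  expect_setequal(unique(ep$scalar_frames), c(22L, 23L))
})

test_that("trials at the recording edge are dropped, others unaffected", {
  session <- make_session(60, 0, seed = 25)
  specs <- make_specs(preferred = 10, gain = 20)
  rec <- simulate_responses(specs, session, seed = 1, noise = FALSE)
  expect_message(wide <- extract_epochs(rec, window_ms = c(-2000, 2000)),
                 "dropped")
  expect_gt(wide$n_dropped, 0)
  base <- quiet_epochs(rec)
  keep <- match(wide$trials$index, base$trials$index)
  expect_equal(wide$scalar, base$scalar[, keep, drop = FALSE])
  expect_error(extract_epochs(rec, window_ms = c(500, -500)), "reversed")
})

test_that("tuning parameters are recovered from noiseless isolated recordings", {
  session <- make_session(600, 0, seed = 26)
  specs <- make_specs(preferred = c(0, 30, 60, 90, 120, 150), gain = 35,
                      width = 40, baseline = 4)
  rec <- simulate_responses(specs, session, kernel_tau_ms = 1, seed = 1,
                            noise = FALSE)
  ep <- isolated_epochs(rec)
  for (n in 1:6) {
    curve <- vapply(seq(0, 150, 30), function(o)
      mean(ep$scalar[n, ep$trials$orientation == o]), numeric(1))
    f <- fit_circular_gaussian(seq(0, 150, 30), curve)
    expect_equal(f$gain, 35, tolerance = 1e-6)
    expect_equal(f$width, 40, tolerance = 1e-6)
    expect_equal(f$offset, 4, tolerance = 1e-6)
    expect_equal(ori_dist(f$preferred, specs$preferred_orientation[n]), 0,
                 tolerance = 1e-6)
  }
})

test_that("uncorrelated noise gives near-diagonal covariance; shared factors do not", {
  session <- make_session(120, 0, seed = 27)
  sp0 <- simulate_population(12, 0, seed = 9, noise_corr = 0)
  sp1 <- simulate_population(12, 0, seed = 9, noise_corr = 0.5)
  r0 <- simulate_responses(sp0, session, seed = 10)
  r1 <- simulate_responses(sp1, session, seed = 10)
  off <- function(rec) {
    cc <- stats::cor(t(rec$traces))
    mean(abs(cc[upper.tri(cc)]))
  }
  expect_lt(off(r0), 0.05)
  expect_gt(off(r1), 5 * off(r0))
})

test_that("the injected surprise effect is recovered for nearly all selective neurons", {
  session <- make_session(2400, 7200, seed = 46)
  specs <- simulate_population(150, 0.3, effect = 1.3, seed = 23)
  rec <- simulate_responses(specs, session, seed = 24)
  ep <- quiet_epochs(rec)
  true_sel <- which(specs$is_selective)
  summ <- summarize_conditions(ep, neurons = true_sel)
  su <- unique(summ$table[, c("neuron", "surprise_effect")])
  su <- su$surprise_effect[is.finite(su$surprise_effect)]
  # surprise = gain(random) - gain(unexpected); the injected enhancement
  # makes it negative
  expect_gt(mean(su < 0), 0.95)
})
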