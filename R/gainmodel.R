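#' Construct the orientation channel bank
#'
#' A bank of six orientation-selective information channels with preferred
#' orientations 0-150 degrees in 30-degree steps. Each channel's sensitivity
#' profile is a circular Gaussian (period 180) with unit gain and width
#' `width` (40 degrees by default); the bank then responds to a grating
#' through an expansive squaring output nonlinearity, so the measured
#' response of channel k to orientation x is
#' `S_k * exp(-d(x, phi_k)^2 / (2 width^2))^2`, with `S_k` the channel's
#' current multiplicative sensitivity state. With all `S_k = 1` the bank is
#' (to within a small harmonic ripple) equally sensitive to all
#' orientations and the doubled-angle vector average of the population
#' response returns the presented orientation, exactly so on the 30-degree
#' stimulus grid.
#'
#' @param n_channels number of channels (default 6).
#' @param width Gaussian sensitivity width in degrees (> 0).
#' @param gain channel amplitude (arbitrary units).
#' @param modulation_factor persistence factor m: the sensitivity state
#'   carries over between trials with exponent `m / (m + 1)`, so gain
#'   modulation decays over several subsequent trials (about four or more
#'   at the default m = 3) rather than resetting.
#' @param response_exponent exponent of the output nonlinearity (default 2).
#' @return a `channel_bank`.
#' @export
channel_bank <- function(n_channels = 6, width = 40, gain = 1,
                         modulation_factor = 3, response_exponent = 2) {
  if (width <= 0) stop("width must be positive")
  structure(list(preferred = seq(0, 180 - 180 / n_channels,
                                 by = 180 / n_channels),
                 width = width, gain = gain,
                 modulation_factor = modulation_factor,
                 response_exponent = response_exponent),
            class = "channel_bank")
}

# Gaussian sensitivity of every channel to orientation x (linear stage)
channel_sensitivity <- function(bank, x) {
  bank$gain * exp(-ori_dist(bank$preferred, x)^2 / (2 * bank$width^2))
}

# measured channel responses for sensitivity state S
channel_response <- function(bank, x, state = rep(1, length(bank$preferred))) {
  state * channel_sensitivity(bank, x)^bank$response_exponent
}

#' Adaptation and expectation gain profiles
#'
#' Adaptation reduces each channel's gain in proportion to its sensitivity
#' to the previous stimulus: channels near the adapter are maximally
#' reduced, orthogonal channels essentially unaffected. Expectation applies
#' an "inverse copy" of the response tuning centred on the expected
#' orientation: stimulus-space sensitivity around the prediction is reduced
#' before the stimulus appears, using the response-shaped profile (the
#' sensitivity Gaussian raised to the output exponent, which is what an
#' Eq.-1 style fit of the bank's response profile returns). Absent inputs
#' yield all-ones profiles.
#'
#' @param bank a `channel_bank`.
#' @param prev_orientation previous stimulus orientation or `NULL`/`NA`.
#' @param expected_orientation predicted orientation or `NULL`/`NA`.
#' @param setting list or vector with `adaptation_gain` and
#'   `expectation_gain`, both in [0, 1].
#' @return list with `adaptation` and `expectation` per-channel profiles.
#' @export
compute_gains <- function(bank, prev_orientation = NULL,
                          expected_orientation = NULL, setting) {
  ga <- setting[["adaptation_gain"]]
  ge <- setting[["expectation_gain"]]
  if (ga < 0 || ga > 1 || ge < 0 || ge > 1)
    stop("gains must lie in [0, 1]")
  ones <- rep(1, length(bank$preferred))
  adaptation <- ones
  if (!is.null(prev_orientation) && length(prev_orientation) &&
      is.finite(prev_orientation) && ga > 0) {
    s <- channel_sensitivity(bank, prev_orientation)
    adaptation <- 1 - ga * s / max(s)
  }
  expectation <- ones
  if (!is.null(expected_orientation) && length(expected_orientation) &&
      is.finite(expected_orientation) && ge > 0) {
    s <- channel_sensitivity(bank, expected_orientation)^bank$response_exponent
    expectation <- 1 - ge * s / max(s)
  }
  list(adaptation = adaptation, expectation = expectation)
}

#' Expectation sensitivity profile over stimulus orientation space
#'
#' The continuous inverse-copy profile applied around an expected
#' orientation, evaluated on a fine orientation grid (useful for
#' inspecting where suppression is maximal).
#'
#' @param bank a `channel_bank`.
#' @param expected_orientation predicted orientation (degrees).
#' @param expectation_gain gain in [0, 1].
#' @param grid orientations at which to evaluate.
#' @return data.frame with `orientation` and `sensitivity`.
#' @export
expectation_profile <- function(bank, expected_orientation, expectation_gain,
                                grid = seq(0, 179, by = 1)) {
  g <- exp(-ori_dist(grid, expected_orientation)^2 /
           (2 * bank$width^2))^bank$response_exponent
  data.frame(orientation = grid,
             sensitivity = 1 - expectation_gain * g / max(g))
}

#' Run the channel model over a stimulus sequence
#'
#' Per trial: the adaptation profile (from the previous orientation) and the
#' expectation profile (from the expected orientation, when the sequence
#' defines one) are applied to the persistent sensitivity state, the channel
#' responses to the presented orientation are emitted, and the state is
#' renormalised by its maximum so that modulation decays over subsequent
#' trials at a rate set by the modulation factor:
#' `S_t = normmax(S_{t-1}^(m/(m+1)) * g_adapt * g_expect)`.
#'
#' @param bank a `channel_bank`.
#' @param seq a labelled `orientation_sequence`.
#' @param setting gain setting, e.g. `gain_setting(0.25, 0.25)`.
#' @param modulation_factor optional override of the bank's m.
#' @return a `model_trace`: list with `responses` (trials x channels),
#'   `state` (trials x channels, post-normalisation), `adaptation`,
#'   `expectation` (the applied profiles), and the per-trial `orientation`,
#'   `expected`, `transition`.
#' @export
run_model <- function(bank, seq, setting,
                      modulation_factor = bank$modulation_factor) {
  if (!nrow(seq)) stop("empty sequence")
  m <- modulation_factor
  ex <- m / (m + 1)
  nc <- length(bank$preferred)
  nt <- nrow(seq)
  R <- SA <- GA <- GE <- matrix(NA_real_, nt, nc)
  S <- rep(1, nc)
  for (t in seq_len(nt)) {
    prev <- if (t > 1) seq$orientation[t - 1] else NULL
    expd <- seq$expected_orientation[t]
    g <- compute_gains(bank, prev, expd, setting)
    S_raw <- S^ex * g$adaptation * g$expectation
    R[t, ] <- S_raw * channel_sensitivity(bank, seq$orientation[t])^bank$response_exponent
    # renormalise by the maximum; a tiny floor keeps fully suppressed
    # channels (gain exactly 1) recoverable instead of absorbing at zero
    S <- pmax(S_raw / max(S_raw), 1e-12)
    GA[t, ] <- g$adaptation
    GE[t, ] <- g$expectation
    SA[t, ] <- S
  }
  structure(list(responses = R, state = SA, adaptation = GA, expectation = GE,
                 orientation = seq$orientation,
                 expected = seq$expected_orientation,
                 transition = seq$transition,
                 setting = setting, bank = bank),
            class = "model_trace")
}

#' Gain setting constructor
#'
#' @param adaptation_gain,expectation_gain gains in [0, 1]. The paper-style
#'   equilibrium settings are Random `gain_setting(0.5, 0)` and Rotating
#'   `gain_setting(0.25, 0.25)`.
#' @return named list.
#' @export
gain_setting <- function(adaptation_gain, expectation_gain) {
  list(adaptation_gain = adaptation_gain, expectation_gain = expectation_gain)
}

#' Decode each trial of a model trace by population vector average
#'
#' @param trace a `model_trace`.
#' @return data.frame: trial, decoded orientation, signed error, transition,
#'   signed violation (for unexpected trials).
#' @export
decode_trace <- function(trace) {
  nc <- ncol(trace$responses)
  pref <- trace$bank$preferred
  dec <- apply(trace$responses, 1, function(r)
    vector_average_orientation(r, pref)$orientation)
  err <- ori_diff_signed(dec, trace$orientation)
  viol <- ifelse(is.finite(trace$expected),
                 ori_diff_signed(trace$orientation, trace$expected), NA_real_)
  data.frame(trial = seq_along(dec), decoded = dec, error = err,
             transition = trace$transition, violation = viol)
}

# aligned 6-point condition tuning curve from a model trace:
# channel responses indexed by the channel's preferred orientation relative
# to the presented orientation, averaged over the trials of one condition
.aligned_model_curve <- function(trace, which_trials) {
  pref <- trace$bank$preferred
  deltas <- c(-60, -30, 0, 30, 60, 90)
  y <- sapply(deltas, function(dd) {
    tot <- 0; cnt <- 0
    for (k in seq_along(pref)) {
      sel <- which_trials[ori_diff_signed(pref[k], trace$orientation[which_trials]) == dd]
      if (length(sel)) { tot <- tot + sum(trace$responses[sel, k]); cnt <- cnt + length(sel) }
    }
    tot / cnt
  })
  list(delta = deltas, mean = y)
}

#' Fit condition tuning curves of model traces
#'
#' Aligns the six channels to their preferred orientation, averages the
#' responses within each condition and fits the circular Gaussian, returning
#' gain and width per condition.
#'
#' @param traces named list of `model_trace` objects; conditions `random`
#'   (from the Random-sequence trace) and `expected`/`unexpected` (from the
#'   Rotating-sequence trace) are extracted by transition label.
#' @return data.frame: condition, gain, width, offset, n_trials.
#' @export
fit_model_conditions <- function(traces) {
  grab <- function(trace, label) {
    idx <- which(trace$transition == label)
    if (!length(idx)) return(NULL)
    cv <- .aligned_model_curve(trace, idx)
    f <- fit_circular_gaussian(cv$delta, cv$mean)
    data.frame(condition = label, gain = f$gain, width = f$width,
               offset = f$offset, n_trials = length(idx))
  }
  out <- list(
    random = if (!is.null(traces$random)) grab(traces$random, "random"),
    expected = if (!is.null(traces$rotating)) grab(traces$rotating, "expected"),
    unexpected = if (!is.null(traces$rotating)) grab(traces$rotating, "unexpected"))
  absent <- names(out)[vapply(out, is.null, logical(1))]
  if (length(absent)) stop("missing condition: ",
                           paste(absent, collapse = ", "))
  do.call(rbind, out)
}

#' Simulate the across-session condition statistics of the channel model
#'
#' Runs the paper-style experiment on the model: per session, two runs each
#' of Random (adaptation 0.5, expectation 0) and Rotating (0.25, 0.25)
#' sequences of 1800 presentations, condition tuning curves aligned and
#' fitted per session, then summarised across sessions (mean, SD, median,
#' quartiles of gain and width per condition).
#'
#' @param n_sessions number of sessions (default 23).
#' @param trials_per_run presentations per run (default 1800).
#' @param n_runs runs per condition per session (default 2).
#' @param seed master integer seed.
#' @param bank a `channel_bank`.
#' @param random_setting,rotating_setting the gain settings.
#' @return list with `per_session` (session x condition fits) and `summary`.
#' @export
simulate_condition_statistics <- function(n_sessions = 23,
                                          trials_per_run = 1800, n_runs = 2,
                                          seed = 1, bank = channel_bank(),
                                          random_setting = gain_setting(0.5, 0),
                                          rotating_setting = gain_setting(0.25, 0.25)) {
  seed <- as.integer(seed)
  per_session <- list()
  for (s in seq_len(n_sessions)) {
    acc <- list()   # accumulate aligned sums over runs per condition
    for (r in seq_len(n_runs)) {
      sub <- (seed + 7919L * s + 101L * r) %% .Machine$integer.max
      sq_rand <- generate_sequence("random", trials_per_run, seed = sub,
                                   balance = TRUE)
      sq_rot <- generate_sequence("rotating", trials_per_run, seed = sub + 1L)
      tr_rand <- run_model(bank, sq_rand, random_setting)
      tr_rot <- run_model(bank, sq_rot, rotating_setting)
      for (cond in c("random", "expected", "unexpected")) {
        trace <- if (cond == "random") tr_rand else tr_rot
        idx <- which(trace$transition == cond)
        cv <- .aligned_model_curve(trace, idx)
        w <- length(idx)
        if (is.null(acc[[cond]])) acc[[cond]] <- list(y = cv$mean * w, w = w)
        else acc[[cond]] <- list(y = acc[[cond]]$y + cv$mean * w,
                                 w = acc[[cond]]$w + w)
      }
    }
    fits <- do.call(rbind, lapply(names(acc), function(cond) {
      f <- fit_circular_gaussian(c(-60, -30, 0, 30, 60, 90),
                                 acc[[cond]]$y / acc[[cond]]$w)
      data.frame(session = s, condition = cond, gain = f$gain,
                 width = f$width, offset = f$offset,
                 n_trials = acc[[cond]]$w)
    }))
    per_session[[s]] <- fits
  }
  per_session <- do.call(rbind, per_session)
  summary <- do.call(rbind, lapply(split(per_session, per_session$condition),
    function(d) data.frame(
      condition = d$condition[1],
      gain_mean = mean(d$gain), gain_sd = sd(d$gain),
      gain_median = median(d$gain),
      gain_q1 = unname(quantile(d$gain, 0.25)),
      gain_q3 = unname(quantile(d$gain, 0.75)),
      width_mean = mean(d$width), width_sd = sd(d$width),
      width_median = median(d$width),
      width_q1 = unname(quantile(d$width, 0.25)),
      width_q3 = unname(quantile(d$width, 0.75)))))
  rownames(summary) <- NULL
  list(per_session = per_session, summary = summary)
}

#' Ridge regression of neuronal responses on model channel regressors
#'
#' Regresses each neuron's trial series of scalar responses on the six
#' channel-response regressors produced by a model run, with the ridge
#' penalty chosen per neuron by generalised cross-validation (closed form
#' via SVD). Returns beta weights, the regressor (orientation) with the
#' highest beta per neuron, and cross-validated variance explained.
#'
#' @param model_responses trials x channels regressor matrix.
#' @param neuron_scalars trials x neurons response matrix.
#' @param lambda_grid candidate ridge penalties for GCV.
#' @param n_folds folds for the cross-validated R^2.
#' @param seed fold-assignment seed.
#' @return list with `betas` (neurons x channels), `best_regressor`
#'   (channel index per neuron), `lambda`, `r2_cv`.
#' @export
regress_to_neurons <- function(model_responses, neuron_scalars,
                               lambda_grid = 10^seq(-4, 3, length.out = 30),
                               n_folds = 10, seed = 1) {
  X <- as.matrix(model_responses)
  Y <- as.matrix(neuron_scalars)
  if (nrow(X) != nrow(Y)) stop("trial counts of model and neurons differ")
  if (all(apply(X, 2, sd) < 1e-14))
    stop("degenerate regressors: all channels constant across trials")
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  UtY <- t(sv$u) %*% Yc
  d2 <- sv$d^2

  gcv_pick <- function(uty_col, y_col) {
    press <- vapply(lambda_grid, function(l) {
      shr <- d2 / (d2 + l)
      fit <- sv$u %*% (shr * uty_col)
      df <- sum(shr)
      mean((y_col - fit)^2) / (1 - df / n)^2
    }, numeric(1))
    lambda_grid[which.min(press)]
  }

  p <- ncol(X)
  betas <- matrix(NA_real_, ncol(Y), p)
  lambda <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    l <- gcv_pick(UtY[, j], Yc[, j])
    lambda[j] <- l
    betas[j, ] <- sv$v %*% ((sv$d / (d2 + l)) * UtY[, j])
  }
  best <- apply(betas, 1, which.max)

  # cross-validated R^2 with the per-neuron lambda
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  sse <- sst <- numeric(ncol(Y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- fold == f
    Xtr <- scale(X[tr, , drop = FALSE], center = TRUE, scale = FALSE)
    ctr <- attr(Xtr, "scaled:center")
    for (j in seq_len(ncol(Y))) {
      ytr <- Y[tr, j]; mu <- mean(ytr)
      b <- solve(crossprod(Xtr) + lambda[j] * diag(ncol(X)),
                 crossprod(Xtr, ytr - mu))
      pred <- sweep(X[te, , drop = FALSE], 2, ctr) %*% b + mu
      sse[j] <- sse[j] + sum((Y[te, j] - pred)^2)
      sst[j] <- sst[j] + sum((Y[te, j] - mean(Y[, j]))^2)
    }
  }
  list(betas = betas, best_regressor = best, lambda = lambda,
       r2_cv = 1 - sse / sst)
}

#' Compare adaptation, expectation and combined model variants
#'
#' Runs the channel model over a stimulus sequence for a grid of gain
#' levels under three model types (adaptation-only, expectation-only, and
#' combined: adaptation fixed at 0.25 with varying expectation gain), and
#' reports the cross-validated variance explained of each neuron's
#' responses by ridge regression on the model regressors.
#'
#' @param bank a `channel_bank`.
#' @param seq a labelled `orientation_sequence` (rotating).
#' @param neuron_scalars trials x neurons responses, aligned with `seq`.
#' @param levels gain levels (default `c(0, 0.2, 0.4, 0.6, 0.8, 1.0)`).
#' @param types model types to run.
#' @param seed seed for the regression folds.
#' @return data.frame: type, level, neuron, r2_cv.
#' @export
model_comparison_grid <- function(bank, seq, neuron_scalars,
                                  levels = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                                  types = c("adaptation", "expectation", "combined"),
                                  seed = 1) {
  out <- list()
  for (type in types) for (lv in levels) {
    setting <- switch(type,
      adaptation = gain_setting(lv, 0),
      expectation = gain_setting(0, lv),
      combined = gain_setting(0.25, lv))
    tr <- run_model(bank, seq, setting)
    rg <- regress_to_neurons(tr$responses, neuron_scalars, seed = seed)
    out[[length(out) + 1]] <- data.frame(
      type = type, level = lv, neuron = seq_len(ncol(neuron_scalars)),
      r2_cv = rg$r2_cv)
  }
  do.call(rbind, out)
}
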