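#' Simulate a population of model neurons
#'
#' Draws per-neuron generative tuning parameters for a synthetic V1
#' population. A fixed fraction of neurons is orientation selective with
#' circular-Gaussian tuning; the rest respond at baseline only. Selective
#' neurons carry a multiplicative gain factor applied on unexpected events,
#' the generative mirror of the expectation-violation enhancement the
#' analyses are designed to detect. A shared low-rank noise structure
#' (random loading vectors) is attached so that downstream covariance
#' shrinkage is exercised by correlated trial-to-trial noise.
#'
#' @param n_neurons number of neurons.
#' @param frac_selective proportion of orientation-selective neurons in
#'   [0, 1]; exactly `round(frac_selective * n_neurons)` are selective.
#' @param effect multiplicative tuning-gain factor on unexpected events
#'   (1 = no effect).
#' @param noise_corr proportion of noise variance carried by factors shared
#'   across neurons, in [0, 1).
#' @param seed integer seed.
#' @param gain_mean,gain_sd log-normal tuning gain parameters (dF/F %).
#' @param width_mean,width_sd generative tuning width (degrees).
#' @param baseline_mean baseline response (dF/F %).
#' @param noise_sd per-frame noise standard deviation (dF/F %).
#' @param n_factors number of shared noise factors.
#' @return data.frame of neuron specs (one row per neuron) with attributes
#'   `loadings` (n_neurons x n_factors), `noise_corr` and `seed`.
#' @export
simulate_population <- function(n_neurons, frac_selective = 0.273,
                                effect = 1.3, noise_corr = 0.2, seed = 1,
                                gain_mean = 40, gain_sd = 0.4,
                                width_mean = 40, width_sd = 5,
                                baseline_mean = 5, noise_sd = 15,
                                n_factors = 3) {
  if (frac_selective < 0 || frac_selective > 1)
    stop("frac_selective must lie in [0, 1]")
  if (noise_corr < 0 || noise_corr >= 1)
    stop("noise_corr must lie in [0, 1)")
  set.seed(as.integer(seed))
  n_sel <- round(frac_selective * n_neurons)
  is_sel <- rep(FALSE, n_neurons)
  if (n_sel > 0) is_sel[sample.int(n_neurons, n_sel)] <- TRUE
  specs <- data.frame(
    neuron = seq_len(n_neurons),
    preferred_orientation = runif(n_neurons, 0, 180),
    tuning_gain = ifelse(is_sel, gain_mean * exp(rnorm(n_neurons, 0, gain_sd)), 0),
    tuning_width = pmax(10, rnorm(n_neurons, width_mean, width_sd)),
    baseline = pmax(0, rnorm(n_neurons, baseline_mean, 2)),
    is_selective = is_sel,
    unexpected_gain_factor = ifelse(is_sel, effect, 1),
    noise_sd = rep(noise_sd, n_neurons)
  )
  loadings <- matrix(rnorm(n_neurons * n_factors), n_neurons, n_factors)
  loadings <- loadings / sqrt(rowSums(loadings^2))
  structure(specs, loadings = loadings, noise_corr = noise_corr,
            seed = as.integer(seed))
}

#' Simulate a dF/F population recording for a stimulus sequence
#'
#' Each event drives every neuron with
#' `baseline + gain * exp(-d^2 / (2 width^2))`, where `d` is the circular
#' distance (period 180) between the grating and the neuron's preferred
#' orientation; on unexpected events the tuned term is multiplied by the
#' neuron's `unexpected_gain_factor`. Drives are held for the 250 ms
#' presentation, convolved with a single-exponential calcium kernel
#' (GCaMP6f-like decay), and corrupted by Gaussian noise with the
#' population's shared low-rank component. The recording includes 1 s of
#' padding before the first and 3 s after the last event so that
#' peri-stimulus epochs fit.
#'
#' @param specs population from [simulate_population()].
#' @param seq labelled `orientation_sequence`.
#' @param frame_rate_hz imaging frame rate (default 30).
#' @param kernel_tau_ms calcium decay time constant (> 0; default 400).
#' @param seed integer seed for the noise.
#' @param noise if `FALSE`, emit noiseless traces.
#' @return a `population_recording`: list with `traces` (neurons x frames),
#'   `frame_rate_hz`, `events` (the sequence with a `frame_index` column,
#'   0-based) and `specs`.
#' @export
simulate_responses <- function(specs, seq, frame_rate_hz = 30,
                               kernel_tau_ms = 400, seed = 1, noise = TRUE) {
  if (nrow(seq) == 0) stop("empty sequence")
  if (kernel_tau_ms <= 0) stop("kernel_tau_ms must be positive")
  n_neurons <- nrow(specs)
  set.seed(as.integer(seed))

  dt_ms <- 1000 / frame_rate_hz
  pre_frames <- ceiling(1000 / dt_ms)
  post_frames <- ceiling(3000 / dt_ms)
  onset_frame <- pre_frames + round(seq$onset_ms / dt_ms)   # 0-based
  n_frames <- max(onset_frame) + round(STIM_DUR_MS / dt_ms) + post_frames

  # per-event tuned drive for every neuron (neurons x events)
  d <- outer(specs$preferred_orientation, seq$orientation, ori_dist)
  tuned <- specs$tuning_gain * exp(-d^2 / (2 * specs$tuning_width^2))
  unexp <- seq$transition == "unexpected"
  if (any(unexp)) tuned[, unexp] <- tuned[, unexp] * specs$unexpected_gain_factor
  drive_ev <- specs$baseline + tuned

  # frame-sampled drive: each event occupies its 250 ms slot
  slot <- round(STIM_DUR_MS / dt_ms)
  drive <- matrix(0, n_neurons, n_frames)
  for (e in seq_len(nrow(seq))) {
    f0 <- onset_frame[e] + 1
    drive[, f0:(f0 + slot - 1)] <- drive_ev[, e]
  }

  # causal exponential kernel, unit sum (a sustained drive of 1 reads out as 1)
  kl <- max(1, ceiling(5 * kernel_tau_ms / dt_ms))
  kern <- exp(-(0:(kl - 1)) * dt_ms / kernel_tau_ms)
  kern <- kern / sum(kern)
  conv_row <- function(x) {
    z <- stats::convolve(x, rev(kern), type = "open")
    z[seq_along(x)]
  }
  traces <- t(apply(drive, 1, conv_row))

  if (noise) {
    c2 <- attr(specs, "noise_corr") %||% 0
    loadings <- attr(specs, "loadings")
    eps <- matrix(rnorm(n_neurons * n_frames), n_neurons, n_frames)
    shared <- if (c2 > 0 && !is.null(loadings)) {
      z <- matrix(rnorm(ncol(loadings) * n_frames), ncol(loadings), n_frames)
      loadings %*% z
    } else 0
    traces <- traces + specs$noise_sd * (sqrt(1 - c2) * eps + sqrt(c2) * shared)
  }

  ev <- seq
  ev$frame_index <- onset_frame
  structure(list(traces = traces, frame_rate_hz = frame_rate_hz,
                 events = ev, specs = specs,
                 kernel_tau_ms = kernel_tau_ms),
            class = "population_recording")
}

#' Extract peri-stimulus epochs and scalar trial responses
#'
#' Cuts one epoch per event from a recording, frame-aligned to the nearest
#' frame at stimulus onset, and computes the scalar per-trial response as
#' the mean dF/F over a fixed post-onset window (default 250-1000 ms,
#' evaluated on absolute frame times, so a trial spans 22 or 23 frames at
#' 30 Hz depending on onset phase). Trials whose epoch would exceed the
#' recording are dropped with a message.
#'
#' @param rec a `population_recording`.
#' @param window_ms epoch window around onset, default `c(-500, 2000)`.
#' @param scalar_window_ms averaging window for the scalar response,
#'   default `c(250, 1000)`.
#' @param baseline_policy `"none"` or `"prestim"` (subtract the mean of the
#'   pre-onset part of each epoch).
#' @return an `epoched_responses`: list with `data` (neurons x trials x
#'   time), `time_ms`, `trials` (event metadata for retained trials),
#'   `scalar` (neurons x trials), `scalar_frames` (frames per trial in the
#'   scalar window) and `n_dropped`.
#' @export
extract_epochs <- function(rec, window_ms = c(-500, 2000),
                           scalar_window_ms = c(250, 1000),
                           baseline_policy = c("none", "prestim")) {
  baseline_policy <- match.arg(baseline_policy)
  if (window_ms[1] >= window_ms[2]) stop("window_ms is reversed")
  if (is.null(rec$events$frame_index)) stop("events are not bound to frames")
  dt_ms <- 1000 / rec$frame_rate_hz
  k0 <- floor(window_ms[1] / dt_ms)
  k1 <- ceiling(window_ms[2] / dt_ms)
  offs <- k0:k1
  n_frames <- ncol(rec$traces)

  f_on <- rec$events$frame_index             # 0-based
  ok <- (f_on + k0 >= 0) & (f_on + k1 <= n_frames - 1)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("extract_epochs: dropped %d trial(s) at recording edge", n_dropped))
  keep <- which(ok)

  n_neurons <- nrow(rec$traces)
  data <- array(NA_real_, c(n_neurons, length(keep), length(offs)))
  scalar <- matrix(NA_real_, n_neurons, length(keep))
  scalar_frames <- integer(length(keep))
  frame_time <- (seq_len(n_frames) - 1) * dt_ms
  for (j in seq_along(keep)) {
    t <- keep[j]
    idx <- f_on[t] + offs + 1
    ep <- rec$traces[, idx, drop = FALSE]
    if (baseline_policy == "prestim") {
      pre <- offs < 0
      if (any(pre)) ep <- ep - rowMeans(ep[, pre, drop = FALSE])
    }
    data[, j, ] <- ep
    onset_ms_abs <- f_on[t] * dt_ms
    win <- which(frame_time >= onset_ms_abs + scalar_window_ms[1] &
                 frame_time <= onset_ms_abs + scalar_window_ms[2])
    scalar_frames[j] <- length(win)
    sc <- rowMeans(rec$traces[, win, drop = FALSE])
    if (baseline_policy == "prestim") {
      pre <- offs < 0
      sc <- sc - rowMeans(rec$traces[, f_on[t] + offs[pre] + 1, drop = FALSE])
    }
    scalar[, j] <- sc
  }
  structure(list(data = data, time_ms = offs * dt_ms,
                 trials = as.data.frame(rec$events)[keep, , drop = FALSE],
                 scalar = scalar, scalar_frames = scalar_frames,
                 n_dropped = n_dropped,
                 frame_rate_hz = rec$frame_rate_hz),
            class = "epoched_responses")
}
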