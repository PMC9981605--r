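# Shared fixture builders. Everything is generated in code at test time.

# A mixed imaging session: a random run followed by a rotating(/-control)
# run, re-indexed onto one 4 Hz clock.
make_session <- function(n_random, n_rotating, seed,
                         rot_kind = "rotating_control",
                         balance_random = n_random %% 6 == 0) {
  sq_rand <- generate_sequence("random", n_random, seed = seed,
                               balance = balance_random)
  sq_rot <- generate_sequence(rot_kind, n_rotating, seed = seed + 1L)
  session <- rbind(as.data.frame(sq_rand), as.data.frame(sq_rot))
  session$index <- seq_len(nrow(session)) - 1L
  session$onset_ms <- (session$index) * 250
  structure(session, class = c("orientation_sequence", "data.frame"),
            kind = "mixed", seed = as.integer(seed))
}

# Hand-built neuron specs with exact parameters (bypasses the random draws)
make_specs <- function(preferred, gain, width = 40, baseline = 0,
                       factor = 1.3, noise_sd = 15, noise_corr = 0) {
  n <- length(preferred)
  specs <- data.frame(
    neuron = seq_len(n),
    preferred_orientation = preferred,
    tuning_gain = rep_len(gain, n),
    tuning_width = rep_len(width, n),
    baseline = rep_len(baseline, n),
    is_selective = rep_len(gain, n) > 0,
    unexpected_gain_factor = rep_len(factor, n),
    noise_sd = rep_len(noise_sd, n)
  )
  structure(specs, noise_corr = noise_corr,
            loadings = matrix(0, n, 1), seed = NA_integer_)
}

# epochs with suppressed edge-drop messages
quiet_epochs <- function(...) suppressMessages(extract_epochs(...))

# an "isolated" readout: near-instant kernel and a scalar window inside the
# presentation slot, so each trial's scalar reflects only its own stimulus
isolated_epochs <- function(rec) {
  suppressMessages(extract_epochs(rec, window_ms = c(-100, 240),
                                  scalar_window_ms = c(30, 200)))
}
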