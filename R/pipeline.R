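#' Configuration for a full analysis run
#'
#' Collects every parameter of an end-to-end run. All randomness flows from
#' the single `seed` via fixed per-stage offsets, so a run is reproducible
#' from its config alone.
#'
#' @param seed master integer seed.
#' @param n_neurons neurons in the simulated population.
#' @param frac_selective fraction of orientation-selective neurons.
#' @param effect unexpected gain factor injected by the simulator
#'   (1 = no effect, the negative control).
#' @param n_random_trials,n_rotating_trials presentations per condition.
#' @param noise_sd per-frame noise (dF/F %).
#' @param noise_corr shared noise fraction.
#' @param n_folds decoding cross-validation folds.
#' @param population_sizes neuron-pool sizes for decoding (NULL: full pool).
#' @param n_draws neuron draws per population size.
#' @param model_sessions sessions for the channel-model condition statistics.
#' @param model_trials_per_run,model_runs channel-model sequence sizes.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_neurons = 200, frac_selective = 0.273,
                       effect = 1.3, n_random_trials = 600,
                       n_rotating_trials = 600, noise_sd = 15,
                       noise_corr = 0.2, n_folds = 10,
                       population_sizes = NULL, n_draws = 8,
                       model_sessions = 23, model_trials_per_run = 1800,
                       model_runs = 2) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

# deterministic sub-seed derivation, kept below 2^31
.substream <- function(seed, k) (as.integer(seed) + 104729L * k) %% .Machine$integer.max

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order: stimulus generation (one random and one
#' rotating sequence, concatenated into a session), population simulation,
#' response simulation, epoch extraction, selectivity screening,
#' per-condition tuning with the surprise effect, population decoding by
#' cross-validated inverted encoding, the channel-model condition
#' statistics, and a sign-flip cluster test on the Unexpected-vs-Random
#' preferred-orientation time courses. Returns all result tables plus a
#' manifest of seeds and parameters; optionally writes the tables as CSV.
#'
#' @param config a `run_config`.
#' @param outdir optional directory for CSV output.
#' @param stages subset of `c("tuning", "decoding", "model")` to run after
#'   the simulation stages (all by default).
#' @return result bundle (list) with elements `config`, `screen`, `tuning`,
#'   `surprise`, `cluster`, `decoding`, `model`, `manifest`.
#' @export
run_full_analysis <- function(config = run_config(), outdir = NULL,
                              stages = c("tuning", "decoding", "model")) {
  stopifnot(inherits(config, "run_config"))
  stage <- "stimgen"
  bundle <- list(config = config)
  result <- tryCatch({
    sq_rand <- generate_sequence("random", config$n_random_trials,
                                 seed = .substream(config$seed, 1),
                                 balance = config$n_random_trials %% 6 == 0)
    sq_rot <- generate_sequence("rotating_control", config$n_rotating_trials,
                                seed = .substream(config$seed, 2))
    # one session: random run followed by rotating run
    rot_shift <- sq_rot
    session <- rbind(as.data.frame(sq_rand), as.data.frame(rot_shift))
    session$index <- seq_len(nrow(session)) - 1L
    session$onset_ms <- session$index * STIM_DUR_MS
    session <- structure(session,
                         class = c("orientation_sequence", "data.frame"),
                         kind = "mixed", seed = config$seed)

    stage <- "neurosim"
    specs <- simulate_population(config$n_neurons, config$frac_selective,
                                 effect = config$effect,
                                 noise_corr = config$noise_corr,
                                 noise_sd = config$noise_sd,
                                 seed = .substream(config$seed, 3))
    rec <- simulate_responses(specs, session,
                              seed = .substream(config$seed, 4))
    epochs <- extract_epochs(rec)

    stage <- "screening"
    screen <- screen_selectivity(epochs)
    sel <- which(screen$selective)
    bundle$screen <- screen

    if ("tuning" %in% stages) {
      stage <- "tuning"
      summ <- summarize_conditions(epochs, neurons = sel)
      bundle$tuning <- summ
      su <- unique(summ$table[, c("neuron", "surprise_effect")])
      bundle$surprise <- su[is.finite(su$surprise_effect), ]

      # cluster test: preferred-orientation response time course,
      # Unexpected minus Random, across selective neurons
      pref <- summ$preferred_bin$preferred_bin
      tr <- epochs$trials
      dmat <- t(vapply(seq_along(sel), function(i) {
        iu <- which(tr$transition == "unexpected" & tr$orientation == pref[i])
        ir <- which(tr$transition == "random" & tr$orientation == pref[i])
        colMeans(matrix(epochs$data[sel[i], iu, ], nrow = length(iu))) -
          colMeans(matrix(epochs$data[sel[i], ir, ], nrow = length(ir)))
      }, numeric(length(epochs$time_ms))))
      bundle$cluster <- sign_flip_cluster_test(
        dmat, n_perm = 1000, seed = .substream(config$seed, 5),
        time_ms = epochs$time_ms)
    }

    if ("decoding" %in% stages) {
      stage <- "decoding"
      bundle$decoding <- crossvalidate(
        epochs$scalar, epochs$trials$orientation, epochs$trials$transition,
        n_folds = config$n_folds,
        population_sizes = config$population_sizes,
        n_draws = config$n_draws, seed = .substream(config$seed, 6))
    }

    if ("model" %in% stages) {
      stage <- "model"
      bundle$model <- simulate_condition_statistics(
        n_sessions = config$model_sessions,
        trials_per_run = config$model_trials_per_run,
        n_runs = config$model_runs,
        seed = .substream(config$seed, 7))
    }
    bundle
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  result$manifest <- list(
    package_version = as.character(utils::packageVersion("predgain")),
    seed = config$seed,
    substreams = setNames(lapply(1:7, function(k) .substream(config$seed, k)),
                          c("random_seq", "rotating_seq", "population",
                            "responses", "cluster", "decoding", "model")),
    parameters = unclass(config),
    notes = c("encoder inversion: minimal-norm SVD pseudoinverse with Ledoit-Wolf whitening",
              "channel model: squaring output nonlinearity, persistence exponent m/(m+1)"))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, nm) if (!is.null(x))
      write.csv(x, file.path(outdir, paste0(nm, ".csv")), row.names = FALSE)
    wr(result$screen, "selectivity")
    if (!is.null(result$tuning)) wr(result$tuning$table, "tuning")
    wr(result$surprise, "surprise")
    if (!is.null(result$decoding)) wr(result$decoding$accuracy, "decoding")
    if (!is.null(result$model)) {
      wr(result$model$per_session, "model_sessions")
      wr(result$model$summary, "model_summary")
    }
    jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' Compare the surprise effect between two synthetic cohorts
#'
#' Runs the tuning stage on two cohorts (e.g. an "awake" and an
#' "anaesthetised" cohort differing in seed and effect size) and compares
#' their per-neuron surprise effects with a two-sided two-sample t-test.
#'
#' @param config_a,config_b `run_config`s for the two cohorts.
#' @return list with the two surprise-effect tables and the `t.test` result.
#' @export
compare_cohorts <- function(config_a, config_b) {
  a <- run_full_analysis(config_a, stages = "tuning")
  b <- run_full_analysis(config_b, stages = "tuning")
  list(surprise_a = a$surprise, surprise_b = b$surprise,
       test = t.test(a$surprise$surprise_effect, b$surprise$surprise_effect))
}
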