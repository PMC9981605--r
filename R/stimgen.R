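#' @importFrom stats rnorm runif sd quantile median aggregate oneway.test
#'   t.test pt qt complete.cases setNames
#' @importFrom utils write.csv read.csv head tail
NULL

ORIENTATIONS <- seq(0, 150, by = 30)
STIM_DUR_MS <- 250

#' Generate a grating sequence
#'
#' Builds an ordered sequence of grating presentations (4 Hz, 250 ms each,
#' orientations 0-150 degrees in 30-degree steps) under one of three
#' predictability regimes:
#'
#' * `random`: each orientation drawn independently of the last (optionally
#'   as a balanced shuffle so all six orientations occur equally often).
#' * `rotating`: the orientation steps by +/-30 degrees per presentation for
#'   a run of 5-9 presentations, then jumps to a random orientation other
#'   than the predicted one (an expectation violation), after which rotation
#'   resumes in the opposite direction from the landing orientation.
#' * `rotating_control`: as `rotating`, but after every unexpected jump one
#'   additional random jump occurs before rotation resumes in the opposite
#'   direction, controlling for the systematic rotation that follows a
#'   violation.
#'
#' Every event is labelled with its transition type (`sequence_start`,
#' `random`, `expected`, `unexpected`), the rotation direction in effect and,
#' where defined, the orientation that was expected.
#'
#' @param kind one of `"random"`, `"rotating"`, `"rotating_control"`.
#' @param n_events number of presentations (>= 0).
#' @param seed integer seed; identical arguments give identical sequences.
#' @param balance if `TRUE`, enforce equal presentation counts per
#'   orientation: exactly for `random` (requires `n_events` divisible by 6),
#'   and approximately for rotating kinds by weighting jump draws towards
#'   under-represented orientations.
#' @param session_id,run_id optional identifiers stored as attributes.
#' @return an `orientation_sequence`: a data.frame of events with columns
#'   `index` (0-based), `onset_ms`, `orientation`, `condition`, `transition`,
#'   `rotation_dir`, `expected_orientation`, plus attributes `kind` and
#'   `seed`.
#' @export
generate_sequence <- function(kind = c("random", "rotating", "rotating_control"),
                              n_events, seed, balance = FALSE,
                              session_id = NA, run_id = NA) {
  kind <- match.arg(kind)
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 0 ||
      n_events != floor(n_events))
    stop("n_events must be a non-negative integer")
  n_events <- as.integer(n_events)
  if (balance && kind == "random" && n_events %% 6 != 0)
    stop("balance requires n_events divisible by 6")
  set.seed(as.integer(seed))

  ori <- if (kind == "random") {
    if (n_events == 0) numeric(0)
    else if (balance) sample(rep(ORIENTATIONS, n_events / 6))
    else sample(ORIENTATIONS, n_events, replace = TRUE)
  } else {
    .rotating_orientations(n_events, control = (kind == "rotating_control"),
                           balance = balance)
  }

  ev <- data.frame(
    index = seq_len(n_events) - 1L,
    onset_ms = (seq_len(n_events) - 1L) * STIM_DUR_MS,
    orientation = ori
  )
  seq_obj <- structure(ev, class = c("orientation_sequence", "data.frame"),
                       kind = kind, seed = as.integer(seed),
                       session_id = session_id, run_id = run_id)
  label_transitions(seq_obj)
}

# Orientation walk for the rotating kinds. The landing orientation of each
# unexpected jump excludes the predicted continuation (otherwise the event
# would not be unexpected); all other orientations, including the one just
# shown, are permissible, matching the transition statistics of the Random
# condition. The control kind's extra post-violation jump is drawn uniformly
# over all six orientations so that it is fully uncorrelated with the
# violation.
.rotating_orientations <- function(n, control, balance = FALSE) {
  if (n == 0) return(numeric(0))
  counts <- setNames(rep(0, 6), as.character(ORIENTATIONS))
  draw <- function(excl = NULL) {
    pool <- if (is.null(excl)) ORIENTATIONS else setdiff(ORIENTATIONS, excl)
    if (balance) {
      deficit <- max(counts) - counts[as.character(pool)]
      w <- deficit + 1
      pool[sample.int(length(pool), 1, prob = w)]
    } else if (length(pool) == 1) pool else sample(pool, 1)
  }
  ori <- numeric(n)
  ori[1] <- sample(ORIENTATIONS, 1)
  counts[as.character(ori[1])] <- 1
  dir <- sample(c(-1, 1), 1)
  i <- 1
  push <- function(x) {
    force(x)
    i <<- i + 1
    ori[i] <<- x
    counts[as.character(x)] <<- counts[as.character(x)] + 1
  }
  while (i < n) {
    run_len <- sample(5:9, 1)
    for (k in seq_len(run_len)) {
      if (i >= n) break
      push(ori_wrap(ori[i] + 30 * dir))
    }
    if (i >= n) break
    predicted <- ori_wrap(ori[i] + 30 * dir)
    push(draw(predicted))                   # unexpected jump
    if (control && i < n) push(draw())      # extra random jump
    dir <- -dir
  }
  ori[seq_len(n)]
}

#' Label transitions of an orientation sequence
#'
#' Derives, from the orientations alone (plus the sequence kind), each
#' event's transition type, the rotation direction in effect, and the
#' expected orientation where one is defined. An event in a rotating
#' sequence is `expected` when its orientation continues the current
#' rotation by exactly 30 degrees; any other step is `unexpected` and
#' reverses the rotation direction. In the control kind the event
#' immediately after an unexpected jump is `random` by design and carries no
#' expectation. The function is idempotent: relabelling a labelled sequence
#' reproduces it exactly.
#'
#' @param seq an `orientation_sequence` (only `orientation` and the `kind`
#'   attribute are consulted).
#' @return the sequence with `condition`, `transition`, `rotation_dir` and
#'   `expected_orientation` columns (re)computed.
#' @export
label_transitions <- function(seq) {
  kind <- attr(seq, "kind")
  if (is.null(kind)) stop("sequence has no kind attribute")
  n <- nrow(seq)
  ori <- seq$orientation
  transition <- character(n)
  rotation_dir <- rep("none", n)
  expected <- rep(NA_real_, n)

  if (n > 0) transition[1] <- "sequence_start"
  if (kind == "random") {
    if (n > 1) transition[2:n] <- "random"
  } else {
    dir <- 0        # unknown until first 30-degree step
    post_jump <- FALSE
    for (t in seq_len(n)[-1]) {
      step <- ori_diff_signed(ori[t], ori[t - 1])
      if (post_jump) {
        # control kind: the event after a violation is a random jump
        transition[t] <- "random"
        post_jump <- FALSE
      } else if (dir == 0) {
        if (abs(step) == 30) {
          dir <- sign(step)
          transition[t] <- "expected"
          expected[t] <- ori[t]
        } else {
          transition[t] <- "unexpected"
        }
      } else {
        expected[t] <- ori_wrap(ori[t - 1] + 30 * dir)
        if (ori[t] == expected[t]) {
          transition[t] <- "expected"
        } else {
          transition[t] <- "unexpected"
          dir <- -dir
          if (kind == "rotating_control") post_jump <- TRUE
        }
      }
      rotation_dir[t] <- if (dir == 1) "cw" else if (dir == -1) "ccw" else "none"
    }
  }
  seq$condition <- rep(kind, n)
  seq$transition <- transition
  seq$rotation_dir <- rotation_dir
  seq$expected_orientation <- expected
  seq
}

#' Write an event table to delimited text
#'
#' Writes the event table as CSV and, alongside it, a small JSON sidecar
#' (`<path>.json`) holding the kind, seed and identifiers so a sequence can
#' be reconstructed or audited.
#'
#' @param seq an `orientation_sequence`.
#' @param path CSV output path.
#' @export
write_events <- function(seq, path) {
  write.csv(as.data.frame(seq), path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = attr(seq, "kind"), seed = attr(seq, "seed"),
               n_events = nrow(seq), session_id = attr(seq, "session_id"),
               run_id = attr(seq, "run_id"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return an `orientation_sequence`.
#' @export
read_events <- function(path) {
  ev <- read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(ev, class = c("orientation_sequence", "data.frame"),
            kind = meta$kind %||% ev$condition[1],
            seed = meta$seed %||% NA_integer_,
            session_id = meta$session_id, run_id = meta$run_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
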