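#' Fit a circular Gaussian tuning curve
#'
#' Fits `G(x) = A exp(-(x - phi - j*180)^2 / (2 sigma^2)) + C` by
#' Levenberg-Marquardt least squares, with the wrap index `j` searched over
#' integers -4..4 and the best solution across `j` (and a small multi-start
#' over initial preferred orientations) returned. `A` is the tuning gain,
#' `phi` the preferred orientation (reported modulo 180 into [0, 180)),
#' `sigma` the tuning width and `C` a constant offset.
#'
#' @param orientations orientations (degrees) at which responses were
#'   measured; at least 4 distinct values are required.
#' @param responses responses (e.g. dF/F %), same length.
#' @param sigma0 initial width (degrees).
#' @param sigma_bounds lower/upper bounds on the width.
#' @param offset fit the constant offset `C` (`TRUE`) or fix it at 0.
#' @param wrap if `TRUE` (default) the Gaussian is evaluated at the circular
#'   orientation distance, so curves peaked near the 0/180 boundary are
#'   represented correctly and the wrap index merely canonicalises the
#'   preferred orientation; `FALSE` uses the literal shifted form
#'   `x - phi - j*180` with a single shift per fit.
#' @param j_range the wrap search runs over `j in -j_range..j_range`
#'   (only used with `wrap = FALSE`).
#' @return a `tuning_fit` list: `gain`, `preferred`, `width`, `offset`,
#'   `wrap_index`, `rss`, `converged`.
#' @export
fit_circular_gaussian <- function(orientations, responses, sigma0 = 40,
                                  sigma_bounds = c(5, 120), offset = TRUE,
                                  wrap = TRUE, j_range = 4) {
  x <- as.numeric(orientations)
  y <- as.numeric(responses)
  if (length(unique(x)) < 4) stop("need at least 4 distinct orientations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")

  flat <- diff(range(y)) < 1e-12
  if (flat) {
    return(structure(list(gain = 0, preferred = ori_wrap(x[which.max(y)]),
                          width = sigma0, offset = mean(y), wrap_index = 0L,
                          rss = 0, converged = TRUE), class = "tuning_fit"))
  }

  best <- NULL
  x_peak <- x[which.max(y)]
  j_grid <- if (wrap) 0L else seq.int(-j_range, j_range)
  for (j in j_grid) {
    for (phi0 in c(x_peak, x_peak + 15)) {
      dist_fn <- if (wrap) function(p) ori_dist(x, p[2])
                 else function(p) x - p[2] - j * 180
      if (offset) {
        par0 <- c(A = max(y) - min(y), phi = phi0, sigma = sigma0, C = min(y))
        res_fn <- function(p) y - (p[1] * exp(-dist_fn(p)^2 / (2 * p[3]^2)) + p[4])
        lower <- c(0, -720, sigma_bounds[1], -Inf)
        upper <- c(Inf, 720, sigma_bounds[2], Inf)
      } else {
        par0 <- c(A = max(y), phi = phi0, sigma = sigma0)
        res_fn <- function(p) y - p[1] * exp(-dist_fn(p)^2 / (2 * p[3]^2))
        lower <- c(0, -720, sigma_bounds[1])
        upper <- c(Inf, 720, sigma_bounds[2])
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = par0, fn = res_fn, lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-14) {
        p <- fit$par
        best <- list(gain = unname(p[1]), preferred = ori_wrap(unname(p[2])),
                     width = unname(p[3]),
                     offset = if (offset) unname(p[4]) else 0,
                     wrap_index = as.integer(j), rss = rss,
                     converged = fit$info %in% 1:4)
      }
    }
  }
  if (is.null(best))
    best <- list(gain = NA_real_, preferred = NA_real_, width = NA_real_,
                 offset = NA_real_, wrap_index = NA_integer_, rss = Inf,
                 converged = FALSE)
  structure(best, class = "tuning_fit")
}

#' Screen neurons for orientation selectivity
#'
#' One-way analysis of variance of the scalar (250-1000 ms) response across
#' the six orientations, computed separately within each screening condition
#' (by default Random and Unexpected trials). A neuron is selective if
#' p < `alpha` in either condition. Neurons with fewer than `min_trials`
#' trials for any orientation in a condition are excluded from that
#' condition's test.
#'
#' @param epochs an `epoched_responses`.
#' @param conditions transition labels to screen within.
#' @param alpha significance level per test.
#' @param min_trials minimum trials per orientation per condition.
#' @return data.frame with one row per neuron: p-values per condition,
#'   `selective`, and `excluded` (no condition testable).
#' @export
screen_selectivity <- function(epochs, conditions = c("random", "unexpected"),
                               alpha = 0.05, min_trials = 2) {
  trials <- epochs$trials
  n_neurons <- nrow(epochs$scalar)
  pmat <- matrix(NA_real_, n_neurons, length(conditions),
                 dimnames = list(NULL, conditions))
  for (ci in seq_along(conditions)) {
    idx <- which(trials$transition == conditions[ci])
    if (!length(idx)) next
    g <- factor(trials$orientation[idx])
    if (nlevels(g) < 2 || any(table(g) < min_trials)) next
    for (n in seq_len(n_neurons)) {
      y <- epochs$scalar[n, idx]
      if (sd(y) < 1e-15) next
      pmat[n, ci] <- oneway.test(y ~ g, var.equal = TRUE)$p.value
    }
  }
  excluded <- rowSums(!is.na(pmat)) == 0
  selective <- !excluded & apply(pmat, 1, function(p) any(p < alpha, na.rm = TRUE))
  out <- data.frame(neuron = seq_len(n_neurons), selective = selective,
                    excluded = excluded)
  for (ci in seq_along(conditions)) out[[paste0("p_", conditions[ci])]] <- pmat[, ci]
  out
}

# mean scalar response at each of the 6 orientations for a trial subset;
# returns a neurons x 6 matrix
.tuning_curve <- function(scalar, trials, idx) {
  m <- sapply(ORIENTATIONS, function(o) {
    sel <- idx[trials$orientation[idx] == o]
    if (!length(sel)) rep(NA_real_, nrow(scalar))
    else rowMeans(scalar[, sel, drop = FALSE])
  })
  matrix(m, ncol = length(ORIENTATIONS))
}

#' Per-condition tuning summaries and the surprise effect
#'
#' For each neuron and condition, computes the 6-point tuning curve from the
#' scalar responses, fits the circular Gaussian, and derives the surprise
#' effect (fitted gain in Random minus Unexpected; negative values indicate
#' enhancement by surprise). Also returns a population-aligned tuning curve
#' per condition (neurons aligned to their preferred orientation from the
#' reference condition) with its Gaussian fit, and circular-mean
#' orientation-selectivity time courses.
#'
#' @param epochs an `epoched_responses`.
#' @param neurons indices of neurons to summarise (e.g. the selective ones).
#' @param conditions transition labels to summarise.
#' @param reference condition used to define each neuron's preferred
#'   orientation for alignment.
#' @param timecourse also compute the circular-mean time course (slower).
#' @return list with `table` (per neuron x condition fits, surprise effect),
#'   `aligned` (per condition: aligned average curve and its fit) and
#'   `timecourse` (condition x time matrix of mean circular-mean resultants,
#'   or `NULL`).
#' @export
summarize_conditions <- function(epochs, neurons = NULL,
                                 conditions = c("random", "expected", "unexpected"),
                                 reference = "random", timecourse = FALSE) {
  trials <- epochs$trials
  scalar <- epochs$scalar
  if (is.null(neurons)) neurons <- seq_len(nrow(scalar))
  present <- conditions[conditions %in% trials$transition]
  if (length(present) < length(conditions))
    warning("conditions absent and omitted: ",
            paste(setdiff(conditions, present), collapse = ", "))

  curves <- list()   # condition -> neurons x 6
  for (cond in present) {
    idx <- which(trials$transition == cond)
    curves[[cond]] <- .tuning_curve(scalar[neurons, , drop = FALSE], trials, idx)
  }

  tab <- do.call(rbind, lapply(seq_along(neurons), function(i) {
    do.call(rbind, lapply(present, function(cond) {
      yy <- curves[[cond]][i, ]
      if (any(!is.finite(yy))) return(NULL)
      f <- fit_circular_gaussian(ORIENTATIONS, yy)
      # a fit pinned at the width bounds has collapsed into a spike or a
      # ramp and carries no interpretable gain
      valid <- f$converged && f$width > 5.5 && f$width < 119
      data.frame(neuron = neurons[i], condition = cond, gain = f$gain,
                 preferred = f$preferred, width = f$width, offset = f$offset,
                 rss = f$rss, valid = valid)
    }))
  }))
  # surprise effect: random minus unexpected fitted gain, per neuron,
  # defined only where both condition fits are valid
  if (all(c("random", "unexpected") %in% present)) {
    gr <- tab[tab$condition == "random", c("neuron", "gain", "valid")]
    gu <- tab[tab$condition == "unexpected", c("neuron", "gain", "valid")]
    m <- merge(gr, gu, by = "neuron", suffixes = c("_random", "_unexpected"))
    m$surprise_effect <- ifelse(m$valid_random & m$valid_unexpected,
                                m$gain_random - m$gain_unexpected, NA_real_)
    tab <- merge(tab, m[, c("neuron", "surprise_effect")], by = "neuron",
                 all.x = TRUE)
  } else tab$surprise_effect <- NA_real_

  # population curves aligned to the reference-condition preferred orientation
  ref_curve <- curves[[reference]]
  pref_bin <- ORIENTATIONS[apply(ref_curve, 1, which.max)]
  aligned <- lapply(present, function(cond) {
    deltas <- c(-60, -30, 0, 30, 60, 90)
    am <- sapply(deltas, function(dd) {
      v <- numeric(0)
      for (i in seq_along(neurons)) {
        o <- ori_wrap(pref_bin[i] + dd)
        v <- c(v, curves[[cond]][i, match(o, ORIENTATIONS)])
      }
      mean(v, na.rm = TRUE)
    })
    f <- fit_circular_gaussian(deltas, am)
    list(delta = deltas, mean = am, fit = f)
  })
  names(aligned) <- present

  tc <- NULL
  if (timecourse) {
    nt <- length(epochs$time_ms)
    tc <- matrix(NA_real_, length(present), nt,
                 dimnames = list(present, NULL))
    for (cond in present) {
      idx <- which(trials$transition == cond)
      for (ti in seq_len(nt)) {
        slab <- epochs$data[neurons, idx, ti, drop = FALSE]
        res <- sapply(seq_along(neurons), function(i) {
          yy <- sapply(ORIENTATIONS, function(o)
            mean(slab[i, trials$orientation[idx] == o, 1]))
          w <- yy - min(yy)
          circular_mean_orientation(ORIENTATIONS, w)$resultant
        })
        tc[cond, ti] <- mean(res)
      }
    }
  }
  list(table = tab, aligned = aligned, timecourse = tc,
       preferred_bin = data.frame(neuron = neurons, preferred_bin = pref_bin))
}

#' Violation-binned tuning curves
#'
#' Groups unexpected trials by the magnitude of the expectation violation
#' and, per bin, computes the population tuning curve aligned to each
#' neuron's preferred orientation together with its Gaussian fit, giving
#' gain and baseline as functions of how wrong the prediction was.
#'
#' @param epochs an `epoched_responses` from a rotating sequence.
#' @param neurons neuron indices to include.
#' @param preferred_bin per-neuron preferred orientation (on the 30-degree
#'   grid), e.g. from [summarize_conditions()].
#' @return data.frame: violation magnitude, fitted gain, offset, width.
#' @export
violation_tuning <- function(epochs, neurons, preferred_bin) {
  trials <- epochs$trials
  idx_u <- which(trials$transition == "unexpected" &
                 is.finite(trials$expected_orientation))
  viol <- violation_magnitude(trials$expected_orientation[idx_u],
                              trials$orientation[idx_u])
  deltas <- c(-60, -30, 0, 30, 60, 90)
  out <- lapply(sort(unique(viol)), function(v) {
    idx <- idx_u[viol == v]
    am <- sapply(deltas, function(dd) {
      vals <- numeric(0)
      for (i in seq_along(neurons)) {
        o <- ori_wrap(preferred_bin[i] + dd)
        sel <- idx[trials$orientation[idx] == o]
        if (length(sel))
          vals <- c(vals, mean(epochs$scalar[neurons[i], sel]))
      }
      mean(vals)
    })
    f <- fit_circular_gaussian(deltas, am)
    data.frame(violation = v, gain = f$gain, offset = f$offset,
               width = f$width, n_trials = length(idx))
  })
  do.call(rbind, out)
}

#' Per-neuron expectation-modulation test
#'
#' Two-sided two-sample t-test on single-trial scalar responses at each
#' neuron's preferred orientation, Unexpected versus Random.
#'
#' @param epochs an `epoched_responses`.
#' @param neurons neuron indices.
#' @param preferred_bin per-neuron preferred orientation on the stimulus grid.
#' @param alpha significance level.
#' @return data.frame: neuron, mean difference (unexpected - random), p,
#'   modulated flag.
#' @export
modulation_test <- function(epochs, neurons, preferred_bin, alpha = 0.05) {
  trials <- epochs$trials
  out <- lapply(seq_along(neurons), function(i) {
    iu <- which(trials$transition == "unexpected" &
                trials$orientation == preferred_bin[i])
    ir <- which(trials$transition == "random" &
                trials$orientation == preferred_bin[i])
    if (length(iu) < 2 || length(ir) < 2)
      return(data.frame(neuron = neurons[i], diff = NA_real_, p = NA_real_,
                        modulated = NA))
    tt <- t.test(epochs$scalar[neurons[i], iu], epochs$scalar[neurons[i], ir])
    data.frame(neuron = neurons[i],
               diff = mean(epochs$scalar[neurons[i], iu]) -
                      mean(epochs$scalar[neurons[i], ir]),
               p = tt$p.value, modulated = tt$p.value < alpha)
  })
  do.call(rbind, out)
}
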