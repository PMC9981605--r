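#' Circular orientation arithmetic (period 180 degrees)
#'
#' Orientations of gratings live on a half-circle: a grating at 180 degrees
#' is the same stimulus as one at 0 degrees. All differences in this package
#' therefore wrap with period 180, and "vector" operations double the angle
#' first so that standard circular statistics apply.
#'
#' @param x orientation(s) in degrees.
#' @return `ori_wrap` returns orientations wrapped into [0, 180).
#' @export
ori_wrap <- function(x) x %% 180

# wrap into [0, 180), snapping values within rounding error of 180 to 0
.snap_wrap <- function(x) {
  x <- x %% 180
  x[x >= 180 - 1e-9] <- 0
  x
}

#' Signed circular difference between orientations
#'
#' @param a,b orientations in degrees.
#' @return signed difference `a - b` wrapped into (-90, 90].
#' @export
ori_diff_signed <- function(a, b) {
  r <- ((a - b + 90) %% 180) - 90
  ifelse(r == -90, 90, r)
}

#' Absolute circular distance between orientations
#'
#' @param a,b orientations in degrees.
#' @return distance in [0, 90].
#' @export
ori_dist <- function(a, b) abs(ori_diff_signed(a, b))

#' Expectation-violation magnitude
#'
#' The circular distance (period 180) between the orientation a rotating
#' sequence predicted and the orientation actually presented. For the
#' 30-degree stimulus grid the unsigned magnitude is one of 0, 30, 60, 90.
#' With `signed = TRUE` the difference `presented - expected` is returned in
#' (-90, 90], the convention used when binning decoding errors by the side
#' on which the expected orientation fell.
#'
#' @param expected expected orientation(s), degrees in [0, 360).
#' @param presented presented orientation(s), degrees in [0, 360).
#' @param signed return the signed difference instead of the magnitude.
#' @return violation in degrees.
#' @export
violation_magnitude <- function(expected, presented, signed = FALSE) {
  if (any(!is.finite(expected)) || any(!is.finite(presented)))
    stop("orientations must be finite")
  if (any(expected < 0 | expected >= 360) || any(presented < 0 | presented >= 360))
    stop("orientations must lie in [0, 360)")
  if (signed) ori_diff_signed(presented, expected)
  else ori_dist(presented, expected)
}

#' Circular mean and resultant of an orientation tuning curve
#'
#' Computes the weighted circular mean on doubled angles (period 180). The
#' resultant length measures how concentrated the curve is around a single
#' orientation; a perfectly uniform curve has resultant 0.
#'
#' @param orientations orientations in degrees at which `weights` were measured.
#' @param weights non-negative weights (typically responses minus their
#'   minimum, so that a flat curve carries no orientation signal).
#' @return list with `mean` (degrees in [0, 180), `NA` if the resultant is
#'   numerically zero) and `resultant` (mean resultant vector length, in the
#'   units of `weights`).
#' @export
circular_mean_orientation <- function(orientations, weights) {
  stopifnot(length(orientations) == length(weights))
  z <- sum(weights * exp(2i * pi * orientations / 180))
  r <- Mod(z) / length(orientations)
  m <- if (Mod(z) < 1e-12) NA_real_ else .snap_wrap(Arg(z) * 90 / pi)
  list(mean = m, resultant = r)
}

#' Decode an orientation from a response profile by vector averaging
#'
#' Sums unit vectors at twice each orientation, weighted by the response, and
#' halves the angle of the resultant. Used both for the channel model's
#' population read-out and for encoding-model reconstructions.
#'
#' @param responses response at each orientation.
#' @param orientations orientations in degrees.
#' @return list with `orientation` (decoded, degrees in [0,180), `NA` when
#'   the profile carries no net orientation signal) and `resultant`
#'   (magnitude of the mean resultant vector).
#' @export
vector_average_orientation <- function(responses, orientations) {
  z <- sum(responses * exp(2i * pi * orientations / 180))
  if (Mod(z) / max(1, length(responses)) < 1e-12)
    return(list(orientation = NA_real_, resultant = 0))
  list(orientation = .snap_wrap(Arg(z) * 90 / pi),
       resultant = Mod(z) / length(responses))
}

#' Decoding accuracy of a set of orientation errors
#'
#' The mean resultant length of the error distribution on doubled angles:
#' 1 when every trial is decoded exactly, 0 at chance.
#'
#' @param errors signed orientation errors in degrees.
#' @return scalar in [0, 1] (signed: the projection onto the zero-error
#'   direction, so systematic biases reduce it).
#' @export
error_resultant <- function(errors) {
  errors <- errors[is.finite(errors)]
  if (!length(errors)) return(NA_real_)
  Re(mean(exp(2i * pi * errors / 180)))
}
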