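#' Basis set for orientation encoding
#'
#' Half-cosine basis functions raised to a power, centred every
#' 180/n_channels degrees (nine channels at 0, 20, ..., 160 by default),
#' evaluated on a 1-degree orientation grid. With `normalize = TRUE` the
#' basis values at each orientation are scaled so the channels tile
#' orientation space exactly (their sum is constant across orientations).
#'
#' @param n_channels number of channels (default 9; 8 is retained as an
#'   option for compatibility with alternative channel counts).
#' @param exponent power applied to the rectified cosine (default 8).
#' @param grid_step evaluation grid spacing in degrees.
#' @param normalize scale so the channel sum is constant over orientations.
#' @return a `basis_set`: list with `centres`, `exponent`, `grid`
#'   (orientations) and `values` (grid x channels matrix).
#' @export
basis_set <- function(n_channels = 9, exponent = 8, grid_step = 1,
                      normalize = TRUE) {
  centres <- seq(0, 180 - 180 / n_channels, by = 180 / n_channels)
  grid <- seq(0, 180 - grid_step, by = grid_step)
  values <- sapply(centres, function(c0)
    pmax(cos(pi * ori_diff_signed(grid, c0) / 180), 0)^exponent)
  if (normalize) {
    s <- rowSums(values)
    values <- values / s * mean(s)
  }
  structure(list(centres = centres, exponent = exponent, grid = grid,
                 values = values, normalize = normalize),
            class = "basis_set")
}

# basis values at arbitrary orientations (channels x length(x))
.basis_at <- function(basis, x) {
  v <- sapply(x, function(o)
    pmax(cos(pi * ori_diff_signed(o, basis$centres) / 180), 0)^basis$exponent)
  v <- matrix(v, nrow = length(basis$centres))
  if (isTRUE(basis$normalize)) {
    s <- colSums(v)
    ref <- mean(rowSums(basis$values))
    v <- sweep(v, 2, s, "/") * ref
  }
  v
}

#' Build the tuned regressor matrix for a set of presented orientations
#'
#' Column t holds each channel's basis value at the orientation presented on
#' trial t.
#'
#' @param orientations presented orientations in degrees, in [0, 180).
#' @param basis a `basis_set`.
#' @return channels x trials matrix.
#' @export
build_design <- function(orientations, basis = basis_set()) {
  if (!length(orientations)) stop("empty sequence")
  if (any(orientations < 0 | orientations >= 180))
    stop("orientations must lie in [0, 180)")
  .basis_at(basis, orientations)
}

# Ledoit-Wolf shrinkage of a sample covariance towards its diagonal.
# Returns the shrunk covariance and the shrinkage intensity.
.ledoit_wolf <- function(X) {            # X: observations x variables
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  target <- diag(diag(S), p)
  # dispersion of per-observation outer products around S (Ledoit & Wolf
  # 2004, b^2), computed without forming the outer products:
  # sum_i ||x_i x_i' - S||^2 = sum_i ||x_i||^4 - 2 sum_i x_i' S x_i + n ||S||^2
  nrm2 <- rowSums(Xc^2)
  quad <- rowSums((Xc %*% S) * Xc)
  b2 <- (sum(nrm2^2) - 2 * sum(quad) + n * sum(S^2)) / n^2
  d2 <- sum((S - target)^2)
  lambda <- if (d2 < 1e-30) 1 else min(1, max(0, b2 / d2))
  list(sigma = (1 - lambda) * S + lambda * target, lambda = lambda)
}

#' Train the forward encoding model
#'
#' Estimates the neurons x channels weight matrix from training responses
#' `B1` (neurons x trials) and the tuned regressors `C1` (channels x
#' trials). The default estimates each channel's weights separately by
#' least squares (the stimulus set spans only six orientations, so the
#' joint normal equations are singular for nine channels);
#' `method = "joint"` solves the full normal equations
#' `W = B1 C1' (C1 C1')^-1` and errors on rank deficiency. The residual
#' noise covariance between neurons is estimated with Ledoit-Wolf shrinkage
#' towards its diagonal and stored for whitening during decoding.
#'
#' @param B1 neurons x trials training responses.
#' @param C1 channels x trials regressors (column-aligned with `B1`).
#' @param method `"per_channel"` (default) or `"joint"`.
#' @param shrinkage `"ledoit"` (default) or `"none"`.
#' @return an `encoder_model`: `W`, `sigma` (shrunk covariance or `NULL`),
#'   `lambda` (shrinkage intensity), `method`.
#' @export
train_encoder <- function(B1, C1, method = c("per_channel", "joint"),
                          shrinkage = c("ledoit", "none")) {
  method <- match.arg(method)
  shrinkage <- match.arg(shrinkage)
  if (ncol(B1) != ncol(C1)) stop("B1 and C1 must be column-aligned")
  if (ncol(C1) < nrow(C1)) stop("fewer trials than channels")
  if (method == "joint") {
    G <- C1 %*% t(C1)
    if (rcond(G) < 1e-12)
      stop("C1 C1' is singular: the design does not span the channel space")
    W <- B1 %*% t(C1) %*% solve(G)
  } else {
    denom <- rowSums(C1^2)
    W <- (B1 %*% t(C1)) / matrix(denom, nrow(B1), nrow(C1), byrow = TRUE)
  }
  sigma <- NULL; lambda <- NA_real_
  if (shrinkage == "ledoit") {
    resid <- B1 - W %*% C1
    if (sum(resid^2) > 1e-18 * max(1, sum(B1^2))) {
      lw <- .ledoit_wolf(t(resid))
      sigma <- lw$sigma
      lambda <- lw$lambda
    }
  }
  structure(list(W = W, sigma = sigma, lambda = lambda, method = method),
            class = "encoder_model")
}

#' Invert the encoding model on test data
#'
#' Estimates test channel responses by the (optionally noise-whitened)
#' least-squares inversion of the trained weights, expands them through the
#' basis onto the orientation grid, and decodes each trial's orientation by
#' the doubled-angle vector sum over the reconstructed profile. The
#' orientation error is the signed circular difference between decoded and
#' presented orientation; the decoding accuracy is the resultant of the
#' error distribution.
#'
#' With `literal = TRUE` the inversion uses the unscaled form
#' `C2 = (W W') W' B2` for comparison; the default is the least-squares
#' estimator `C2 = (W' S^-1 W)^-1 W' S^-1 B2` with `S` the shrunk residual
#' covariance (identity when unavailable).
#'
#' @param model an `encoder_model`.
#' @param B2 neurons x trials test responses (neuron order as in training).
#' @param basis the `basis_set` used to build the design.
#' @param presented optional presented orientations, enabling errors,
#'   accuracy and the re-centred mean profile.
#' @param literal use the unscaled inversion form.
#' @return a `reconstruction`: `channels` (channels x trials), `profile`
#'   (grid x trials), `decoded`, `resultant`, `error`, `accuracy`,
#'   `recentred` (profile x trials on a -89..90 axis) when `presented`
#'   given.
#' @export
decode <- function(model, B2, basis = basis_set(), presented = NULL,
                   literal = FALSE) {
  W <- model$W
  if (nrow(B2) != nrow(W)) stop("neuron count mismatch between model and B2")
  if (literal) {
    C2 <- (W %*% t(W)) %*% t(W) %*% B2
  } else {
    # with 6 distinct stimuli and 9 channels W has rank <= 6, so the
    # inversion uses the minimal-norm least-squares solution (SVD
    # pseudoinverse), after whitening by the shrunk noise covariance when
    # one was estimated
    Wd <- W; Bd <- B2
    if (!is.null(model$sigma)) {
      eg <- eigen(model$sigma, symmetric = TRUE)
      ev <- pmax(eg$values, max(eg$values) * 1e-12)
      S2 <- eg$vectors %*% (t(eg$vectors) / sqrt(ev))
      Wd <- S2 %*% W
      Bd <- S2 %*% B2
    }
    sv <- svd(Wd)
    tol <- max(dim(Wd)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    C2 <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Bd) / sv$d[pos])
  }
  profile <- basis$values %*% C2          # grid x trials
  dec <- apply(profile, 2, function(p) {
    va <- vector_average_orientation(p, basis$grid)
    c(va$orientation, va$resultant)
  })
  decoded <- dec[1, ]
  resultant <- dec[2, ]
  out <- list(channels = C2, profile = profile, grid = basis$grid,
              decoded = decoded, resultant = resultant)
  if (!is.null(presented)) {
    out$presented <- presented
    out$error <- ori_diff_signed(decoded, presented)
    out$accuracy <- error_resultant(out$error)
    # re-centre each trial's profile on its presented orientation
    rel <- seq(-89, 90)
    rec <- sapply(seq_along(presented), function(t) {
      o <- ori_wrap(presented[t] + rel)
      profile[match(o, basis$grid), t]
    })
    out$recentred <- matrix(rec, nrow = length(rel),
                            dimnames = list(rel, NULL))
  }
  structure(out, class = "reconstruction")
}

# stratified fold assignment: within each orientation (and condition),
# spread trials as evenly as possible over folds
.stratified_folds <- function(orientations, n_folds, seed,
                              strata = NULL) {
  set.seed(seed)
  fold <- integer(length(orientations))
  key <- if (is.null(strata)) as.character(orientations)
         else paste(orientations, strata)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Cross-validated decoding of orientation from population responses
#'
#' Splits trials into stratified folds (most even distribution of stimuli
#' per fold), trains the encoder on the training folds and decodes the test
#' fold, so that every trial is tested exactly once. Accuracy (error
#' resultant) is reported per condition, optionally per population size
#' with `n_draws` random neuron subsets per size.
#'
#' @param scalar neurons x trials response matrix.
#' @param orientations presented orientation per trial.
#' @param conditions condition label per trial.
#' @param n_folds number of folds (default 10).
#' @param basis a `basis_set`.
#' @param population_sizes optional vector of neuron-pool sizes.
#' @param n_draws random neuron subsets per population size (default 24).
#' @param seed integer seed (fold assignment and neuron draws).
#' @param method,shrinkage passed to [train_encoder()].
#' @return list with `accuracy` (data.frame: condition, n_neurons, draw,
#'   accuracy), `errors` (per-trial signed errors for the full population
#'   run, `NULL` if only sized runs requested) and `fold` assignment.
#' @export
crossvalidate <- function(scalar, orientations, conditions, n_folds = 10,
                          basis = basis_set(), population_sizes = NULL,
                          n_draws = 24, seed = 1,
                          method = "per_channel", shrinkage = "ledoit") {
  n_trials <- length(orientations)
  if (n_folds > n_trials) stop("more folds than trials")
  fold <- .stratified_folds(orientations, n_folds, seed)
  C_all <- build_design(orientations, basis)

  run_once <- function(neurons) {
    err <- rep(NA_real_, n_trials)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- fold == f
      mdl <- train_encoder(scalar[neurons, tr, drop = FALSE],
                           C_all[, tr, drop = FALSE],
                           method = method, shrinkage = shrinkage)
      rec <- decode(mdl, scalar[neurons, te, drop = FALSE], basis,
                    presented = orientations[te])
      err[te] <- rec$error
    }
    err
  }

  acc_rows <- list(); errors <- NULL
  if (is.null(population_sizes)) {
    err <- run_once(seq_len(nrow(scalar)))
    errors <- err
    for (cond in unique(conditions))
      acc_rows[[length(acc_rows) + 1]] <-
        data.frame(condition = cond, n_neurons = nrow(scalar), draw = 1L,
                   accuracy = error_resultant(err[conditions == cond]))
  } else {
    for (sz in population_sizes) {
      if (sz > nrow(scalar)) stop("population size exceeds available neurons")
      for (d in seq_len(n_draws)) {
        set.seed(seed + 1000L * d + as.integer(sz))
        neurons <- sample.int(nrow(scalar), sz)
        err <- run_once(neurons)
        for (cond in unique(conditions))
          acc_rows[[length(acc_rows) + 1]] <-
            data.frame(condition = cond, n_neurons = sz, draw = d,
                       accuracy = error_resultant(err[conditions == cond]))
      }
    }
  }
  list(accuracy = do.call(rbind, acc_rows), errors = errors, fold = fold)
}

#' Decoding bias binned by signed expectation violation
#'
#' Means of signed decoding errors grouped by the signed violation
#' (presented minus expected orientation). A bias with the same sign as the
#' violation indicates repulsion of the decoded orientation away from the
#' expected orientation.
#'
#' @param errors signed decoding errors (degrees).
#' @param violations signed expectation violations (degrees).
#' @return data.frame: violation bin, mean bias, n.
#' @export
violation_binned_bias <- function(errors, violations) {
  ok <- is.finite(errors) & is.finite(violations)
  bins <- sort(unique(violations[ok]))
  do.call(rbind, lapply(bins, function(v) {
    e <- errors[ok & violations == v]
    data.frame(violation = v, bias = mean(e), n = length(e))
  }))
}
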