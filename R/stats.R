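#' Sign-flip cluster permutation test for paired time series
#'
#' Non-parametric test of whether a set of paired differences (one time
#' series per unit: neurons, sessions or permuted neuron groups) deviates
#' from zero, controlling the family-wise error over timepoints by
#' cluster-based correction. The timepoint statistic is a one-sample t
#' against zero; clusters are maximal contiguous runs of |t| above the
#' two-sided `cluster_alpha` threshold with a common sign, and cluster mass
#' is the summed t. The null distribution is built by flipping the sign of
#' each unit's entire time series with probability 1/2 (which preserves the
#' temporal autocorrelation within a unit, the only exchangeable structure
#' for paired series) and recording the maximal absolute cluster mass.
#' P-values use the add-one convention and are never exactly 0.
#'
#' @param diffs units x timepoints matrix of paired differences.
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param cluster_alpha cluster-forming threshold (two-sided).
#' @param alpha significance threshold on cluster p-values.
#' @param seed integer seed.
#' @param time_ms optional timepoint labels for the cluster spans.
#' @return a `cluster_test` list: `t` (observed t per timepoint),
#'   `clusters` (data.frame: start, end, start_ms, end_ms, mass, p,
#'   significant), `sig_timepoints` (logical), `n_perm`, `seed`.
#' @export
sign_flip_cluster_test <- function(diffs, n_perm = 5000, cluster_alpha = 0.05,
                                   alpha = 0.05, seed = 1, time_ms = NULL) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs); nt <- ncol(diffs)
  if (n < 2) stop("need at least 2 units")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (any(!is.finite(diffs))) stop("diffs must be finite")
  if (is.null(time_ms)) time_ms <- seq_len(nt)

  tstat <- function(num_mean) {
    # num_mean: means per timepoint (possibly a matrix perm x time);
    # the sum of squares is flip-invariant, so sd comes from ss and mean
    ss <- colSums(diffs^2)
    if (is.matrix(num_mean)) {
      v <- (rep(1, nrow(num_mean)) %o% ss - n * num_mean^2) / (n - 1)
      v[v < 0] <- 0
      num_mean / sqrt(v / n + (v == 0))
    } else {
      v <- pmax(0, (ss - n * num_mean^2) / (n - 1))
      num_mean / sqrt(v / n + (v == 0))
    }
  }
  thr <- qt(1 - cluster_alpha / 2, df = n - 1)

  find_clusters <- function(tv) {
    above <- abs(tv) > thr & is.finite(tv)
    sgn <- sign(tv)
    out <- list()
    i <- 1
    while (i <= length(tv)) {
      if (above[i]) {
        j <- i
        while (j < length(tv) && above[j + 1] && sgn[j + 1] == sgn[i]) j <- j + 1
        out[[length(out) + 1]] <- c(start = i, end = j,
                                    mass = sum(tv[i:j]))
        i <- j + 1
      } else i <- i + 1
    }
    out
  }

  t_obs <- tstat(colMeans(diffs))
  obs_clusters <- find_clusters(t_obs)

  set.seed(as.integer(seed))
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_means <- (flips %*% diffs) / n
  perm_t <- tstat(perm_means)
  null_max <- vapply(seq_len(n_perm), function(p) {
    cl <- find_clusters(perm_t[p, ])
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }, numeric(1))

  clusters <- if (length(obs_clusters)) {
    do.call(rbind, lapply(obs_clusters, function(cl) {
      p <- (1 + sum(null_max >= abs(cl[["mass"]]))) / (n_perm + 1)
      data.frame(start = cl[["start"]], end = cl[["end"]],
                 start_ms = time_ms[cl[["start"]]], end_ms = time_ms[cl[["end"]]],
                 mass = cl[["mass"]], p = p, significant = p < alpha)
    }))
  } else data.frame(start = integer(0), end = integer(0),
                    start_ms = numeric(0), end_ms = numeric(0),
                    mass = numeric(0), p = numeric(0), significant = logical(0))

  sig <- rep(FALSE, nt)
  if (nrow(clusters)) {
    for (k in which(clusters$significant))
      sig[clusters$start[k]:clusters$end[k]] <- TRUE
  }
  structure(list(t = t_obs, clusters = clusters, sig_timepoints = sig,
                 n_perm = n_perm, cluster_alpha = cluster_alpha,
                 alpha = alpha, seed = as.integer(seed)),
            class = "cluster_test")
}
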