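# Synthetic benchmark generator and preprocessing utilities for the
# standard benchmark datasets.

#' Generate a Gaussian-mixture clustering benchmark
#'
#' Draws spherical-to-axis-aligned Gaussian clusters at stated means and
#' per-dimension scales, optionally appends pure-noise dimensions that
#' carry no cluster signal (the scenario in which variance-based scaling
#' misleads distance-based clustering: a high-variance noise dimension
#' keeps unit weight under 1/sigma scaling and drowns the signal), and
#' optionally injects exact duplicate rows to exercise duplicate removal.
#'
#' @param n_per_cluster samples per cluster (scalar or one per cluster).
#' @param means cluster-by-dimension matrix of cluster centres; default
#'   three unit-scale clusters at (0,0), (5,0), (0,5), which k-means
#'   separates well at unit variance.
#' @param sds per-dimension standard deviations of each cluster (scalar,
#'   vector of length d, or cluster-by-dimension matrix); all > 0.
#' @param n_noise_dims number of appended signal-free dimensions.
#' @param noise_scale standard deviation of the noise dimensions.
#' @param duplicate_count exact duplicate rows to append (copies of
#'   randomly chosen rows, labels copied along).
#' @param seed reproducibility seed (ambient RNG if `NULL`).
#' @return list with `x` (matrix, signal dimensions first) and `labels`
#'   (integer reference partition).
#' @examples
#' m <- make_mixture(n_per_cluster = 20, seed = 1)
#' table(m$labels)
#' @export
make_mixture <- function(n_per_cluster = 50,
                         means = rbind(c(0, 0), c(5, 0), c(0, 5)),
                         sds = 1, n_noise_dims = 0, noise_scale = 1,
                         duplicate_count = 0, seed = NULL) {
  means <- as.matrix(means)
  K <- nrow(means)
  d_sig <- ncol(means)
  n_per_cluster <- rep_len(n_per_cluster, K)
  sds <- if (is.matrix(sds)) sds else matrix(rep_len(sds, d_sig), K, d_sig,
                                             byrow = TRUE)
  if (any(sds <= 0) || noise_scale <= 0) stop("all scales must be positive")
  n_total <- sum(n_per_cluster)
  if (n_total < 4L) stop("need at least 4 samples in total")
  with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(stats::rnorm(n_per_cluster[k] * d_sig,
                          mean = rep(means[k, ], each = n_per_cluster[k]),
                          sd = rep(sds[k, ], each = n_per_cluster[k])),
             nrow = n_per_cluster[k])
    }))
    labels <- rep(seq_len(K), n_per_cluster)
    if (n_noise_dims > 0) {
      noise <- matrix(stats::rnorm(n_total * n_noise_dims, 0, noise_scale),
                      nrow = n_total)
      x <- cbind(x, noise)
    }
    if (duplicate_count > 0) {
      idx <- sample.int(n_total, duplicate_count, replace = TRUE)
      x <- rbind(x, x[idx, , drop = FALSE])
      labels <- c(labels, labels[idx])
    }
    colnames(x) <- c(paste0("V", seq_len(d_sig)),
                     if (n_noise_dims > 0) paste0("noise", seq_len(n_noise_dims)))
    list(x = x, labels = labels)
  })
}

#' The corrected Iris data
#'
#' The Iris table as distributed by the UCI repository differs from the
#' original publication in two samples; the corrected form has sample 35
#' equal to (4.9, 3.1, 1.5, 0.2) and sample 38 equal to
#' (4.9, 3.6, 1.4, 0.1).  R's built-in [datasets::iris] already carries
#' these values, so the default is returned as-is after verification;
#' a raw UCI-style matrix is corrected in place.  The corrected table has
#' one duplicated row (samples 102 and 143), hence 149 unique samples.
#'
#' @param raw optional 150 x 4 numeric matrix to verify/correct; default
#'   uses the built-in Iris measurements.
#' @return list with `x` (150 x 4 corrected matrix) and `labels` (the
#'   three species as integers 1:3; `NULL` when `raw` was supplied).
#' @export
corrected_iris <- function(raw = NULL) {
  labels <- NULL
  if (is.null(raw)) {
    raw <- as.matrix(datasets::iris[, 1:4])
    labels <- as.integer(datasets::iris$Species)
  } else {
    raw <- as.matrix(raw)
  }
  if (!all(dim(raw) == c(150L, 4L)))
    stop("expected the standard 150 x 4 Iris table")
  uci <- c(4.9, 3.1, 1.5, 0.1)  # both flawed rows read like this at UCI
  fixes <- list(`35` = c(4.9, 3.1, 1.5, 0.2),
                `38` = c(4.9, 3.6, 1.4, 0.1))
  for (rn in names(fixes)) {
    i <- as.integer(rn)
    if (isTRUE(all.equal(unname(raw[i, ]), uci, tolerance = 1e-8))) {
      raw[i, ] <- fixes[[rn]]
    } else if (!isTRUE(all.equal(unname(raw[i, ]), fixes[[rn]],
                                 tolerance = 1e-8))) {
      warning("row ", i, " matches neither the UCI nor the corrected values; left unchanged")
    }
  }
  list(x = raw, labels = labels)
}

#' Reduce to the first three principal components
#'
#' Centered (but not scaled) principal component analysis, keeping the
#' first `ncomp` component scores — the "DR3" preprocessing used on the
#' wide benchmarks.  Component signs follow a fixed convention (the
#' loading of largest magnitude is made positive) so results do not
#' depend on the underlying eigensolver's sign choices.
#'
#' @param x numeric matrix with at least `ncomp` columns.
#' @param ncomp number of components to keep (default 3).
#' @return score matrix (n x ncomp) with attribute `variance_retained`,
#'   the fraction of total variance kept.
#' @export
dr3_reduce <- function(x, ncomp = 3) {
  x <- as.matrix(x)
  if (ncol(x) < ncomp) stop("need at least ", ncomp, " columns")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(p$sdev > 1e-12 * p$sdev[1]) < ncomp)
    stop("data rank below ", ncomp, "; cannot keep ", ncomp, " components")
  keep <- seq_len(ncomp)
  flip <- vapply(keep, function(j) {
    v <- p$rotation[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  scores <- sweep(p$x[, keep, drop = FALSE], 2L, flip, "*")
  attr(scores, "variance_retained") <- sum(p$sdev[keep]^2) / sum(p$sdev^2)
  scores
}

#' Keep the first ten mean-value dimensions
#'
#' The diagnostic breast-cancer table carries 30 image statistics per
#' sample: 10 means, 10 standard errors, 10 worst values.  This keeps the
#' 10 mean-value columns (the first ten), unchanged and in order.
#'
#' @param x numeric matrix with exactly 30 columns.
#' @return the n x 10 matrix of the first ten columns.
#' @export
truncate_means_10 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 30L) stop("expected 30 columns, got ", ncol(x))
  x[, 1:10, drop = FALSE]
}

#' Column-mean imputation that never creates duplicates
#'
#' Replaces each missing value by its column mean — a deliberately simple,
#' documented stand-in for the proprietary model-based synthesis used on
#' the original benchmarks.  If imputation makes a row collide with
#' another row, a tiny deterministic jitter (multiples of 1e-9) is added
#' to the row's first imputed cell and a message is logged, so downstream
#' duplicate removal only ever discards genuine duplicates.
#'
#' @param x numeric matrix, possibly with `NA`s.
#' @return the imputed matrix.
#' @export
simple_impute <- function(x) {
  x <- as.matrix(x)
  if (!anyNA(x)) return(x)
  imputed <- is.na(x)
  for (k in seq_len(ncol(x))) {
    miss <- imputed[, k]
    if (all(miss)) stop("column ", k, " is entirely missing")
    if (any(miss)) x[miss, k] <- mean(x[!miss, k])
  }
  for (pass in 1:5) {
    dup <- duplicated(x) | duplicated(x, fromLast = TRUE)
    collide <- which(dup & rowSums(imputed) > 0)
    collide <- collide[duplicated(x)[collide]]  # jitter later copies only
    if (length(collide) == 0L) break
    for (i in collide) {
      k <- which(imputed[i, ])[1L]
      x[i, k] <- x[i, k] + i * 1e-9
      message("simple_impute: jittered row ", i,
              " by ", i * 1e-9, " to break a duplicate collision")
    }
  }
  x
}
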