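# End-to-end workflow: scaling schemes, k-means clustering, evaluation
# against a reference partition, trial sweeps, distance histograms.

#' Apply a scaling scheme to a data matrix
#'
#' Three schemes: `"none"` leaves the matrix untouched; `"inv_sigma"`
#' divides each column by its standard deviation (the workhorse of
#' pre-clustering scaling); `"alpha_over_sigma"` multiplies column k by
#' \eqn{\alpha_k/\sigma_k}, the shape-complexity scheme.  All rows are
#' scaled (duplicates included — clustering and evaluation use the full
#' sample); sigma always comes from the full sample.
#'
#' @param x matrix or [sc_data()] object.
#' @param scheme one of `"none"`, `"inv_sigma"`, `"alpha_over_sigma"`.
#' @param alpha scaling factors, required iff `scheme` is
#'   `"alpha_over_sigma"`.
#' @return the scaled n_orig x d matrix.
#' @export
apply_scaling <- function(x, scheme = c("none", "inv_sigma", "alpha_over_sigma"),
                          alpha = NULL) {
  scheme <- match.arg(scheme)
  data <- sc_data(x)
  fac <- switch(scheme,
    none = rep(1, data$d),
    inv_sigma = 1 / data$sigma,
    alpha_over_sigma = {
      if (is.null(alpha)) stop("'alpha' is required for the alpha_over_sigma scheme")
      check_alpha(alpha, data$d) / data$sigma
    })
  sweep(data$values, 2L, fac, "*")
}

#' Restart-stabilized k-means with the fixed-cluster-count guarantee
#'
#' Runs [stats::kmeans()] (Hartigan–Wong) with `restarts` random starts
#' and verifies that the returned partition has exactly C non-empty
#' clusters — the premise of the fixed-number-of-clusters evaluation
#' null.  On an empty cluster (or a degenerate-start error) it redraws up
#' to 10 times before giving up.  When `seed` is given the caller's RNG
#' state is left untouched.
#'
#' @param x numeric matrix of (scaled) samples.
#' @param C desired number of clusters (>= 2).
#' @param seed optional seed; `NULL` uses the ambient RNG stream.
#' @param restarts number of random starts (`nstart`); 1 reproduces a
#'   single-run protocol, the default 20 stabilizes the optimum.
#' @param iter_max Lloyd/Hartigan–Wong iteration cap per start.
#' @return integer vector of cluster labels (1..C).
#' @export
cluster_kmeans <- function(x, C, seed = NULL, restarts = 20, iter_max = 100) {
  x <- as.matrix(x)
  if (C < 2L) stop("'C' must be at least 2")
  if (C > nrow(x)) stop("more clusters than samples")
  with_seed(seed, {
    for (attempt in 1:10) {
      cl <- tryCatch(
        stats::kmeans(x, centers = C, nstart = restarts,
                      iter.max = iter_max)$cluster,
        error = function(e) NULL)
      if (!is.null(cl) && length(unique(cl)) == C) return(cl)
    }
    stop("k-means failed to produce ", C,
         " non-empty clusters in 10 attempts")
  })
}

#' Evaluate an obtained partition against a reference
#'
#' Convenience wrapper returning both chance-corrected indices.
#'
#' @param obtained,reference label vectors of equal length.
#' @param C number of clusters of the evaluation null; defaults to the
#'   number of clusters in the obtained partition.
#' @return named vector `c(ari_fnc = , ami_max = )`.
#' @export
evaluate_run <- function(obtained, reference, C = NULL) {
  pp <- partition_pair(reference, obtained)
  c(ari_fnc = ari_fnc(pp, C = C), ami_max = ami_max(pp))
}

#' Sweep scaling-factor trials through clustering and evaluation
#'
#' The full benchmark loop: fit scaling factors by multi-start
#' optimization ([sc_fit()]), then for every converged trial scale the
#' data by \eqn{\alpha_k/\sigma_k}, cluster with k-means, and score the
#' partition against the reference with [ari_fnc()] and [ami_max()].
#' The observed index ranges over trials summarize how much the choice
#' among candidate scaling schemes matters; the best trial's alpha is the
#' natural candidate to inspect first.
#'
#' @inheritParams sc_fit
#' @param reference reference labeling of all n_orig samples.
#' @param C number of clusters (as in the reference partition).
#' @param restarts k-means restarts per trial.
#' @return an object of class `"sc_sweep"`: `fit` (the underlying
#'   `sc_fit`), `table` (per-trial data frame: alphas, objective, sc,
#'   converged, ari_fnc, ami_max), `C`, `best_alpha` (trial with the
#'   highest ARI_fnc), `ari_range`, `ami_range`, `discard_fraction`.
#' @export
trial_sweep <- function(x, reference, C, n_trials = 1000, seed = NULL,
                        mode = c("problem_p", "max_sc"),
                        control = sc_control(), restarts = 20) {
  mode <- match.arg(mode)
  reference <- as_labels(reference)
  fit <- sc_fit(x, n_trials = n_trials, seed = seed, mode = mode,
                control = control)
  if (length(reference) != fit$data$n_orig)
    stop("'reference' must label all ", fit$data$n_orig, " samples")
  df <- as.data.frame(fit$trials)
  km_seeds <- if (is.null(seed)) rep(list(NULL), nrow(df))
              else lapply(df$trial_id, function(i) derive_seed(seed, i))
  df$ari_fnc <- NA_real_
  df$ami_max <- NA_real_
  for (i in which(df$converged)) {
    a <- unlist(df[i, paste0("alpha_", seq_len(fit$data$d))])
    y <- apply_scaling(fit$data, "alpha_over_sigma", alpha = a)
    cl <- cluster_kmeans(y, C, seed = km_seeds[[i]], restarts = restarts)
    ev <- evaluate_run(cl, reference, C = C)
    df$ari_fnc[i] <- ev[["ari_fnc"]]
    df$ami_max[i] <- ev[["ami_max"]]
  }
  conv <- df[df$converged, , drop = FALSE]
  best <- conv[which.max(conv$ari_fnc), ]
  structure(
    list(fit = fit, table = df, C = C,
         best_alpha = unlist(best[paste0("alpha_", seq_len(fit$data$d))]),
         ari_range = range(conv$ari_fnc),
         ami_range = range(conv$ami_max),
         discard_fraction = fit$trials$discard_fraction),
    class = "sc_sweep")
}

#' @export
print.sc_sweep <- function(x, ...) {
  cat(sprintf("sc_sweep: %d trials (%s), C = %d, %.1f%% discarded\n",
              nrow(x$table), x$fit$mode, x$C, 100 * x$discard_fraction))
  cat(sprintf("  ARI_fnc in [%.3f, %.3f];  AMI_max in [%.3f, %.3f]\n",
              x$ari_range[1], x$ari_range[2],
              x$ami_range[1], x$ami_range[2]))
  cat("  best-trial alpha:", format(x$best_alpha, digits = 4), "\n")
  invisible(x)
}

#' Plot a trial sweep
#'
#' Two panels: shape complexity against the first scaling factor, trials
#' shaded by their ARI_fnc; and the histogram of ARI_fnc over all
#' converged trials.  A histogram peaking well left of the maximum warns
#' that consensus among trials would pick a poor scheme.
#'
#' @param x an `"sc_sweep"`.
#' @param ... unused.
#' @export
plot.sc_sweep <- function(x, ...) {
  df <- x$table[x$table$converged, , drop = FALSE]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  shade <- grDevices::gray(1 - (df$ari_fnc - min(df$ari_fnc)) /
                             max(diff(range(df$ari_fnc)), 1e-12))
  graphics::plot(df$alpha_1, df$sc, col = shade, pch = 16,
                 xlab = expression(alpha[1]), ylab = "SC")
  graphics::hist(df$ari_fnc, main = "", xlab = expression(ARI[fnc]))
  invisible(x)
}

#' Histogram of all unique-pair distances
#'
#' Bins the Euclidean distances between all pairs of rows of a (scaled)
#' matrix.  Use a common `breaks` vector (or `binwidth`) across scaling
#' schemes to make their histograms directly comparable; scaling the
#' matrix uniformly by t scales every distance by exactly t.
#'
#' @param x numeric matrix.
#' @param binwidth fixed bin width (default: range/30).
#' @param breaks explicit break points (overrides `binwidth`).
#' @return class `"distance_histogram"`: `counts`, `mids`, `breaks`,
#'   `n_pairs` and the raw `distances`.
#' @export
distance_histogram <- function(x, binwidth = NULL, breaks = NULL) {
  r <- as.vector(stats::dist(as.matrix(x)))
  if (is.null(breaks)) {
    if (is.null(binwidth)) binwidth <- max(r) / 30
    breaks <- seq(0, max(r) + binwidth, by = binwidth)
  }
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  structure(list(counts = h$counts, mids = h$mids, breaks = h$breaks,
                 n_pairs = length(r), distances = r),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("distance_histogram: %d pair distances in [%.4g, %.4g], %d bins\n",
              x$n_pairs, min(x$distances), max(x$distances),
              length(x$counts)))
  invisible(x)
}

#' @export
plot.distance_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", lwd = 3,
                 xlab = expression(r[ij]), ylab = "pair count", ...)
  invisible(x)
}

#' Read a delimited numeric data matrix
#'
#' @param path CSV/TSV/whitespace-delimited file, one row per sample.
#' @param header logical; does the first line carry column names?
#' @param sep field separator (`""` = any whitespace).
#' @return numeric matrix.
#' @export
read_data_matrix <- function(path, header = FALSE, sep = ",") {
  as.matrix(utils::read.table(path, header = header, sep = sep))
}
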