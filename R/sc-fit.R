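#' Fit shape-complexity scaling factors
#'
#' The main fitting function: runs a multi-start sequence of local solves
#' of the scaling-factor program — Problem P (minimize the squared
#' orthogonality residual on the sphere \eqn{\sum_k \alpha_k^2 = d} with
#' \eqn{\alpha_k \ge 10^{-5}}) or its max-SC alternative (maximize SC in
#' the box) — and keeps the best converged trial: the lowest objective for
#' Problem P, the highest shape complexity for max-SC.
#'
#' Every converged trial is a \emph{candidate} scaling scheme; the point of
#' the method is to sift candidates with knowledge of the data (or a
#' reference partition, see [trial_sweep()]), not to trust a single global
#' optimum.  The full trial set is retained in the fitted object.
#'
#' @param x numeric matrix (samples by dimensions) or [sc_data()] object.
#' @param n_trials number of random restarts.
#' @param seed master seed for reproducibility.
#' @param mode `"problem_p"` (default) or `"max_sc"`.
#' @param control solver settings, see [sc_control()].
#' @return an object of class `"sc_fit"` with components `data`
#'   (`sc_data`), `trials` (`sc_trials`), `best` (best converged
#'   `sc_trial`), `alpha` (its scaling factors) and `mode`.  Methods:
#'   [coef.sc_fit()] (best alpha), [predict.sc_fit()] (scale a matrix by
#'   alpha_k/sigma_k), `print`, `summary`, [plot.sc_fit()].
#' @examples
#' m <- make_mixture(n_per_cluster = 15, seed = 42)
#' fit <- sc_fit(m$x, n_trials = 5, seed = 1)
#' coef(fit)
#' @export
sc_fit <- function(x, n_trials = 1000, seed = NULL,
                   mode = c("problem_p", "max_sc"),
                   control = sc_control()) {
  data <- sc_data(x)
  mode <- match.arg(mode)
  trials <- run_trials(data, n_trials, seed, mode, control)
  conv <- Filter(function(t) isTRUE(t$converged), trials$trials)
  if (length(conv) == 0L)
    stop("no trial converged; increase max_iterations or n_trials")
  obj <- vapply(conv, `[[`, numeric(1), "objective")
  best <- conv[[if (mode == "problem_p") which.min(obj) else which.max(obj)]]
  structure(
    list(data = data, trials = trials, best = best, alpha = best$alpha,
         mode = mode, control = control, call = match.call()),
    class = "sc_fit")
}

#' @rdname sc_fit
#' @param object,... method arguments.
#' @export
coef.sc_fit <- function(object, ...) object$alpha

#' Scale data by the fitted factors
#'
#' Applies the fitted scaling \eqn{\alpha_k/\sigma_k} column-wise, where
#' sigma is taken from the data the model was fitted to (so new samples
#' are scaled consistently with the training matrix).
#'
#' @param object an `"sc_fit"`.
#' @param newdata matrix to scale; defaults to the fitted data.
#' @param ... unused.
#' @return the scaled matrix.
#' @export
predict.sc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$data$d)
    stop("'newdata' must have ", object$data$d, " columns")
  sweep(newdata, 2L, object$alpha / object$data$sigma, "*")
}

#' @export
print.sc_fit <- function(x, ...) {
  cat(sprintf("Shape-complexity scaling fit (%s)\n", x$mode))
  cat(sprintf("  %d trials, %.1f%% discarded\n", x$trials$n_trials,
              100 * x$trials$discard_fraction))
  cat(sprintf("  best objective: %.6g (SC = %.6g)\n",
              x$best$objective, x$best$sc))
  cat("  alpha:", format(x$alpha, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.sc_fit <- function(object, ...) {
  df <- as.data.frame(object$trials)
  conv <- df[df$converged, , drop = FALSE]
  structure(
    list(mode = object$mode, n_trials = object$trials$n_trials,
         discard_fraction = object$trials$discard_fraction,
         objective_range = range(conv$objective),
         sc_range = range(conv$sc),
         alpha = object$alpha,
         inv_sigma = 1 / object$data$sigma,
         alpha_over_sigma = object$alpha / object$data$sigma),
    class = "summary.sc_fit")
}

#' @export
print.summary.sc_fit <- function(x, ...) {
  cat(sprintf("Shape-complexity scaling fit (%s): %d trials, %.1f%% discarded\n",
              x$mode, x$n_trials, 100 * x$discard_fraction))
  cat(sprintf("  objective range over converged trials: [%.4g, %.4g]\n",
              x$objective_range[1], x$objective_range[2]))
  cat(sprintf("  SC range: [%.6g, %.6g]\n", x$sc_range[1], x$sc_range[2]))
  tab <- rbind(`1/sigma_k` = x$inv_sigma, `alpha_k` = x$alpha,
               `alpha_k/sigma_k` = x$alpha_over_sigma)
  colnames(tab) <- paste0("k=", seq_along(x$alpha))
  print(round(tab, 4))
  invisible(x)
}

#' Plot a scaling-factor fit
#'
#' Scatter of the shape complexity attained by each converged trial
#' against its first scaling factor (the choice of dimension is arbitrary;
#' it offers a glimpse of the solution cloud's structure).
#'
#' @param x an `"sc_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sc_fit <- function(x, ...) {
  df <- as.data.frame(x$trials)
  df <- df[df$converged, , drop = FALSE]
  graphics::plot(df$alpha_1, df$sc, xlab = expression(alpha[1]),
                 ylab = "shape complexity", ...)
  invisible(x)
}
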