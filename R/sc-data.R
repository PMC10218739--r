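#' Assemble a data matrix for shape-complexity analysis
#'
#' Validates a numeric sample-by-dimension matrix and precomputes everything
#' the shape-complexity machinery needs: per-dimension standard deviations,
#' the indices of the duplicate-free rows, and the pair-count constant
#' \eqn{N = n_{orig}(n_{orig}-1)}.
#'
#' Duplicate rows must be set aside before pairwise quantities are formed
#' (a zero distance makes the sum of reciprocal distances diverge), but the
#' standard deviations are computed over \emph{all} rows, duplicates
#' included, so that the variance/pair-sum identity
#' \deqn{\sigma_k^2 = N^{-1} \sum_{i<j} (X_{ik}-X_{jk})^2}
#' holds on the full sample (sums over all unordered pairs of the original
#' rows; \code{sd()} denominator \eqn{n_{orig}-1}).  Consequently the
#' standardized pair sums equal \eqn{N} exactly only when the data are
#' duplicate-free.
#'
#' @param x a numeric matrix or data frame, one row per sample, one column
#'   per dimension.  At least 2 rows and 2 columns; no missing values
#'   (see [simple_impute()]); no constant columns.
#' @return an object of class `"sc_data"`: a list with elements `values`
#'   (the n_orig x d matrix), `n_orig`, `d`, `sigma` (length-d standard
#'   deviations), `unique_index` (row indices of the first occurrence of
#'   each distinct row), `n` (number of unique rows) and `N`.
#' @seealso [standardized_sq_diffs()], [shape_complexity()], [sc_fit()]
#' @examples
#' d <- sc_data(rbind(c(0, 1), c(1, 0), c(2, 2), c(2, 2)))
#' d$n_orig  # 4
#' d$n       # 3: one duplicate row
#' @export
sc_data <- function(x) {
  if (inherits(x, "sc_data")) return(x)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (anyNA(x) || any(!is.finite(x)))
    stop("'x' contains missing or non-finite values; impute first (see simple_impute())")
  n_orig <- nrow(x)
  d <- ncol(x)
  if (n_orig < 2L) stop("need at least 2 samples")
  if (d < 2L) stop("need at least 2 dimensions")
  unique_index <- which(!duplicated(x))
  if (length(unique_index) < 2L)
    stop("fewer than 2 unique samples after duplicate removal")
  sigma <- apply(x, 2L, stats::sd)
  if (any(sigma <= 0)) {
    bad <- which(sigma <= 0)
    stop("dimension(s) ", paste(bad, collapse = ", "),
         " are constant (zero standard deviation); drop them before scaling")
  }
  structure(
    list(values = x, n_orig = n_orig, d = d, sigma = sigma,
         unique_index = unique_index, n = length(unique_index),
         N = n_orig * (n_orig - 1)),
    class = "sc_data")
}

#' Remove duplicate rows for pairwise computations
#'
#' Identifies exact duplicate rows and records the duplicate-free subset,
#' keeping the original matrix (and its standard deviations) intact:
#' clustering and partition evaluation use all rows, while shape complexity
#' and its optimization use only the unique rows.
#'
#' @inheritParams sc_data
#' @return an `"sc_data"` object (this is the same constructor as
#'   [sc_data()]; the name mirrors the pipeline step).
#' @export
dedup <- function(x) sc_data(x)

#' @export
print.sc_data <- function(x, ...) {
  cat(sprintf("sc_data: %d samples (%d unique) x %d dimensions\n",
              x$n_orig, x$n, x$d))
  cat("sigma:", format(x$sigma, digits = 4), "\n")
  invisible(x)
}
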