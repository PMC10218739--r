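# Shape-complexity core: standardized pair differences, scaled distances,
# SC = g*h and its analytic gradient.

#' Standardized squared pair differences
#'
#' Computes \eqn{\rho^2_{ijk} = ((X_{ik}-X_{jk})/\sigma_k)^2} for every
#' unordered pair (i < j) of \emph{unique} rows and every dimension k.
#' Standard deviations come from all rows (see [sc_data()]); on
#' duplicate-free data each column of the result sums to
#' \eqn{N = n_{orig}(n_{orig}-1)}.
#'
#' @param data an [sc_data()] object, or anything coercible by it.
#' @return a `choose(n, 2)` x d matrix, pairs in lexicographic (i < j)
#'   order, with attributes `N`, `n` and `d`.  Memory is O(n^2 d), the
#'   practical scalability limit of the whole approach.
#' @export
standardized_sq_diffs <- function(data) {
  data <- sc_data(data)
  u <- data$values[data$unique_index, , drop = FALSE]
  npair <- data$n * (data$n - 1) / 2
  rho2 <- matrix(vapply(seq_len(data$d),
                        function(k) as.vector(stats::dist(u[, k] / data$sigma[k]))^2,
                        numeric(npair)),
                 nrow = npair, ncol = data$d)
  attr(rho2, "N") <- data$N
  attr(rho2, "n") <- data$n
  attr(rho2, "d") <- data$d
  rho2
}

# Accept either a precomputed rho2 matrix or data coercible to sc_data.
as_rho2 <- function(x) {
  if (is.matrix(x) && is.null(attr(x, "class")) && !is.null(attr(x, "N")))
    return(x)
  if (inherits(x, "sc_data") || is.data.frame(x) ||
      (is.matrix(x) && is.null(attr(x, "N"))))
    return(standardized_sq_diffs(x))
  x
}

#' Scaled pairwise distances
#'
#' \eqn{r_{ij} = (\sum_k \alpha_k^2 \rho^2_{ijk})^{1/2}}: the Euclidean
#' distance between rows after each dimension is scaled by
#' \eqn{\alpha_k/\sigma_k}.  With all-ones `alpha` this is the distance
#' between 1/sigma-standardized rows; multiplying `alpha` by t multiplies
#' every distance by t.
#'
#' @param rho2 matrix from [standardized_sq_diffs()] (or data coercible to
#'   it).
#' @param alpha positive scaling factors, one per dimension.
#' @return vector of strictly positive pair distances, same pair order as
#'   `rho2`.
#' @export
pair_distances <- function(rho2, alpha) {
  rho2 <- as_rho2(rho2)
  alpha <- check_alpha(alpha, ncol(rho2))
  r <- sqrt(drop(rho2 %*% alpha^2))
  if (any(r == 0))
    stop("zero pair distance encountered: remove duplicate rows first (sc_data() does this)")
  r
}

#' Shape complexity of scaled data
#'
#' \eqn{SC = g h} with \eqn{g = (\sum_{i<j} r_{ij}^2)^{1/2}} (root sum of
#' squared pair distances) and \eqn{h = \sum_{i<j} r_{ij}^{-1}} (sum of
#' reciprocal pair distances).  Increasing any distance increases g and
#' decreases h, the tension that makes SC stationary points interesting:
#' g responds most to the largest distances, h to the smallest.  SC is
#' radially invariant: SC(t alpha) = SC(alpha) for any t > 0.
#'
#' @inheritParams pair_distances
#' @return list with elements `sc`, `g`, `h`.
#' @examples
#' m <- make_mixture(n_per_cluster = 10, seed = 1)
#' shape_complexity(sc_data(m$x), rep(1, ncol(m$x)))$sc
#' @export
shape_complexity <- function(rho2, alpha) {
  r <- pair_distances(rho2, alpha)
  g <- sqrt(sum(r * r))
  h <- sum(1 / r)
  list(sc = g * h, g = g, h = h)
}

#' Gradient of shape complexity in the scaling factors
#'
#' Analytic gradient \eqn{SC'_k = g'_k h + g h'_k} with
#' \eqn{g'_k = \alpha_k g^{-1} \sum_{i<j} \rho^2_{ijk}} and
#' \eqn{h'_k = -\alpha_k \sum_{i<j} r_{ij}^{-3} \rho^2_{ijk}}.
#' Radial invariance shows up as the directional-derivative identity
#' \eqn{\sum_k \alpha_k SC'_k = 0}.
#'
#' @inheritParams pair_distances
#' @return list with `grad` (length-d SC gradient), `gk`, `hk` (gradients
#'   of g and h), and the scalars `sc`, `g`, `h`.
#' @export
sc_gradient <- function(rho2, alpha) {
  rho2 <- as_rho2(rho2)
  d <- ncol(rho2)
  alpha <- check_alpha(alpha, d)
  r <- pair_distances(rho2, alpha)
  g <- sqrt(sum(r * r))
  h <- sum(1 / r)
  gk <- alpha / g * colSums(rho2)
  hk <- -alpha * drop(crossprod(rho2, r^-3))
  list(grad = gk * h + g * hk, gk = gk, hk = hk, sc = g * h, g = g, h = h)
}

#' Closed form for the root-sum-square of pair distances
#'
#' On duplicate-free data the standardized pair sums collapse to N per
#' dimension, so \eqn{g = (N \sum_k \alpha_k^2)^{1/2}} without touching the
#' pairs at all.  On the constraint sphere \eqn{\sum_k \alpha_k^2 = d}
#' this is \eqn{(N d)^{1/2}}.
#'
#' @param data an [sc_data()] object (must be duplicate-free, i.e.
#'   `n == n_orig`, for the identity to hold exactly).
#' @param alpha positive scaling factors.
#' @return the scalar g.
#' @export
g_closed_form <- function(data, alpha) {
  data <- sc_data(data)
  alpha <- check_alpha(alpha, data$d)
  if (data$n != data$n_orig)
    warning("data contain duplicate rows; the closed form for g is exact only on duplicate-free data")
  sqrt(data$N * sum(alpha^2))
}
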