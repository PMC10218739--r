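# Chance-corrected external partition indices: the adjusted Rand index
# under the fixed-number-of-clusters null (Stirling-number expectation)
# and adjusted mutual information normalized by the maximum entropy.

#' Pair a reference and an obtained partition
#'
#' Builds the contingency table of the two labelings and the four pair
#' categories: TS ("true similar", pairs co-clustered in both), TD ("true
#' dissimilar", split in both), FD ("false dissimilar", together in the
#' reference but split in the obtained) and FS (the remaining category).
#' They always satisfy TS + TD + FD + FS = choose(n, 2).
#'
#' @param reference,obtained label vectors of equal length (integers,
#'   factors, or anything coercible); cluster ids are arbitrary.
#' @return an object of class `"partition_pair"`: `contingency`, `n`, `C`
#'   (number of clusters in the obtained partition), `pair_counts`
#'   (named TS/TD/FD/FS).
#' @export
partition_pair <- function(reference, obtained) {
  reference <- as_labels(reference)
  obtained <- as_labels(obtained)
  if (length(reference) != length(obtained))
    stop("'reference' and 'obtained' must have the same length")
  n <- length(reference)
  ct <- table(reference, obtained)
  TS <- sum(choose(ct, 2))
  FD <- sum(choose(rowSums(ct), 2)) - TS
  FS <- sum(choose(colSums(ct), 2)) - TS
  TD <- choose(n, 2) - TS - FD - FS
  structure(
    list(reference = reference, obtained = obtained, n = n,
         contingency = ct, C = ncol(ct),
         pair_counts = c(TS = TS, TD = TD, FD = FD, FS = FS)),
    class = "partition_pair")
}

as_partition_pair <- function(reference, obtained = NULL) {
  if (inherits(reference, "partition_pair")) return(reference)
  if (is.null(obtained)) stop("supply an 'obtained' labeling")
  partition_pair(reference, obtained)
}

#' @rdname partition_pair
#' @param pp a `"partition_pair"`.
#' @export
pair_counts <- function(pp) as_partition_pair(pp)$pair_counts

#' Rand index
#'
#' Fraction of sample pairs on which the two partitions agree:
#' \eqn{RI = (TS + TD) / \binom{n}{2}}.
#'
#' @param reference a `"partition_pair"` or a reference labeling.
#' @param obtained obtained labeling (ignored if `reference` is already a
#'   pair).
#' @return a number in [0, 1].
#' @export
rand_index <- function(reference, obtained = NULL) {
  pp <- as_partition_pair(reference, obtained)
  unname((pp$pair_counts["TS"] + pp$pair_counts["TD"]) / choose(pp$n, 2))
}

## ---- exact big integers (base 1e7 digit vectors, little-endian) ----
## Needed for Stirling numbers of the second kind far beyond double
## precision; only addition and multiplication by a small integer are
## required by the recurrence S(n, C) = C S(n-1, C) + S(n-1, C-1).

big_norm <- function(v) {
  repeat {
    carry <- v %/% 1e7
    if (!any(carry > 0)) break
    v <- v - carry * 1e7
    v <- c(v, 0)[seq_len(length(v) + 1L)] + c(0, carry)
  }
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  v
}

big_add <- function(a, b) {
  L <- max(length(a), length(b))
  big_norm(c(a, rep(0, L - length(a))) + c(b, rep(0, L - length(b))))
}

big_smul <- function(a, k) {
  stopifnot(k >= 0, k < 9e8)  # digit * k must stay exactly representable
  big_norm(a * k)
}

big_log <- function(v) {
  L <- length(v)
  mant <- v[L]
  if (L > 1L) mant <- mant + v[L - 1L] / 1e7
  if (L > 2L) mant <- mant + v[L - 2L] / 1e14
  log(mant) + (L - 1L) * log(1e7)
}

big_to_string <- function(v) {
  s <- paste0(sprintf("%07.0f", rev(v[-length(v)])), collapse = "")
  paste0(sprintf("%.0f", v[length(v)]), s)
}

# Exact S(m, j) rows for m = 1..n, j = 1..C; returns list with the last
# two rows (each a list of digit vectors), for ratio computations.
stirling_rows <- function(n, C) {
  row <- c(list(c(1)), rep(list(c(0)), C - 1L))  # m = 1
  prev <- NULL
  if (n >= 2L) for (m in 2:n) {
    prev <- row
    row <- vector("list", C)
    row[[1L]] <- c(1)
    if (C >= 2L) for (j in 2:C) {
      row[[j]] <- big_add(big_smul(prev[[j]], j), prev[[j - 1L]])
    }
  }
  list(last = row, prev = prev)
}

#' Stirling numbers of the second kind, exactly
#'
#' The number of ways to partition n labeled items into exactly C
#' non-empty blocks, computed with exact big-integer arithmetic via the
#' recurrence \eqn{S(n, C) = C\,S(n-1, C) + S(n-1, C-1)} (no floating
#' overflow even for n in the thousands).
#'
#' @param n number of items (n >= 1).
#' @param C number of blocks, 1 <= C <= n.
#' @return the exact value: numeric when it fits a double exactly
#'   (< 2^53), otherwise a decimal character string.
#' @examples
#' stirling2(4, 2)   # 7
#' stirling2(10, 3)  # 9330
#' @export
stirling2 <- function(n, C) {
  n <- as.integer(n); C <- as.integer(C)
  if (is.na(n) || is.na(C) || n < 1L || C < 1L || C > n)
    stop("need integers 1 <= C <= n")
  v <- stirling_rows(n, C)$last[[C]]
  if (length(v) <= 2L) {
    x <- sum(v * c(1, 1e7)[seq_along(v)])
    if (x < 2^53) return(x)
  }
  big_to_string(v)
}

# U = S(n-1, C) / S(n, C): probability that a fixed pair is co-clustered
# under a uniform random partition into exactly C non-empty blocks.
stirling_ratio <- function(n, C) {
  if (C == 1L) return(1)
  rows <- stirling_rows(n, C)
  exp(big_log(rows$prev[[C]]) - big_log(rows$last[[C]]))
}

#' Expected Rand index under the fixed-number-of-clusters null
#'
#' \eqn{E_{fnc}[RI] = UV + (1-U)(1-V)} with
#' \eqn{U = S(n-1, C)/S(n, C)} (the probability that a given pair is
#' co-clustered in a uniformly random partition into exactly C non-empty
#' blocks) and \eqn{V = (TS + FD)/\binom{n}{2}} (the fraction of pairs
#' co-clustered in the reference).  This is the exact mean of RI over all
#' equiprobable C-block obtained partitions.
#'
#' @inheritParams rand_index
#' @param C number of clusters of the null model; defaults to the number
#'   of clusters in the obtained partition.
#' @return the expected Rand index.
#' @export
expected_rand_fnc <- function(reference, obtained = NULL, C = NULL) {
  pp <- as_partition_pair(reference, obtained)
  if (is.null(C)) C <- pp$C
  U <- stirling_ratio(pp$n, as.integer(C))
  V <- unname((pp$pair_counts["TS"] + pp$pair_counts["FD"]) / choose(pp$n, 2))
  U * V + (1 - U) * (1 - V)
}

#' Adjusted Rand index for a fixed number of clusters
#'
#' \deqn{ARI_{fnc} = \frac{RI - E_{fnc}[RI]}{1 - E_{fnc}[RI]},}
#' the Rand index corrected for chance under the null that the obtained
#' partition is a uniformly random partition into exactly C non-empty
#' clusters — the null that matches k-means output, which always has
#' exactly C clusters.  At most 1, attained exactly when the partitions
#' are identical; negative when agreement is below the chance level.
#'
#' @inheritParams expected_rand_fnc
#' @return a number <= 1.
#' @export
ari_fnc <- function(reference, obtained = NULL, C = NULL) {
  pp <- as_partition_pair(reference, obtained)
  if (is.null(C)) C <- pp$C
  if (pp$C != C)
    stop("obtained partition has ", pp$C, " non-empty clusters, not C = ", C,
         " (the fixed-number-of-clusters premise)")
  E <- expected_rand_fnc(pp, C = C)
  if (1 - E < 1e-12)
    stop("expected Rand index equals 1; ARI_fnc is undefined here")
  (rand_index(pp) - E) / (1 - E)
}

#' Shannon entropies and mutual information of two partitions
#'
#' From the joint probabilities \eqn{p_{RO} = |R \cap O| / n} and their
#' marginals: \eqn{MI = H(R) + H(O) - H(R, O)}, with \eqn{0 \log 0 = 0}.
#' Natural logarithms throughout (the base cancels in [ami_max()]).
#'
#' @inheritParams rand_index
#' @return list with `H_R`, `H_O`, `H_RO`, `MI`.
#' @export
mutual_information <- function(reference, obtained = NULL) {
  pp <- as_partition_pair(reference, obtained)
  p <- pp$contingency / pp$n
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  H_R <- ent(rowSums(p)); H_O <- ent(colSums(p)); H_RO <- ent(as.vector(p))
  list(H_R = H_R, H_O = H_O, H_RO = H_RO,
       MI = max(H_R + H_O - H_RO, 0))
}

#' Expected mutual information under the permutation null
#'
#' The exact expectation of MI when the obtained labels are randomly
#' permuted with both partitions' cluster sizes held fixed: each
#' contingency cell count then follows a hypergeometric law, and the
#' expectation is the standard cell-wise sum over all feasible counts
#' (log-factorials via `lgamma` keep it stable for n in the thousands).
#'
#' @inheritParams rand_index
#' @return the expected mutual information (natural log units).
#' @export
expected_mi <- function(reference, obtained = NULL) {
  pp <- as_partition_pair(reference, obtained)
  n <- pp$n
  a <- rowSums(pp$contingency)
  b <- colSums(pp$contingency)
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (lo > hi) next
    nij <- lo:hi
    term <- nij / n * log(n * nij / (a[i] * b[j]))
    lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) +
      lgamma(n - a[i] + 1) + lgamma(n - b[j] + 1) - lgamma(n + 1) -
      lgamma(nij + 1) - lgamma(a[i] - nij + 1) - lgamma(b[j] - nij + 1) -
      lgamma(n - a[i] - b[j] + nij + 1)
    emi <- emi + sum(term * exp(lp))
  }
  emi
}

#' Adjusted mutual information, max-entropy normalization
#'
#' \deqn{AMI_{max} = \frac{MI - E[MI]}{\max\{H(R), H(O)\} - E[MI]},}
#' where E[MI] is the permutation-model expectation ([expected_mi()]).
#' At most 1, attained exactly for identical partitions; can be slightly
#' negative when MI falls below its chance level.  Invariant to the
#' logarithm base.
#'
#' @inheritParams rand_index
#' @return a number <= 1.
#' @export
ami_max <- function(reference, obtained = NULL) {
  pp <- as_partition_pair(reference, obtained)
  mi <- mutual_information(pp)
  emi <- expected_mi(pp)
  denom <- max(mi$H_R, mi$H_O) - emi
  if (abs(denom) < 1e-12)
    stop("max{H(R), H(O)} equals E[MI]; AMI_max is undefined here")
  (mi$MI - emi) / denom
}

#' @export
print.partition_pair <- function(x, ...) {
  cat(sprintf("partition_pair: n = %d, %d reference x %d obtained clusters\n",
              x$n, nrow(x$contingency), x$C))
  print(x$pair_counts)
  invisible(x)
}

#' @export
summary.partition_pair <- function(object, ...) {
  mi <- mutual_information(object)
  E <- expected_rand_fnc(object)
  emi <- expected_mi(object)
  out <- c(RI = rand_index(object), E_fnc_RI = E,
           ARI_fnc = ari_fnc(object),
           H_R = mi$H_R, H_O = mi$H_O, H_RO = mi$H_RO, MI = mi$MI,
           E_MI = emi, AMI_max = ami_max(object))
  class(out) <- "summary.partition_pair"
  out
}

#' @export
print.summary.partition_pair <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Read integer labels, one per line
#'
#' @param path text file with one integer label per line.
#' @return integer vector.
#' @export
read_labels <- function(path) {
  as.integer(scan(path, what = integer(), quiet = TRUE))
}
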