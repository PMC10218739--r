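# Independent oracles used across the suite: brute-force enumerations and
# direct-summation implementations kept deliberately separate from the
# package's code paths.

rand_data <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# Central finite differences.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Direct-summation shape complexity and Problem-P objective from the raw
# matrix: explicit loops over pairs of unique rows, sigma over all rows.
brute_sc_parts <- function(X, alpha) {
  sig <- apply(X, 2, sd)
  U <- X[!duplicated(X), , drop = FALSE]
  n <- nrow(U)
  r <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- c(r, sqrt(sum(alpha^2 * ((U[i, ] - U[j, ]) / sig)^2)))
  }
  list(g = sqrt(sum(r^2)), h = sum(1 / r), sc = sqrt(sum(r^2)) * sum(1 / r),
       r = r)
}

brute_objective_p <- function(X, alpha) {
  sig <- apply(X, 2, sd)
  N <- nrow(X) * (nrow(X) - 1)
  U <- X[!duplicated(X), , drop = FALSE]
  n <- nrow(U)
  acc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rho2 <- ((U[i, ] - U[j, ]) / sig)^2
    r <- sqrt(sum(alpha^2 * rho2))
    acc <- acc + r^-3 * (rho2[1] - rho2[2]) / N
  }
  acc^2
}

# Pair categories by explicit enumeration of all sample pairs.
brute_pair_counts <- function(ref, obt) {
  n <- length(ref)
  TS <- TD <- FD <- FS <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sr <- ref[i] == ref[j]
    so <- obt[i] == obt[j]
    if (sr && so) TS <- TS + 1
    else if (!sr && !so) TD <- TD + 1
    else if (sr && !so) FD <- FD + 1
    else FS <- FS + 1
  }
  c(TS = TS, TD = TD, FD = FD, FS = FS)
}

brute_rand_index <- function(ref, obt) {
  pc <- brute_pair_counts(ref, obt)
  (pc["TS"] + pc["TD"]) / choose(length(ref), 2)
}

# All partitions of n items into exactly C non-empty blocks, as label
# vectors (restricted growth strings).
enum_set_partitions <- function(n, C) {
  res <- list()
  rec <- function(labels, maxl) {
    i <- length(labels) + 1L
    if (i > n) {
      if (maxl == C) res[[length(res) + 1L]] <<- labels
      return(invisible(NULL))
    }
    if (maxl + (n - i + 1L) < C) return(invisible(NULL))
    for (l in seq_len(min(maxl + 1L, C))) rec(c(labels, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  res
}

# All permutations of a vector (tiny n only).
enum_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in enum_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Plug-in mutual information with explicit loops over cluster ids.
mi_plugin <- function(ref, obt) {
  n <- length(ref)
  mi <- 0
  for (a in unique(ref)) for (b in unique(obt)) {
    pab <- sum(ref == a & obt == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (sum(ref == a) / n * sum(obt == b) / n))
  }
  mi
}

entropy_plugin <- function(lab) {
  p <- table(lab) / length(lab)
  -sum(p * log(p))
}

# Random labeling with exactly C non-empty clusters.
rand_labels <- function(n, C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    l <- sample.int(C, n, replace = TRUE)
    if (length(unique(l)) == C) return(l)
  }
}
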