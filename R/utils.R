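# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# .Random.seed afterwards.  seed = NULL means "use the ambient stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Derive a secondary 31-bit seed from a master seed, for independent
# substreams (e.g. the k-means stream of a sweep).  NULL passes through.
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + salt) %% 2147483647) + 1L
}

check_alpha <- function(alpha, d, min = 0) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != d)
    stop("'alpha' must have length ", d, " (one factor per dimension)")
  if (anyNA(alpha) || any(!is.finite(alpha)))
    stop("'alpha' must be finite")
  if (any(alpha <= min))
    stop("scaling factors must be positive (> ", min, ")")
  alpha
}

# Coerce a labeling to consecutive integers starting at 1.
as_labels <- function(x) {
  if (is.factor(x)) return(as.integer(x))
  x <- as.vector(x)
  as.integer(factor(x, levels = unique(x)))
}
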