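# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's RNG state. `seed = NULL` uses the current stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index; keeps independent
# streams for per-sample / per-individual simulations under one user seed.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 1103L + as.double(i) * 12347L) %% 2147483647
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# output files with a digest of the run configuration.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, kept exact in doubles
    # by splitting h into 16-bit halves (16777619 * 2^16 mod 2^32 = 1048576)
    h <- ((h %% 65536) * 16777619 + (h %/% 65536) * 1048576) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(x >= 0, n >= x)
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# Random DNA of length n from the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1]]),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.frame constructor without the checking overhead; used on hot paths
# where columns are known-valid equal-length vectors
quick_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}
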