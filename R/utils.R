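# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic operations in the package funnel through this so that a
# single integer seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a master seed and a stream index,
# kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  x <- (as.double(seed) %% m) + 1
  for (k in c(stream + 1, 48271)) {
    x <- (x * 16807 + k) %% m
  }
  as.integer(x)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
}

# Map per-chromosome coordinates onto a single concatenated axis so interval
# work can use one IRanges space. Returns named offset vector.
chrom_offsets <- function(chrom_sizes) {
  stop_if_missing_cols(chrom_sizes, c("chrom", "size"), "chrom_sizes")
  off <- cumsum(c(0, as.double(chrom_sizes$size[-nrow(chrom_sizes)])))
  setNames(off, chrom_sizes$chrom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
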