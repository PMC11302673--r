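# Internal helpers: seed derivation and small numeric utilities.

# Deterministic stream seed derived from a master seed and integer indices.
# Keeps every derived seed inside the 32-bit signed range.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- (as.double(master) * 48271) %% 2147483629
  for (k in seq_along(idx)) {
    s <- (s * 69621 + as.double(idx[k]) * 1013904223 + k) %% 2147483629
  }
  as.integer(s %% 2147483629 + 1)
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Row-wise median of a matrix with few columns, via a vectorised
# compare-exchange (bubble) network; avoids per-row apply() overhead.
row_medians_small <- function(m) {
  h <- ncol(m)
  if (h == 1L) return(m[, 1L])
  cols <- lapply(seq_len(h), function(j) m[, j])
  for (i in seq_len(h - 1L)) {
    for (j in seq_len(h - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo
      cols[[j + 1L]] <- hi
    }
  }
  if (h %% 2L == 1L) cols[[(h + 1L) %/% 2L]]
  else (cols[[h %/% 2L]] + cols[[h %/% 2L + 1L]]) / 2
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
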