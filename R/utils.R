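# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed < 2^31 from a base seed and small offsets.
derive_seed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed)
  for (o in off) s <- (s * 69069 + as.double(o) + 1) %% 2147483629
  as.integer(s)
}

geometric_mean <- function(x) exp(mean(log(x)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Runs of TRUE in a logical vector -> matrix with columns (start, end) index.
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values) & r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Concatenate GRanges without seqinfo merging chatter.
bind_gr <- function(...) {
  grs <- list(...)
  grs <- grs[vapply(grs, length, 0L) > 0]
  if (!length(grs)) return(GRanges())
  suppressWarnings(do.call(c, lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <-
      unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
    g
  })))
}

# Running mean that keeps vector length, using partial windows at the edges
# (symmetric, so it commutes with reversal).
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
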