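# Internal numeric and bookkeeping helpers (not exported).

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stream sub-seeds derived from one global seed.
# Kept strictly below 2^31 - 1 for any |seed| <= 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(hospitals = 11L, discharges = 23L, counts = 37L,
               bootstrap = 53L, replicate = 71L, calibrate = 89L,
               misc = 97L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (abs(as.integer(seed)) %% 1000003L) * 2039L + offsets[[stream]]
}

# log(1 + exp(x)) without overflow.
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x < 33
  out[big] <- x[big] + exp(-x[big])
  out
}

# Row-wise log-sum-exp of a matrix.
lse_rows <- function(m) {
  mx <- apply(m, 1, max)
  fin <- is.finite(mx)
  out <- mx
  out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  out
}

# Gauss-Hermite nodes/weights for integral of f(t) exp(-t^2), by
# Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    stopifnot(n >= 1)
    if (n == 1) {
      gh <- list(nodes = 0, weights = sqrt(pi))
    } else {
      i <- seq_len(n - 1)
      b <- sqrt(i / 2)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1)] <- b
      J[cbind(i + 1, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      idx <- order(e$values)
      gh <- list(nodes = e$values[idx],
                 weights = sqrt(pi) * e$vectors[1, idx]^2)
    }
    cache[[key]] <- gh
    gh
  }
})

# ICD-style code normalization: trim, uppercase, strip dots.
normalize_codes <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub(".", "", x, fixed = TRUE)
  x[nzchar(x)]
}

# Split a delimited code string ("4280;4281" or "4280 4281") into codes.
split_codes <- function(s) {
  s[is.na(s)] <- ""
  lapply(strsplit(s, "[;,[:space:]]+"), normalize_codes)
}

# Truncated-normal sampler via inverse CDF (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Per-group sums for an integer group index in 1..J (all groups present).
group_sum <- function(x, idx, J) {
  out <- numeric(J)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

stop_psival <- function(...) stop(..., call. = FALSE)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
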