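# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 100000) * 7919 + as.numeric(offset) * 131) %%
               2147483647)
}

# Truncated-normal draws by rejection with a clamping fallback.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

# 4-connected binary erosion/dilation applied slice-wise (2-D, in-plane) to a
# 3-D logical array. Voxels outside the grid count as background.
shift2 <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)) - di
  rj <- seq_len(ncol(m)) - dj
  oki <- ri >= 1L & ri <= nrow(m)
  okj <- rj >= 1L & rj <= ncol(m)
  out[oki, okj] <- m[ri[oki], rj[okj]]
  out
}

erode_slices <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3L)
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    m <- out[, , k]
    for (it in seq_len(iterations)) {
      m <- m & shift2(m, 1L, 0L) & shift2(m, -1L, 0L) &
        shift2(m, 0L, 1L) & shift2(m, 0L, -1L)
    }
    out[, , k] <- m
  }
  out
}

dilate_slices <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3L)
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    m <- out[, , k]
    for (it in seq_len(iterations)) {
      m <- m | shift2(m, 1L, 0L) | shift2(m, -1L, 0L) |
        shift2(m, 0L, 1L) | shift2(m, 0L, -1L)
    }
    out[, , k] <- m
  }
  out
}

# Coerce per-voxel series input (vector = one voxel, matrix = voxels x samples)
# to a matrix with voxels in rows.
as_voxel_matrix <- function(signals) {
  if (is.null(dim(signals))) matrix(signals, nrow = 1L)
  else as.matrix(signals)
}

# Small non-cryptographic checksum for provenance stamps on outputs.
text_checksum <- function(s) {
  b <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 17
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
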