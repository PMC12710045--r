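# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are bit-reproducible without clobbering the
# session stream.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific sub-seed from a global seed; stays inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 100000) * 10007 + 101 * offset) %% 2147480000L
}

# Bilinear interpolation of a raster_grid at arbitrary coordinates,
# clamped to the grid edge.
raster_value_at <- function(r, x, y) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  fc <- (x - r$origin[1]) / r$cell + 0.5   # fractional column index
  fr <- (r$origin[2] - y) / r$cell + 0.5   # fractional row index
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1L); c0 <- pmax(c0, 1L)
  r0 <- pmin(floor(fr), nr - 1L); r0 <- pmax(r0, 1L)
  tx <- fc - c0
  ty <- fr - r0
  v00 <- v[cbind(r0, c0)]
  v01 <- v[cbind(r0, c0 + 1L)]
  v10 <- v[cbind(r0 + 1L, c0)]
  v11 <- v[cbind(r0 + 1L, c0 + 1L)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
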