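#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd median quantile
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a master seed; stays below 2^31.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(salt) * 7919 + as.double(index) * 104729) %% 2147483629
  as.integer(v)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_same_shape <- function(a_h, a_w, b_h, b_w, what = "inputs") {
  if (a_h != b_h || a_w != b_w) {
    stopf("%s have mismatched dimensions: %dx%d vs %dx%d", what, a_h, a_w, b_h, b_w)
  }
}

# 0-based pixel-centre coordinate grids; X[r, c] = c - 1, Y[r, c] = r - 1.
coord_grids <- function(h, w) {
  list(
    X = matrix(rep(seq_len(w) - 1, each = h), h, w),
    Y = matrix(rep(seq_len(h) - 1, times = w), h, w)
  )
}

# Bilinear sampling of a matrix at 0-based (x, y) locations with constant
# zero background outside [0, W-1] x [0, H-1].
bilinear_sample_zero <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  gather <- function(xx, yy) {
    ok <- xx >= 0 & xx <= (w - 1) & yy >= 0 & yy <= (h - 1)
    v <- numeric(length(xx))
    v[ok] <- m[yy[ok] + 1 + xx[ok] * h]
    v
  }
  (1 - tx) * (1 - ty) * gather(x0, y0) +
    tx * (1 - ty) * gather(x0 + 1, y0) +
    (1 - tx) * ty * gather(x0, y0 + 1) +
    tx * ty * gather(x0 + 1, y0 + 1)
}

# Bilinear sampling with edge replication (coordinates clamped to the domain).
bilinear_sample_replicate <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  xc <- clamp(x, 0, w - 1); yc <- clamp(y, 0, h - 1)
  x0 <- pmin(floor(xc), w - 2); y0 <- pmin(floor(yc), h - 2)
  if (w < 2) x0 <- rep(0, length(xc))
  if (h < 2) y0 <- rep(0, length(yc))
  tx <- xc - x0; ty <- yc - y0
  idx <- function(xx, yy) m[yy + 1 + xx * h]
  (1 - tx) * (1 - ty) * idx(x0, y0) +
    tx * (1 - ty) * idx(pmin(x0 + 1, w - 1), y0) +
    (1 - tx) * ty * idx(x0, pmin(y0 + 1, h - 1)) +
    tx * ty * idx(pmin(x0 + 1, w - 1), pmin(y0 + 1, h - 1))
}

# Nearest-neighbour sampling with a constant background outside the domain.
nearest_sample <- function(m, x, y, background = 0) {
  h <- nrow(m); w <- ncol(m)
  xr <- round(x); yr <- round(y)
  ok <- xr >= 0 & xr <= (w - 1) & yr >= 0 & yr <= (h - 1)
  v <- rep(background, length(x))
  v[ok] <- m[yr[ok] + 1 + xr[ok] * h]
  v
}
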