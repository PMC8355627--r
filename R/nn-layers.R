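# Minimal neural-network primitives with explicit forward caches and
# hand-written backward passes. Convolutions are 3x3, pad 1, stride 1 or 2,
# realised as im2col gathers followed by a BLAS matrix multiply; the col2im
# scatter in the backward pass exploits that, for a fixed kernel offset, the
# target indices are collision-free, so nine indexed adds suffice.

.conv_idx_cache <- new.env(parent = emptyenv())

# im2col index tables, cached per (h, w, stride, channels). The kernel
# position k = dr + 3*dc + 1 runs over the 3x3 window; W rows are ordered
# channel-major then kernel-position (row (c-1)*9 + k).
conv_indices <- function(h, w, stride, C) {
  key <- paste(h, w, stride, C, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  ho <- (h - 1L) %/% stride + 1L
  wo <- (w - 1L) %/% stride + 1L
  r0 <- seq(1L, by = stride, length.out = ho)
  c0 <- seq(1L, by = stride, length.out = wo)
  base_r <- rep(r0, times = wo)
  base_c <- rep(c0, each = ho)
  I9 <- matrix(0L, ho * wo, 9)
  for (k in 1:9) {
    dr <- (k - 1L) %% 3L
    dc <- (k - 1L) %/% 3L
    I9[, k] <- (base_c + dc - 1L) * hp + base_r + dr
  }
  plane <- hp * wp
  Ifull <- matrix(0L, ho * wo, 9L * C)
  for (c in seq_len(C)) {
    Ifull[, (c - 1) * 9 + (1:9)] <- I9 + (c - 1L) * plane
  }
  out <- list(I9 = I9, Ifull = Ifull, ho = ho, wo = wo, hp = hp, wp = wp)
  .conv_idx_cache[[key]] <- out
  out
}

new_conv <- function(cin, cout, stride = 1L, zero = FALSE) {
  W <- if (zero) matrix(0, 9 * cin, cout) else {
    matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout)
  }
  list(type = "conv", W = W, b = numeric(cout),
       cin = cin, cout = cout, stride = as.integer(stride))
}

conv_fwd <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; C <- d[3]
  ci <- conv_indices(h, w, layer$stride, C)
  xp <- array(0, c(ci$hp, ci$wp, C))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  n <- ci$ho * ci$wo
  P <- xp[ci$Ifull]
  dim(P) <- c(n, 9L * C)
  y <- P %*% layer$W
  y <- y + rep(layer$b, each = n)
  dim(y) <- c(ci$ho, ci$wo, layer$cout)
  list(out = y, cache = list(P = P, h = h, w = w, C = C, ci = ci))
}

conv_bwd <- function(layer, cache, dy) {
  ci <- cache$ci
  n <- ci$ho * ci$wo
  dym <- dy
  dim(dym) <- c(n, layer$cout)
  dW <- crossprod(cache$P, dym)
  db <- colSums(dym)
  if (layer$stride == 1L) {
    # input gradient of a stride-1 "same" convolution is the correlation of
    # dy with the spatially flipped kernel: one im2col matmul
    Wa <- layer$W
    dim(Wa) <- c(9L, cache$C, layer$cout)
    Wrot <- aperm(Wa[10L - (1:9), , , drop = FALSE], c(1, 3, 2))
    dim(Wrot) <- c(9L * layer$cout, cache$C)
    ci2 <- conv_indices(ci$ho, ci$wo, 1L, layer$cout)
    dyp <- array(0, c(ci2$hp, ci2$wp, layer$cout))
    dyp[2:(ci$ho + 1), 2:(ci$wo + 1), ] <- dym
    P2 <- dyp[ci2$Ifull]
    dim(P2) <- c(n, 9L * layer$cout)
    dx <- P2 %*% Wrot
    dim(dx) <- c(cache$h, cache$w, cache$C)
    return(list(dx = dx, dW = dW, db = db))
  }
  dP <- tcrossprod(dym, layer$W)
  plane <- ci$hp * ci$wp
  dxp <- matrix(0, plane, cache$C)
  for (k in 1:9) {
    idx <- ci$I9[, k]
    cols <- seq(k, by = 9, length.out = cache$C)
    dxp[idx, ] <- dxp[idx, ] + dP[, cols]
  }
  dim(dxp) <- c(ci$hp, ci$wp, cache$C)
  list(dx = dxp[2:(cache$h + 1), 2:(cache$w + 1), , drop = FALSE],
       dW = dW, db = db)
}

new_dense <- function(nin, nout, zero = FALSE) {
  W <- if (zero) matrix(0, nout, nin) else {
    matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  }
  list(type = "dense", W = W, b = numeric(nout))
}

dense_fwd <- function(layer, x) {
  list(out = as.numeric(layer$W %*% x + layer$b), cache = x)
}

dense_bwd <- function(layer, cache, dy) {
  list(dx = as.numeric(crossprod(layer$W, dy)),
       dW = outer(dy, cache), db = dy)
}

lrelu_fwd <- function(x, alpha = 0.1) {
  list(out = pmax(x, 0) + alpha * pmin(x, 0), cache = x > 0, alpha = alpha)
}

lrelu_bwd <- function(cache, dy, alpha = 0.1) {
  dy * (alpha + (1 - alpha) * cache)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dy) dy * cache

avgpool2_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  ro <- seq(1, 2 * h2, 2); co <- seq(1, 2 * w2, 2)
  y <- (x[ro, co, , drop = FALSE] + x[ro + 1, co, , drop = FALSE] +
          x[ro, co + 1, , drop = FALSE] + x[ro + 1, co + 1, , drop = FALSE]) / 4
  list(out = y, cache = d)
}

avgpool2_bwd <- function(cache, dy) {
  h2 <- dim(dy)[1]; w2 <- dim(dy)[2]
  dx <- array(0, cache)
  q <- dy / 4
  ro <- seq(1, 2 * h2, 2); co <- seq(1, 2 * w2, 2)
  dx[ro, co, ] <- q
  dx[ro + 1, co, ] <- q
  dx[ro, co + 1, ] <- q
  dx[ro + 1, co + 1, ] <- q
  dx
}

# Nearest-neighbour 2x upsampling followed by a crop to (th, tw); the crop
# absorbs odd skip sizes in the decoder.
up2_fwd <- function(x, th, tw) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
         drop = FALSE]
  list(out = y[seq_len(th), seq_len(tw), , drop = FALSE],
       cache = list(d = d, th = th, tw = tw))
}

up2_bwd <- function(cache, dy) {
  d <- cache$d
  big <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  big[seq_len(cache$th), seq_len(cache$tw), ] <- dy
  ro <- seq(1, 2 * d[1], 2); co <- seq(1, 2 * d[2], 2)
  big[ro, co, , drop = FALSE] + big[ro + 1, co, , drop = FALSE] +
    big[ro, co + 1, , drop = FALSE] + big[ro + 1, co + 1, , drop = FALSE]
}

# Bilinear image sampling at phi = id + field with zero background, plus the
# gradient of the output with respect to the sampling locations.
warp_fwd <- function(img, fdx, fdy) {
  h <- nrow(img); w <- ncol(img)
  g <- coord_grids(h, w)
  x <- g$X + fdx; y <- g$Y + fdy
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  gat <- function(xx, yy) {
    ok <- xx >= 0 & xx <= (w - 1) & yy >= 0 & yy <= (h - 1)
    v <- numeric(length(xx))
    v[ok] <- img[yy[ok] + 1 + xx[ok] * h]
    v
  }
  v00 <- gat(x0, y0); v10 <- gat(x0 + 1, y0)
  v01 <- gat(x0, y0 + 1); v11 <- gat(x0 + 1, y0 + 1)
  out <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  gx <- (1 - ty) * (v10 - v00) + ty * (v11 - v01)
  gy <- (1 - tx) * (v01 - v00) + tx * (v11 - v10)
  list(out = matrix(out, h, w),
       cache = list(gx = matrix(gx, h, w), gy = matrix(gy, h, w)))
}

warp_bwd <- function(cache, dout) {
  list(ddx = dout * cache$gx, ddy = dout * cache$gy)
}

# Replicate-padded bilinear sampling of a grid with value gradients with
# respect to the sampling locations (zero where the clamp is active) and the
# scatter information needed to push gradients back onto the sampled grid.
grid_sample_fwd <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  inx <- x >= 0 & x <= (w - 1)
  iny <- y >= 0 & y <= (h - 1)
  xc <- clamp(x, 0, w - 1); yc <- clamp(y, 0, h - 1)
  x0 <- pmin(floor(xc), w - 2); y0 <- pmin(floor(yc), h - 2)
  tx <- xc - x0; ty <- yc - y0
  i00 <- y0 + 1 + x0 * h
  i10 <- i00 + h
  i01 <- i00 + 1
  i11 <- i10 + 1
  v00 <- m[i00]; v10 <- m[i10]; v01 <- m[i01]; v11 <- m[i11]
  out <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  gx <- ((1 - ty) * (v10 - v00) + ty * (v11 - v01)) * inx
  gy <- ((1 - tx) * (v01 - v00) + tx * (v11 - v10)) * iny
  list(out = out, gx = gx, gy = gy,
       cache = list(h = h, w = w, i00 = i00, i10 = i10, i01 = i01, i11 = i11,
                    tx = tx, ty = ty))
}

# Scatter-add of upstream gradients onto the sampled grid.
grid_sample_bwd_grid <- function(cache, dout) {
  idx <- c(cache$i00, cache$i10, cache$i01, cache$i11)
  vals <- c(dout * (1 - cache$tx) * (1 - cache$ty),
            dout * cache$tx * (1 - cache$ty),
            dout * (1 - cache$tx) * cache$ty,
            dout * cache$tx * cache$ty)
  s <- rowsum(vals, idx, reorder = TRUE)
  g <- numeric(cache$h * cache$w)
  g[sort(unique(idx))] <- s
  matrix(g, cache$h, cache$w)
}
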