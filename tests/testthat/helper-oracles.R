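# Scalar double-loop reference implementations used as independent oracles,
# plus small fixture builders. Everything is generated in code at test time.

# Per-pixel bilinear warp with zero background; mirrors the warp contract but
# written as the naive scalar algorithm.
brute_warp_bilinear <- function(img, field) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  at <- function(xx, yy) {
    if (xx < 0 || xx > w - 1 || yy < 0 || yy > h - 1) return(0)
    img[yy + 1, xx + 1]
  }
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      x <- (c - 1) + field$dx[r, c]
      y <- (r - 1) + field$dy[r, c]
      x0 <- floor(x); y0 <- floor(y)
      tx <- x - x0; ty <- y - y0
      v <- (1 - tx) * (1 - ty) * at(x0, y0) +
        tx * (1 - ty) * at(x0 + 1, y0) +
        (1 - tx) * ty * at(x0, y0 + 1) +
        tx * ty * at(x0 + 1, y0 + 1)
      out[r, c] <- min(max(v, 0), 1)
    }
  }
  out
}

brute_warp_nearest <- function(seg, field) {
  h <- nrow(seg); w <- ncol(seg)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      x <- round((c - 1) + field$dx[r, c])
      y <- round((r - 1) + field$dy[r, c])
      if (x >= 0 && x <= w - 1 && y >= 0 && y <= h - 1) {
        out[r, c] <- seg[y + 1, x + 1]
      }
    }
  }
  out
}

# Eq.-style scalar endpoint error: ((sum of norms) / (H * W * t))^2
brute_endpoint_error <- function(u, v, t) {
  h <- nrow(u$dx); w <- ncol(u$dx)
  s <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      s <- s + sqrt((u$dx[r, c] - v$dx[r, c])^2 + (u$dy[r, c] - v$dy[r, c])^2)
    }
  }
  (s / (h * w * t))^2
}

brute_mse <- function(a, b) {
  s <- 0
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) s <- s + (a[r, c] - b[r, c])^2
  s / length(a)
}

# Per-class Dice with pixel-count weights from the first argument.
brute_weighted_dice <- function(a, b) {
  classes <- sort(unique(c(a, b)))
  num <- 0; den <- 0
  for (k in classes) {
    na <- sum(a == k); nb <- sum(b == k)
    if (na + nb == 0) next
    inter <- sum(a == k & b == k)
    dice <- 2 * inter / (na + nb)
    num <- num + na * dice
    den <- den + na
  }
  100 * num / den
}

rand_image <- function(h, w, seed = 1) {
  set.seed(seed)
  image2d(matrix(runif(h * w), h, w))
}

# Smooth random field built from a handful of landmark displacements; the
# result is rescaled so its max displacement magnitude is exactly `amp`
# (thin-plate interpolation is linear in the data, so the rescaled field is
# still an RBF field).
rand_rbf_field <- function(h, w, n = 8, amp = 3, seed = 1) {
  set.seed(seed)
  ref <- cbind(runif(n, 0, w - 1), runif(n, 0, h - 1))
  # keep points apart so the interpolant stays tame
  gap <- min(4, min(h, w) / 4)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)[-1]) {
    d <- sqrt((ref[i, 1] - ref[seq_len(i - 1), 1])^2 +
                (ref[i, 2] - ref[seq_len(i - 1), 2])^2)
    if (min(d) < gap) ok[i] <- FALSE
  }
  ref <- ref[ok, , drop = FALSE]
  if (nrow(ref) < 3) {
    ref <- rbind(ref, cbind(c(0, w - 1, (w - 1) / 2), c(0, h - 1, h - 1)))
  }
  mov <- ref + matrix(runif(2 * nrow(ref), -1, 1), ncol = 2)
  f <- from_keypoints(keypoint_set(ref, mov), h, w)
  mx <- max(sqrt(f$dx^2 + f$dy^2))
  s <- if (mx > 0) amp / mx else 0
  displacement_field(f$dx * s, f$dy * s)
}

translation_field <- function(h, w, tx, ty) {
  displacement_field(matrix(tx, h, w), matrix(ty, h, w))
}

new_sample_with_truth <- function(sample, truth) {
  sample$truth <- truth
  sample
}

max_abs_field_diff <- function(a, b) {
  max(abs(a$dx - b$dx), abs(a$dy - b$dy))
}
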