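GENE_PANEL <- c("CALB1", "CALB2", "CCK", "NPY", "PVALB", "SST", "VIP")

#' Specification of one synthetic section pair
#'
#' Identifies a synthetic sample by its gene tag, its coronal section index
#' along the anterior-posterior axis (1..528, the resolution of the reference
#' Nissl volume), a random seed and the target image shape. Identical specs
#' generate bit-identical samples.
#'
#' @param gene_id gene tag; the default panel mirrors seven interneuron
#'   markers (CALB1, CALB2, CCK, NPY, PVALB, SST, VIP).
#' @param section_index integer in `[1, 528]`.
#' @param seed integer random seed.
#' @param shape integer 2-vector `(H, W)`; default 80x114, a quarter of the
#'   production 320x456 frame per axis.
#' @return a `section_spec` object.
#' @export
section_spec <- function(gene_id = "CALB1", section_index = 264L, seed = 1L,
                         shape = c(80L, 114L)) {
  if (section_index < 1 || section_index > 528) {
    stopf("section_index must lie in [1, 528], got %d", section_index)
  }
  structure(list(gene_id = as.character(gene_id),
                 section_index = as.integer(section_index),
                 seed = as.integer(seed),
                 shape = as.integer(shape)),
            class = "section_spec")
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf("<section_spec %s section %d seed %d %dx%d>\n",
              x$gene_id, x$section_index, x$seed, x$shape[1], x$shape[2]))
  invisible(x)
}

new_registration_sample <- function(reference, moving, truth, meta) {
  structure(list(reference = reference, moving = moving, truth = truth,
                 meta = meta),
            class = "registration_sample")
}

#' @export
print.registration_sample <- function(x, ...) {
  cat(sprintf("<registration_sample %s section %d, %dx%d, mean |u| = %.2f px>\n",
              x$meta$gene_id, x$meta$section_index,
              nrow(x$reference), ncol(x$reference),
              mean(sqrt(x$truth$dx^2 + x$truth$dy^2))))
  invisible(x)
}

# Separable Gaussian blur through EBImage; falls back to the input for
# sub-resolution sigmas where blurring is a no-op.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0.01) return(m)
  out <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

# Foreground mask by a global Otsu threshold (parameter-free).
foreground_mask <- function(m) {
  thr <- EBImage::otsu(EBImage::Image(clamp(m, 0, 1)))
  m > thr
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (max(lab) == 0) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# Smooth star-shaped section outline: ellipse with low-order radial harmonics
# whose coefficients vary continuously with the section index.
section_geometry <- function(h, w, section_index) {
  t <- section_index / 528
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  size <- 0.55 + 0.45 * sin(pi * clamp(t, 0.04, 0.96))
  rx <- 0.40 * w * size
  ry <- 0.38 * h * (0.6 + 0.4 * sin(pi * clamp(t, 0.04, 0.96) * 0.85 + 0.25))
  amps <- c(0.10 * sin(2 * pi * t + 0.4),
            0.07 * cos(3 * pi * t + 1.1),
            0.05 * sin(5 * pi * t + 2.0))
  phases <- c(0.8 + t, 2.1 - 0.5 * t, 0.3 + 2 * t)
  g <- coord_grids(h, w)
  ex <- (g$X - cx) / rx
  ey <- (g$Y - cy) / ry
  theta <- atan2(ey, ex)
  rad <- sqrt(ex^2 + ey^2)
  rim <- 1 + amps[1] * cos(2 * theta + phases[1]) +
    amps[2] * cos(3 * theta + phases[2]) +
    amps[3] * cos(4 * theta + phases[3])
  list(mask = rad <= rim, soft = clamp((rim - rad) / 0.08, 0, 1),
       center = c(cx, cy))
}

# Pseudo-Nissl rendering: mid-bright tissue with fine cellular speckle on a
# dark background.
render_reference <- function(geom, h, w) {
  speck <- gaussian_blur(matrix(runif(h * w), h, w), 0.6)
  slow <- gaussian_blur(matrix(runif(h * w), h, w), max(2, min(h, w) / 12))
  slow <- (slow - min(slow)) / max(max(slow) - min(slow), 1e-8)
  tissue <- 0.55 + 0.25 * (speck - 0.5) + 0.18 * (slow - 0.5)
  image2d(matrix(clamp(tissue * geom$soft, 0, 1), h, w))
}

# Pseudo-gene-expression rendering in the reference frame: dark tissue with
# sparse bright puncta whose density and size depend on the gene, so the
# intensity histogram is disjoint from the reference's.
render_moving_modality <- function(geom, h, w, gene_id) {
  gi <- match(gene_id, GENE_PANEL)
  if (is.na(gi)) gi <- 1 + (sum(utf8ToInt(gene_id)) %% 7)
  density <- 0.004 + 0.004 * gi / 7
  radius <- 0.8 + 0.5 * (gi %% 3)
  base <- matrix(0.12, h, w)
  inside <- which(geom$mask)
  n <- max(3, round(length(inside) * density))
  centers <- sample(inside, min(n, length(inside)))
  g <- coord_grids(h, w)
  px <- g$X[centers]; py <- g$Y[centers]
  dots <- matrix(0, h, w)
  for (i in seq_along(px)) {
    x0 <- max(0, floor(px[i] - radius - 1)); x1 <- min(w - 1, ceiling(px[i] + radius + 1))
    y0 <- max(0, floor(py[i] - radius - 1)); y1 <- min(h - 1, ceiling(py[i] + radius + 1))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - py[i])^2, (xs - px[i])^2, "+")
    patch <- clamp(1 - sqrt(d2) / radius, 0, 1)
    dots[ys + 1, xs + 1] <- pmax(dots[ys + 1, xs + 1], 0.85 * patch)
  }
  img <- (base + dots) * geom$soft
  image2d(matrix(clamp(img, 0, 1), h, w))
}

# Random ground-truth transformation: affine (translation, rotation, scale
# about the section centre) composed with a smooth elastic part interpolated
# from perturbed edge control points. Amplitudes scale with the frame size so
# a full-scale (320x456) dataset has mean displacement near 20 px.
random_truth_field <- function(reference, geom, h, w,
                               elastic_amplitude = NULL, affine = "full",
                               max_translation = 20) {
  s <- (h / 320 + w / 456) / 2
  if (is.null(elastic_amplitude)) elastic_amplitude <- 6 * s
  if (isTRUE(affine)) affine <- "full"
  if (identical(affine, FALSE)) affine <- "identity"
  if (affine == "full") {
    ang <- runif(1, -10, 10) * pi / 180
    sc <- runif(2, 0.85, 1.15)
    tmag <- runif(1, 4, max_translation) * s
    tdir <- runif(1, 0, 2 * pi)
    A <- diag(sc) %*% matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    ctr <- geom$center
    off <- ctr - as.numeric(A %*% ctr) + tmag * c(cos(tdir), sin(tdir))
    aff <- affine_map(A, off)
  } else if (affine == "translation") {
    tmag <- runif(1, 0.2 * max_translation, max_translation)
    tdir <- runif(1, 0, 2 * pi)
    aff <- affine_map(diag(2), tmag * c(cos(tdir), sin(tdir)))
  } else {
    aff <- affine_map()
  }
  f_aff <- from_affine(aff, h, w)
  if (elastic_amplitude <= 0) return(f_aff)
  kps <- extract_edge_control_points(reference, n = 8,
                                     seed = floor(runif(1, 0, 2^30)))
  if (length(kps) < 3) return(f_aff)
  kps$mov_points <- kps$ref_points +
    matrix(runif(2 * length(kps), -elastic_amplitude, elastic_amplitude), ncol = 2)
  f_el <- from_keypoints(kps, h, w)
  compose_fields(f_aff, f_el)
}

#' Generate one synthetic multimodal section pair
#'
#' Builds a pseudo-Nissl reference image, a pseudo-gene-expression moving
#' image showing the same section geometry under a random ground-truth
#' deformation, and the deformation itself (mapping reference coordinates to
#' moving coordinates). The generator self-checks that the ground truth is
#' folding-free, that warping the moving image by it recovers the reference
#' foreground (Dice >= 0.95), and that the two modalities are genuinely
#' distinct (foreground mean absolute intensity difference > 0.2); failed
#' checks trigger bounded resampling.
#'
#' @param spec a [section_spec()].
#' @param elastic_amplitude elastic control-point amplitude in pixels;
#'   `NULL` scales the default (6 px at full 320x456 scale) to the frame.
#'   Zero disables the elastic part.
#' @param affine `"full"` (or `TRUE`) for translation + rotation + scale,
#'   `"translation"` for a pure translation, `"identity"` (or `FALSE`) for
#'   none.
#' @param max_translation largest translation magnitude, in pixels at full
#'   320x456 scale for `"full"` (scaled to the frame) and in frame pixels for
#'   `"translation"`.
#' @return a `registration_sample`.
#' @export
generate_section_pair <- function(spec, elastic_amplitude = NULL,
                                  affine = "full", max_translation = 20) {
  h <- spec$shape[1]; w <- spec$shape[2]
  with_seed(spec$seed, {
    geom <- section_geometry(h, w, spec$section_index)
    reference <- render_reference(geom, h, w)
    mov_ref_frame <- render_moving_modality(geom, h, w, spec$gene_id)
    for (attempt in 1:6) {
      truth <- random_truth_field(reference, geom, h, w,
                                  elastic_amplitude = elastic_amplitude,
                                  affine = affine,
                                  max_translation = max_translation)
      if (corrupted_fraction(truth) > 0) next
      if (max(abs(truth$dx)) < 1e-12 && max(abs(truth$dy)) < 1e-12) {
        moving <- mov_ref_frame
      } else {
        moving <- warp_image(mov_ref_frame, invert_field(truth))
      }
      reg <- warp_image(moving, truth)
      fg_ref <- geom$mask
      fg_reg <- unclass(reg) > 0.05
      dice0 <- 2 * sum(fg_ref & fg_reg) / max(sum(fg_ref) + sum(fg_reg), 1)
      if (dice0 < 0.95) next
      if (mean(abs(reference[fg_ref] - reg[fg_ref])) <= 0.2) next
      return(new_registration_sample(reference, moving, truth, spec))
    }
    stopf("sample generation failed self-checks after bounded retries (%s, section %d)",
          spec$gene_id, spec$section_index)
  })
}

#' Paint a tissue artifact onto the moving image
#'
#' Emulates histological acquisition damage: a `tear` is a thin dark crack
#' polyline across the section, a `bubble` is a bright disc with a dark rim.
#' Artifacts corrupt appearance only; the ground-truth geometry is unchanged.
#'
#' @param sample a `registration_sample`.
#' @param kind `"tear"` or `"bubble"`.
#' @param seed integer seed.
#' @param radius bubble radius in pixels (ignored for tears); radius 0 is a
#'   no-op.
#' @return a `registration_sample` with a modified moving image.
#' @export
add_artifacts <- function(sample, kind = c("tear", "bubble"), seed = 1L,
                          radius = NULL) {
  kind <- match.arg(kind)
  m <- as_matrix(sample$moving)
  h <- nrow(m); w <- ncol(m)
  with_seed(seed, {
    fg <- which(m > 0.05)
    if (length(fg) == 0) fg <- seq_along(m)
    if (kind == "tear") {
      g <- coord_grids(h, w)
      i1 <- sample(fg, 1); i2 <- sample(fg, 1)
      p1 <- c(g$X[i1], g$Y[i1]); p2 <- c(g$X[i2], g$Y[i2])
      tt <- seq(0, 1, length.out = 4 * max(h, w))
      wig <- 1.5 * sin(tt * 6 * pi + runif(1, 0, 2 * pi))
      nrm <- c(-(p2[2] - p1[2]), p2[1] - p1[1])
      nl <- sqrt(sum(nrm^2)); if (nl > 0) nrm <- nrm / nl
      xs <- round(p1[1] + tt * (p2[1] - p1[1]) + wig * nrm[1])
      ys <- round(p1[2] + tt * (p2[2] - p1[2]) + wig * nrm[2])
      ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
      idx <- unique(ys[ok] + 1 + xs[ok] * h)
      m[idx] <- m[idx] * 0.15
    } else {
      if (is.null(radius)) radius <- runif(1, 0.02, 0.05) * min(h, w)
      if (radius > 0) {
        ctr <- sample(fg, 1)
        cx <- (ctr - 1) %/% h; cy <- (ctr - 1) %% h
        g <- coord_grids(h, w)
        d <- sqrt((g$X - cx)^2 + (g$Y - cy)^2)
        m[d <= radius] <- 0.9
        m[d > radius & d <= radius + 1.5] <- 0.08
      }
    }
  })
  new_registration_sample(sample$reference, image2d(clamp(m, 0, 1)),
                          sample$truth, sample$meta)
}

#' Sample control points on the section boundary
#'
#' Thresholds the image (global Otsu), keeps the largest foreground
#' component, extracts its boundary pixels and returns `n` of them,
#' approximately uniformly by angular position around the component centroid.
#' The moving points are returned equal to the reference points (zero
#' displacement) for the caller to perturb.
#'
#' @param img an [image2d()] with non-empty foreground.
#' @param n number of control points; 0 yields an empty set.
#' @param seed integer seed.
#' @return a [keypoint_set()].
#' @export
extract_edge_control_points <- function(img, n, seed = 1L) {
  m <- as_matrix(img)
  mask <- largest_component(foreground_mask(m))
  if (!any(mask)) stopf("image has no foreground above the global threshold")
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)] &
    !(pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
        pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)])
  idx <- which(inner)
  if (n == 0) return(keypoint_set(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2)))
  if (n > length(idx)) {
    warning(sprintf("requested %d control points but the contour has %d pixels; reduced",
                    n, length(idx)))
    n <- length(idx)
  }
  g <- coord_grids(h, w)
  bx <- g$X[idx]; by <- g$Y[idx]
  cx <- mean(g$X[mask]); cy <- mean(g$Y[mask])
  ang <- atan2(by - cy, bx - cx)
  ord <- order(ang)
  with_seed(seed, {
    start <- runif(1, 0, 2 * pi)
    targets <- (start + 2 * pi * (seq_len(n) - 1) / n) %% (2 * pi) - pi
    pick <- vapply(targets, function(a) {
      d <- abs(((ang[ord] - a + pi) %% (2 * pi)) - pi)
      ord[which.min(d)]
    }, integer(1))
  })
  pts <- cbind(bx[pick], by[pick])
  keypoint_set(pts, pts)
}

#' Generate a synthetic multimodal dataset
#'
#' Produces `n_genes * sections_per_gene` section pairs with gene and
#' section-index metadata, section indices spread over the full
#' anterior-posterior range `[1, 528]`, deterministically under `seed`.
#'
#' @param n_genes number of gene tags (the default panel has 7; more recycle
#'   with numeric suffixes).
#' @param sections_per_gene sections per gene.
#' @param shape integer `(H, W)` of every image.
#' @param seed master seed.
#' @param ... passed to [generate_section_pair()].
#' @return a list of `registration_sample`s.
#' @export
generate_dataset <- function(n_genes = 7, sections_per_gene = 4,
                             shape = c(80L, 114L), seed = 1L, ...) {
  if (n_genes < 1 || sections_per_gene < 1) {
    stopf("n_genes and sections_per_gene must be at least 1")
  }
  genes <- if (n_genes <= length(GENE_PANEL)) GENE_PANEL[seq_len(n_genes)] else {
    c(GENE_PANEL, paste0("G", seq_len(n_genes - length(GENE_PANEL))))
  }
  samples <- vector("list", n_genes * sections_per_gene)
  k <- 0
  for (gi in seq_len(n_genes)) {
    base <- round(seq(1, 528, length.out = sections_per_gene + 2))[-c(1, sections_per_gene + 2)]
    for (si in seq_len(sections_per_gene)) {
      k <- k + 1
      jitter <- derive_seed(seed, k, salt = 13L) %% 21L - 10L
      sec <- as.integer(clamp(base[si] + jitter, 1, 528))
      spec <- section_spec(genes[gi], sec, derive_seed(seed, k), shape)
      samples[[k]] <- generate_section_pair(spec, ...)
    }
  }
  samples
}

#' Metadata table of a dataset
#'
#' @param samples list of `registration_sample`s.
#' @return a tibble with `gene_id`, `section_index`, `seed`, `height`, `width`.
#' @export
dataset_meta <- function(samples) {
  tibble::tibble(
    gene_id = vapply(samples, function(s) s$meta$gene_id, character(1)),
    section_index = vapply(samples, function(s) s$meta$section_index, integer(1)),
    seed = vapply(samples, function(s) s$meta$seed, integer(1)),
    height = vapply(samples, function(s) nrow(s$reference), integer(1)),
    width = vapply(samples, function(s) ncol(s$reference), integer(1))
  )
}
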