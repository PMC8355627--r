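#' Hierarchical segmentation
#'
#' A label image of leaf region ids together with a region tree. Level 0
#' distinguishes only background (label 0) from foreground (the root);
#' deeper levels split the section into an increasing number of subregions.
#'
#' @param labels integer matrix of leaf region ids (0 = background).
#' @param tree data frame with columns `id`, `parent` (`NA` for the root),
#'   `level` (0 for the root) and optionally `name`.
#' @return a `seg_hierarchy` object with a `max_level` field.
#' @export
seg_hierarchy <- function(labels, tree) {
  tree <- as.data.frame(tree)
  if (!all(c("id", "parent", "level") %in% names(tree))) {
    stopf("tree needs columns id, parent, level")
  }
  ids <- unique(as.vector(labels))
  ids <- ids[ids != 0]
  if (!all(ids %in% tree$id)) stopf("labels contain ids missing from the tree")
  # every node must reach the root
  for (id in tree$id) {
    cur <- id; hops <- 0
    while (!is.na(cur)) {
      row <- match(cur, tree$id)
      if (is.na(row)) stopf("node %d has ancestor %d missing from the tree", id, cur)
      cur <- tree$parent[row]
      hops <- hops + 1
      if (hops > nrow(tree)) stopf("tree contains a cycle at node %d", id)
    }
  }
  structure(list(labels = labels, tree = tree, max_level = max(tree$level)),
            class = "seg_hierarchy")
}

#' @export
print.seg_hierarchy <- function(x, ...) {
  cat(sprintf("<seg_hierarchy %dx%d, %d regions, max level %d>\n",
              nrow(x$labels), ncol(x$labels), nrow(x$tree), x$max_level))
  invisible(x)
}

#' Collapse a label image to a hierarchy level
#'
#' Each label is replaced by its deepest ancestor whose level does not exceed
#' `level`; background stays 0. At level 0 every foreground label collapses
#' to the root, giving a background/foreground map.
#'
#' @param labels integer label matrix.
#' @param tree hierarchy tree (see [seg_hierarchy()]).
#' @param level target level.
#' @return an integer label matrix.
#' @export
collapse_labels <- function(labels, tree, level) {
  tree <- as.data.frame(tree)
  map <- integer(0)
  for (id in unique(as.vector(labels))) {
    if (id == 0) { map[as.character(0)] <- 0L; next }
    cur <- id
    repeat {
      row <- match(cur, tree$id)
      if (is.na(row)) stopf("label %d missing from the tree", id)
      if (tree$level[row] <= level) break
      cur <- tree$parent[row]
    }
    map[as.character(id)] <- as.integer(cur)
  }
  matrix(map[as.character(labels)], nrow(labels), ncol(labels))
}

#' Pixel-weighted hierarchical Dice score
#'
#' Collapses both label images to the requested hierarchy level, computes the
#' Dice overlap of every class, and averages with weights proportional to the
#' class pixel counts in `seg_a`'s collapsed image (classes absent from both
#' are skipped). Returned as a percentage.
#'
#' @param seg_a,seg_b integer label matrices of identical shape. `seg_a`
#'   defines the weights.
#' @param tree hierarchy tree.
#' @param level level to evaluate at; must not exceed the tree's max level.
#' @return Dice score in `[0, 100]`.
#' @export
hierarchical_dice <- function(seg_a, seg_b, tree, level) {
  check_same_shape(nrow(seg_a), ncol(seg_a), nrow(seg_b), ncol(seg_b), "labels")
  if (level > max(tree$level)) {
    stopf("level %d exceeds the hierarchy's max level %d", level, max(tree$level))
  }
  a <- collapse_labels(seg_a, tree, level)
  b <- collapse_labels(seg_b, tree, level)
  classes <- sort(unique(c(a, b)))
  num <- 0; den <- 0
  for (k in classes) {
    na <- sum(a == k); nb <- sum(b == k)
    if (na + nb == 0) next
    dice <- 2 * sum(a == k & b == k) / (na + nb)
    num <- num + na * dice
    den <- den + na
  }
  if (den == 0) return(100)
  100 * num / den
}

#' Synthetic nested hierarchy for a sample
#'
#' Builds a reference-space hierarchical segmentation of a synthetic section:
#' the root is the foreground; deeper levels split it recursively by
#' left/right position, radial bands and vertical position, giving up to 8
#' leaf regions at level `max_level`.
#'
#' @param sample a `registration_sample`.
#' @param max_level depth of the hierarchy (>= 1, default 4).
#' @return a [seg_hierarchy()].
#' @export
generate_hierarchy <- function(sample, max_level = 4L) {
  m <- as_matrix(sample$reference)
  h <- nrow(m); w <- ncol(m)
  fg <- largest_component(foreground_mask(m))
  g <- coord_grids(h, w)
  cx <- mean(g$X[fg]); cy <- mean(g$Y[fg])
  rad <- sqrt((g$X - cx)^2 + (g$Y - cy)^2)
  rmed <- stats::median(rad[fg])
  splits <- list(g$X <= cx, rad <= rmed, g$Y <= cy)
  max_level <- max(1L, min(as.integer(max_level), 4L))
  n_splits <- min(max_level - 1L, length(splits))

  tree <- data.frame(id = 1L, parent = NA_integer_, level = 0L,
                     name = "foreground")
  nodes <- list(list(id = 1L, mask = fg))
  next_id <- 2L
  for (s in seq_len(n_splits)) {
    nxt <- list()
    for (nd in nodes) {
      for (half in c(TRUE, FALSE)) {
        mk <- nd$mask & (splits[[s]] == half)
        tree <- rbind(tree, data.frame(id = next_id, parent = nd$id,
                                       level = s,
                                       name = sprintf("n%d", next_id)))
        nxt[[length(nxt) + 1]] <- list(id = next_id, mask = mk)
        next_id <- next_id + 1L
      }
    }
    nodes <- nxt
  }
  # pad levels so max_level is reached even with fewer geometric splits
  lvl <- n_splits
  while (lvl < max_level) {
    nxt <- list()
    for (nd in nodes) {
      tree <- rbind(tree, data.frame(id = next_id, parent = nd$id,
                                     level = lvl + 1L,
                                     name = sprintf("n%d", next_id)))
      nxt[[length(nxt) + 1]] <- list(id = next_id, mask = nd$mask)
      next_id <- next_id + 1L
    }
    nodes <- nxt
    lvl <- lvl + 1L
  }
  labels <- matrix(0L, h, w)
  for (nd in nodes) labels[nd$mask] <- nd$id
  seg_hierarchy(labels, tree)
}

#' Stratified train/test split
#'
#' Splits by gene and anterior-posterior section tercile (sections 1-176,
#' 177-352, 353-528): within every gene-by-tercile stratum the test
#' proportion deviates from `test_fraction` by at most one sample. Strata
#' with fewer than two samples go wholly to the training set (with a
#' warning).
#'
#' @param dataset list of `registration_sample`s.
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return a list with elements `train` and `test`.
#' @export
stratified_split <- function(dataset, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie strictly between 0 and 1")
  }
  meta <- dataset_meta(dataset)
  tercile <- cut(meta$section_index, c(0, 176, 352, 528), labels = FALSE)
  strata <- paste(meta$gene_id, tercile)
  test_idx <- integer(0)
  with_seed(seed, {
    for (st in unique(strata)) {
      members <- which(strata == st)
      if (length(members) < 2) {
        warning(sprintf("stratum '%s' has %d sample(s); assigned to train", st,
                        length(members)))
        next
      }
      k <- round(length(members) * test_fraction)
      k <- max(0, min(k, length(members) - 1))
      if (k > 0) test_idx <- c(test_idx, sample(members, k))
    }
  })
  list(train = dataset[setdiff(seq_along(dataset), test_idx)],
       test = dataset[sort(test_idx)])
}

#' Gene-holdout split
#'
#' All samples of the holdout gene form the test set; everything else trains.
#'
#' @param dataset list of `registration_sample`s.
#' @param holdout_gene gene tag present in the dataset.
#' @return a list with elements `train` and `test`.
#' @export
gene_holdout_split <- function(dataset, holdout_gene) {
  genes <- vapply(dataset, function(s) s$meta$gene_id, character(1))
  if (!holdout_gene %in% genes) {
    stopf("gene '%s' is not present in the dataset", holdout_gene)
  }
  test <- dataset[genes == holdout_gene]
  train <- dataset[genes != holdout_gene]
  if (length(train) == 0) {
    stopf("holding out '%s' leaves an empty training set", holdout_gene)
  }
  list(train = train, test = test)
}

#' Evaluate a registration network
#'
#' For each sample: predict the combined field, numerically invert both the
#' ground truth and the prediction (scattered data interpolation), warp the
#' reference-space segmentation into moving space with each inverse, and
#' score the pixel-weighted hierarchical Dice at the requested levels
#' (clamped to the hierarchy depth) together with the corrupted-pixel
#' percentage of the prediction.
#'
#' @param model a `registration_model`.
#' @param samples list of `registration_sample`s.
#' @param hierarchies list of [seg_hierarchy()]s, one per sample; `NULL`
#'   generates synthetic hierarchies.
#' @param levels Dice levels to evaluate (clamped to each hierarchy's depth).
#' @param predictions optional list of precomputed `displacement_field`s to
#'   evaluate instead of running the network (used for self-consistency
#'   checks).
#' @return an `eval_report`: list with `dice_by_level` (tibble of level,
#'   mean, sd), `corrupted_pct` (mean, sd) and `per_sample` (tibble).
#' @export
evaluate <- function(model, samples, hierarchies = NULL,
                     levels = c(0, 2, 4, 6, 8), predictions = NULL) {
  if (is.null(hierarchies)) {
    hierarchies <- lapply(samples, generate_hierarchy)
  }
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    hier <- hierarchies[[i]]
    pred <- if (!is.null(predictions)) predictions[[i]] else {
      forward(model, smp$reference, smp$moving)$combined_field
    }
    lv <- unique(pmin(levels, hier$max_level))
    inv_truth <- invert_field(smp$truth)
    inv_pred <- invert_field(pred)
    seg_truth <- warp_labels(hier$labels, inv_truth)
    seg_pred <- warp_labels(hier$labels, inv_pred)
    dice <- vapply(lv, function(l) {
      hierarchical_dice(seg_truth, seg_pred, hier$tree, l)
    }, numeric(1))
    row <- tibble::tibble(sample = i,
                          gene_id = smp$meta$gene_id,
                          section_index = smp$meta$section_index,
                          corrupted_pct = 100 * corrupted_fraction(pred))
    for (j in seq_along(lv)) row[[paste0("dice_", levels[j])]] <- dice[j]
    rows[[i]] <- row
  }
  per_sample <- do.call(rbind, rows)
  dcols <- grep("^dice_", names(per_sample), value = TRUE)
  dice_by_level <- tibble::tibble(
    level = as.integer(sub("dice_", "", dcols)),
    mean = vapply(dcols, function(cn) mean(per_sample[[cn]]), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(dcols, function(cn) sd(per_sample[[cn]]), numeric(1),
                USE.NAMES = FALSE)
  )
  structure(list(dice_by_level = dice_by_level,
                 corrupted_pct = c(mean = mean(per_sample$corrupted_pct),
                                   sd = sd(per_sample$corrupted_pct)),
                 per_sample = per_sample),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (i in seq_len(nrow(x$dice_by_level))) {
    cat(sprintf("  Dice-%d: %.1f +- %.1f\n", x$dice_by_level$level[i],
                x$dice_by_level$mean[i],
                ifelse(is.na(x$dice_by_level$sd[i]), 0, x$dice_by_level$sd[i])))
  }
  cat(sprintf("  corrupted: %.2f%% +- %.2f%%\n", x$corrupted_pct["mean"],
              ifelse(is.na(x$corrupted_pct["sd"]), 0, x$corrupted_pct["sd"])))
  invisible(x)
}
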