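# --- NPY (documented binary array standard), version 1.0 ----------------
# Hand-rolled because the interchange format for displacement fields is NPY
# and no installed R package provides it.

npy_dtype_info <- function(descr) {
  switch(descr,
    "<f4" = list(what = "double", size = 4L),
    "<f8" = list(what = "double", size = 8L),
    "<i4" = list(what = "integer", size = 4L),
    "<i8" = list(what = "integer", size = 8L),
    stopf("unsupported NPY dtype '%s'", descr))
}

#' Write an array to an NPY file
#'
#' Writes a numeric array in C (row-major) order, little-endian, NPY
#' version 1.0.
#'
#' @param x vector, matrix or array.
#' @param path output path.
#' @param dtype `"<f4"`, `"<f8"`, `"<i4"` (little-endian float32/float64/int32).
#' @return the path, invisibly.
#' @export
write_npy <- function(x, path, dtype = "<f4") {
  info <- npy_dtype_info(dtype)
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  # C-order flattening: reverse the axes, then column-major vectorize
  flat <- if (length(shape) > 1) as.vector(aperm(x, rev(seq_along(shape)))) else as.vector(x)
  shape_str <- if (length(shape) == 1) sprintf("(%d,)", shape) else {
    sprintf("(%s)", paste(shape, collapse = ", "))
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    dtype, shape_str)
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  if (pad == 64) pad <- 0
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  if (info$what == "integer") {
    writeBin(as.integer(flat), con, size = info$size, endian = "little")
  } else {
    writeBin(as.numeric(flat), con, size = info$size, endian = "little")
  }
  invisible(path)
}

#' Read an NPY file
#'
#' @param path NPY file (version 1.x, little-endian numeric dtypes).
#' @return a vector, matrix or array with the stored shape.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) stopf("cannot open %s: no such file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(as.integer(magic), c(0x93L, utf8ToInt("NUMPY")))) {
    stopf("%s is not an NPY file", path)
  }
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  if (length(shape) == 0) shape <- 1L
  info <- npy_dtype_info(descr)
  n <- prod(shape)
  data <- readBin(con, info$what, n, size = info$size, endian = "little")
  if (length(data) < n) stopf("%s is truncated", path)
  if (length(shape) == 1) return(data)
  if (fortran) {
    array(data, shape)
  } else {
    aperm(array(data, rev(shape)), rev(seq_along(shape)))
  }
}

# --- displacement fields -------------------------------------------------

#' Save a displacement field
#'
#' Stored as a `(2, H, W)` float32 NPY array (channel order dx, dy) with a
#' JSON sidecar `<path>.json` recording the dimensions and the coordinate
#' convention (`"xy0"`: 0-based, x = column, y = row).
#'
#' @param field a [displacement_field()].
#' @param path output `.npy` path.
#' @return the path, invisibly.
#' @export
save_field <- function(field, path) {
  h <- field_h(field); w <- field_w(field)
  arr <- array(0, c(2, h, w))
  arr[1, , ] <- field$dx
  arr[2, , ] <- field$dy
  write_npy(arr, path, dtype = "<f4")
  jsonlite::write_json(list(height = h, width = w,
                            coordinate_convention = "xy0"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a displacement field saved by [save_field()]
#'
#' @param path `.npy` path.
#' @return a [displacement_field()].
#' @export
load_field <- function(path) {
  arr <- read_npy(path)
  if (length(dim(arr)) != 3 || dim(arr)[1] != 2) {
    stopf("%s does not hold a (2, H, W) field array", path)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!identical(meta$coordinate_convention, "xy0")) {
      stopf("unsupported coordinate convention '%s'", meta$coordinate_convention)
    }
  }
  displacement_field(matrix(arr[1, , ], dim(arr)[2], dim(arr)[3]),
                     matrix(arr[2, , ], dim(arr)[2], dim(arr)[3]))
}

# --- keypoints -----------------------------------------------------------

#' Write a keypoint set to CSV
#'
#' Columns `ref_x, ref_y, mov_x, mov_y`, 0-based float coordinates.
#'
#' @param kps a [keypoint_set()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_keypoints <- function(kps, path) {
  df <- data.frame(ref_x = kps$ref_points[, 1], ref_y = kps$ref_points[, 2],
                   mov_x = kps$mov_points[, 1], mov_y = kps$mov_points[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a keypoint CSV written by [write_keypoints()]
#'
#' @param path CSV with header `ref_x, ref_y, mov_x, mov_y`.
#' @return a [keypoint_set()].
#' @export
read_keypoints <- function(path) {
  df <- read.csv(path)
  need <- c("ref_x", "ref_y", "mov_x", "mov_y")
  if (!all(need %in% names(df))) {
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  }
  keypoint_set(cbind(df$ref_x, df$ref_y), cbind(df$mov_x, df$mov_y))
}

# --- images --------------------------------------------------------------

#' Canonical processing frame
#'
#' All images entering the model are resampled to one fixed resolution; the
#' production default, 320x456 px, corresponds to a 25 um sampling distance
#' for coronal mouse-brain sections.
#'
#' @param height,width frame dimensions in pixels.
#' @return a `canonical_frame` object.
#' @export
canonical_frame <- function(height = 320L, width = 456L) {
  structure(list(height = as.integer(height), width = as.integer(width)),
            class = "canonical_frame")
}

# Bilinear resize with edge replication (align-corners = FALSE convention).
resize_matrix <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  if (h == th && w == tw) return(m)
  xo <- (seq_len(tw) - 0.5) * w / tw - 0.5
  yo <- (seq_len(th) - 0.5) * h / th - 0.5
  X <- matrix(rep(xo, each = th), th, tw)
  Y <- matrix(rep(yo, times = tw), th, tw)
  matrix(bilinear_sample_replicate(m, X, Y), th, tw)
}

#' Load an image into the canonical frame
#'
#' Reads a PNG or TIFF, converts RGB to grayscale with luma weights,
#' resamples bilinearly to the frame dimensions and scales intensities to
#' `[0, 1]`.
#'
#' @param path PNG or TIFF file.
#' @param frame a [canonical_frame()]; `NULL` keeps the native size.
#' @return an [image2d()].
#' @export
load_image <- function(path, frame = canonical_frame()) {
  if (!file.exists(path)) stopf("cannot read image: %s does not exist", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stopf("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) stopf("cannot read image %s: %s", path,
                               conditionMessage(e)))
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    arr <- if (ch >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  arr <- clamp(arr, 0, 1)
  if (!is.null(frame)) arr <- resize_matrix(arr, frame$height, frame$width)
  image2d(arr, clip = TRUE)
}

#' Save an image as 8-bit PNG
#'
#' @param img an [image2d()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_image <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Resample a displacement field to a new resolution
#'
#' Fields are vector data: each component is bilinearly resampled and then
#' rescaled by the axis ratio (`dx` by `W_new / W_old`, `dy` by
#' `H_new / H_old`) so displacements keep their meaning in the new frame.
#'
#' @param field a [displacement_field()].
#' @param new_shape integer `(H, W)`.
#' @return a [displacement_field()].
#' @export
resample_field <- function(field, new_shape) {
  th <- new_shape[1]; tw <- new_shape[2]
  h <- field_h(field); w <- field_w(field)
  displacement_field(resize_matrix(field$dx, th, tw) * tw / w,
                     resize_matrix(field$dy, th, tw) * th / h)
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's native serialized-object container.
#'
#' @param model a `registration_model`.
#' @param path checkpoint path (conventionally `.rds`).
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "registration_model")) stopf("%s is not a model checkpoint", path)
  m
}
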