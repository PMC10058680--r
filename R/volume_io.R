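#' @importFrom stats rnorm runif setNames quantile
#' @importFrom utils write.csv read.csv
NULL

# Class codes shared by every module: a single canonical encoding for files,
# metrics and colormaps.
CLASS_CODES <- c(background = 0L, cell = 1L, `nuclear envelope` = 2L, nucleus = 3L)

#' Class codes of the four-class labeling
#'
#' The fixed alphabet used for ground truth, automatic labels and predictions:
#' 0 = background, 1 = cell (cytoplasm), 2 = nuclear envelope, 3 = nucleus.
#'
#' @return Named integer vector of the four class codes.
#' @export
class_codes <- function() CLASS_CODES

#' Construct a grayscale image volume
#'
#' A `VolumeStack` is a 3D array of 8-bit intensities stored `[row, col, slice]`
#' with voxel-size metadata in nanometres. Slice indices are 1-based
#' throughout, matching the `"start:step:stop"` slice-range notation.
#'
#' @param data 3D numeric array `[row, col, slice]` with values in `[0, 255]`;
#'   a matrix is promoted to a single-slice volume.
#' @param voxel_size numeric length-3 `(z, y, x)` voxel size in nm.
#' @return An object of class `VolumeStack` (an integer 3D array).
#' @export
volume_stack <- function(data, voxel_size = c(z = 50, y = 10, x = 10)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array [row, col, slice]")
  if (any(data < 0 | data > 255, na.rm = TRUE))
    stop("intensities must lie within [0, 255]")
  storage.mode(data) <- "integer"
  structure(data, voxel_size = as.numeric(voxel_size),
            class = c("VolumeStack", "array"))
}

#' Construct a four-class label volume
#'
#' @param data 3D integer array `[row, col, slice]` over the 4-code alphabet
#'   (see [class_codes()]); a matrix is promoted to one slice.
#' @param voxel_size numeric length-3 `(z, y, x)` voxel size in nm.
#' @return An object of class `LabelVolume`.
#' @export
label_volume <- function(data, voxel_size = c(z = 50, y = 10, x = 10)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("label data must be a 3D array [row, col, slice]")
  u <- unique(as.vector(data))
  if (!all(u %in% CLASS_CODES))
    stop("label alphabet error: codes outside {0,1,2,3}: ",
         paste(setdiff(u, CLASS_CODES), collapse = ", "))
  storage.mode(data) <- "integer"
  structure(data, voxel_size = as.numeric(voxel_size),
            class = c("LabelVolume", "array"))
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("VolumeStack: %d x %d pixels, %d slice(s), voxel %s nm (z,y,x)\n",
              d[1], d[2], d[3],
              paste(attr(x, "voxel_size"), collapse = " x ")))
  cat(sprintf("  intensity range [%d, %d]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x)
  tab <- tabulate(as.vector(x) + 1L, nbins = 4L)
  cat(sprintf("LabelVolume: %d x %d pixels, %d slice(s)\n", d[1], d[2], d[3]))
  cat("  class voxel counts:\n")
  for (i in seq_along(CLASS_CODES))
    cat(sprintf("    %d (%s): %d\n", CLASS_CODES[i], names(CLASS_CODES)[i], tab[i]))
  invisible(x)
}

n_slices <- function(v) dim(v)[3L]

#' Parse a 1-based inclusive slice range
#'
#' Slice ranges use the `"start:step:stop"` dialect, e.g. `"101:2:180"` for
#' every other slice from 101 to 179 (the stop is included only when it lies
#' on the lattice). `"a:b"` means step 1 and `"a"` a single slice.
#'
#' @param spec character scalar, `"a:s:b"`, `"a:b"` or `"a"`.
#' @return Integer vector of 1-based slice indices.
#' @examples
#' length(parse_slice_range("101:2:180"))  # 40
#' length(parse_slice_range("230:10:370")) # 15
#' @export
parse_slice_range <- function(spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  if (!is.character(spec) || length(spec) != 1L)
    stop("slice range must be a single string like \"101:2:180\"")
  parts <- strsplit(trimws(spec), ":", fixed = TRUE)[[1L]]
  if (!length(parts) %in% 1:3 || any(!grepl("^-?[0-9]+$", parts)))
    stop("malformed slice range: ", spec)
  nums <- as.integer(parts)
  if (length(nums) == 1L) return(nums)
  if (length(nums) == 2L) { a <- nums[1]; s <- 1L; b <- nums[2] }
  else { a <- nums[1]; s <- nums[2]; b <- nums[3] }
  if (s < 1L) stop("slice-range step must be >= 1")
  if (a > b) stop("slice-range start must not exceed stop")
  if (a < 1L) stop("slice indices are 1-based")
  seq.int(a, b, by = s)
}

read_slice_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, all = TRUE),
    png = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (is.list(img)) img else list(img)
}

plane_to_int <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1L]   # drop color channels if any
  m <- round(p * 255)
  storage.mode(m) <- "integer"
  m
}

#' Read an image or label stack
#'
#' Reads a multi-page TIFF, a single TIFF/PNG, or a directory of
#' lexicographically ordered single-slice images into a [volume_stack()] or
#' [label_volume()]. Label reads validate the 4-code alphabet.
#'
#' @param path file or directory.
#' @param kind `"image"` or `"label"`.
#' @param voxel_size voxel size metadata passed to the constructor.
#' @return `VolumeStack` or `LabelVolume`.
#' @export
read_stack <- function(path, kind = c("image", "label"),
                       voxel_size = c(z = 50, y = 10, x = 10)) {
  kind <- match.arg(kind)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG slices found in ", path)
    planes <- unlist(lapply(files, read_slice_file), recursive = FALSE)
  } else if (file.exists(path)) {
    planes <- read_slice_file(path)
  } else stop("path does not exist: ", path)
  mats <- lapply(planes, plane_to_int)
  dims <- vapply(mats, function(m) dim(m)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension error: slices differ in shape")
  arr <- array(unlist(mats), dim = c(dims[1, 1], dims[2, 1], length(mats)))
  if (kind == "image") volume_stack(arr, voxel_size)
  else label_volume(arr, voxel_size)
}

#' Write an image or label stack
#'
#' Writes either a multi-page TIFF (`format = "tiff"`, path is a file) or a
#' directory of per-slice PNG/TIFF files. Round-trips through [read_stack()]
#' bit-exactly for 8-bit data.
#'
#' @param volume `VolumeStack` or `LabelVolume`.
#' @param path output file (multi-page TIFF) or directory (per-slice files).
#' @param format `"tiff"` or `"png"` (`"png"` forces per-slice files).
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L || d[3] == 0L || d[1] == 0L)
    stop("cannot write an empty volume")
  planes <- lapply(seq_len(d[3]), function(k)
    matrix(as.numeric(volume[, , k]) / 255, d[1], d[2]))
  if (format == "tiff" && !grepl("/$", path) && !dir.exists(path)) {
    ok <- tryCatch(tiff::writeTIFF(planes, path, bits.per.sample = 8L),
                   error = function(e) stop("I/O error writing ", path, ": ",
                                            conditionMessage(e)))
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    ext <- if (format == "png") "png" else "tif"
    for (k in seq_len(d[3])) {
      f <- file.path(path, sprintf("slice_%04d.%s", k, ext))
      if (format == "png") png::writePNG(planes[[k]], f)
      else tiff::writeTIFF(planes[[k]], f, bits.per.sample = 8L)
    }
  }
  invisible(path)
}

#' Export a label map as an RGB overlay PNG
#'
#' Cells are shaded red, nuclei green and the nuclear envelope blue, over the
#' grayscale image when one is given.
#'
#' @param labels 2D label matrix (4-code alphabet).
#' @param path output PNG path.
#' @param image optional 2D intensity matrix (0-255) to shade.
#' @param alpha overlay opacity in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(labels, path, image = NULL, alpha = 0.5) {
  if (length(dim(labels)) == 3L && dim(labels)[3] == 1L) labels <- labels[, , 1]
  base <- if (is.null(image)) matrix(1, nrow(labels), ncol(labels))
          else as.matrix(image) / 255
  rgb <- array(rep(base, 3L), dim = c(dim(base), 3L))
  tint <- list(`1` = c(1, 0, 0), `3` = c(0, 1, 0), `2` = c(0, 0, 1))
  for (cls in names(tint)) {
    m <- labels == as.integer(cls)
    for (ch in 1:3)
      rgb[, , ch][m] <- (1 - alpha) * rgb[, , ch][m] + alpha * tint[[cls]][ch]
  }
  png::writePNG(rgb, path)
  invisible(path)
}
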