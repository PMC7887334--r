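#' @useDynLib pxsal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @import dplyr
NULL

#' Image records
#'
#' A grayscale image together with the provenance needed to map raw-image
#' coordinates into preprocessed coordinates: original size, symmetric zero-pad
#' offsets, and the resize scale factor. Pixel values lie in `[0, 1]`.
#'
#' Coordinate convention used throughout the package: `x` is the column index,
#' `y` the row index, both 0-based with the origin at the top-left pixel and
#' points located at pixel centres. A raw-image point maps to the preprocessed
#' image as `(p + pad) * scale` on each axis (align-corners resizing).
#'
#' @param pixels numeric matrix in `[0, 1]`, rows = y, columns = x.
#' @param orig_width,orig_height size of the image before padding/resizing.
#' @param pad_x,pad_y zero-pad offsets (pixels added on the left/top).
#' @param scale resize factor applied after padding.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, orig_width = ncol(pixels),
                         orig_height = nrow(pixels),
                         pad_x = 0, pad_y = 0, scale = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) == 0 || ncol(pixels) == 0) {
    abort("`pixels` must have nonzero dimensions.")
  }
  structure(
    list(pixels = pixels, orig_width = orig_width, orig_height = orig_height,
         pad_x = pad_x, pad_y = pad_y, scale = scale),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %d x %d (orig %d x %d, pad %g/%g, scale %g)\n",
              nrow(x$pixels), ncol(x$pixels), x$orig_height, x$orig_width,
              x$pad_y, x$pad_x, x$scale))
  invisible(x)
}

#' @export
dim.image_record <- function(x) dim(x$pixels)

#' Read a grayscale PNG image
#'
#' Reads 8- or 16-bit PNGs; multi-channel images are converted to grayscale by
#' channel averaging.
#'
#' @param path PNG file path.
#' @return An [image_record()] with identity provenance.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , seq_len(min(3, dim(px)[3])), drop = FALSE], c(1, 2), mean)
  image_record(px)
}

#' Write an image record (or matrix) as an 8-bit grayscale PNG
#'
#' @param image an [image_record()] or numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  # quantize explicitly so regeneration is byte-identical
  px <- round(px * 255) / 255
  png::writePNG(px, target = path)
  invisible(path)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed < 2^31 from a master seed and a stream index.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) s <- (s * 48271 + as.double(k) * 1103 + 1) %% 2147483629
  as.integer(s)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
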