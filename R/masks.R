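#' Supervision-mask configuration
#'
#' Point annotations are converted into binary disk masks: every pixel whose
#' centre lies within `radius_s` of any annotation point is 1, all others 0.
#' The full-resolution mask is then downsampled to each pyramid level so each
#' annotation point supervises every level.
#'
#' @param radius_s disk radius in pixels at `mask_size` resolution (default 75
#'   at 1024, the empirical radius of the point-to-disk supervision scheme).
#' @param mask_size side of the full-resolution mask (default 1024).
#' @param pyramid_levels number of levels K (default 4).
#' @param level_sizes strictly increasing level side lengths, each dividing
#'   `mask_size` (default 32, 64, 128, 256, i.e. strides 32..4).
#' @param downsample `"max"` (block max-pooling; positive-preserving so small
#'   disks survive at the coarsest level) or `"area_threshold"` (block
#'   mean of at least 0.5).
#' @return A `mask_config` list.
#' @export
mask_config <- function(radius_s = 75, mask_size = 1024, pyramid_levels = 4,
                        level_sizes = mask_size / c(32, 16, 8, 4),
                        downsample = c("max", "area_threshold")) {
  downsample <- match.arg(downsample)
  if (radius_s <= 0) abort("`radius_s` must be > 0.")
  if (length(level_sizes) != pyramid_levels) {
    abort("`level_sizes` must have `pyramid_levels` entries.")
  }
  if (any(diff(level_sizes) <= 0)) abort("`level_sizes` must be strictly increasing.")
  if (any(mask_size %% level_sizes != 0)) {
    abort("each level size must divide `mask_size`.")
  }
  structure(list(radius_s = radius_s, mask_size = as.integer(mask_size),
                 pyramid_levels = as.integer(pyramid_levels),
                 level_sizes = as.integer(level_sizes), downsample = downsample),
            class = "mask_config")
}

# mask_config matched to a model input size: radius scales with the image
mask_config_for_input <- function(input_size, radius_s = 75 * input_size / 1024,
                                  downsample = "max") {
  mask_config(radius_s = radius_s, mask_size = input_size,
              level_sizes = input_size / c(32, 16, 8, 4), downsample = downsample)
}

#' Rasterize annotation points into a binary disk mask
#'
#' Pixel `(i, j)` is 1 iff the Euclidean distance from its centre to any
#' annotation point is at most `radius_s` (inclusive); overlapping disks take
#' their union. Points use 0-based pixel-centre coordinates.
#'
#' @param points tibble/data frame with `x`, `y` columns, or a 2-column
#'   matrix; zero rows give an all-zero mask.
#' @param mask_size side length of the square mask.
#' @param radius_s disk radius in pixels.
#' @return Binary (0/1) `mask_size` x `mask_size` matrix.
#' @export
points_to_mask <- function(points, mask_size, radius_s) {
  if (mask_size < 1) abort("`mask_size` must be >= 1.")
  if (radius_s <= 0) abort("`radius_s` must be > 0.")
  pts <- as_point_matrix(points)
  m <- matrix(0, mask_size, mask_size)
  if (nrow(pts) == 0) return(m)
  if (any(pts[, 1] < 0 | pts[, 1] >= mask_size |
          pts[, 2] < 0 | pts[, 2] >= mask_size)) {
    abort(sprintf("annotation point outside the %d-pixel grid; points must be in preprocessed coordinates.",
                  mask_size))
  }
  coords <- 0:(mask_size - 1)
  r2 <- radius_s^2
  for (i in seq_len(nrow(pts))) {
    dx2 <- (coords - pts[i, 1])^2   # per column
    dy2 <- (coords - pts[i, 2])^2   # per row
    m <- pmax(m, (outer(dy2, dx2, `+`) <= r2) * 1)
  }
  m
}

as_point_matrix <- function(points) {
  if (is.null(points)) return(matrix(numeric(0), ncol = 2))
  if (is.data.frame(points)) {
    return(cbind(points$x, points$y))
  }
  if (is.matrix(points)) return(points)
  abort("`points` must be a data frame with x/y columns or a 2-column matrix.")
}

#' Downsample a binary mask to a coarser grid
#'
#' Block pooling with block side `nrow(mask) / target_size`: under `"max"` an
#' output pixel is 1 iff any pixel of its block is 1 (positive-preserving);
#' under `"area_threshold"` iff at least half the block is 1.
#'
#' @param mask binary square matrix.
#' @param target_size output side length; must divide the mask side.
#' @param method `"max"` or `"area_threshold"`.
#' @return Binary `target_size` x `target_size` matrix.
#' @export
downsample_mask <- function(mask, target_size, method = c("max", "area_threshold")) {
  method <- match.arg(method)
  S <- nrow(mask)
  if (S %% target_size != 0) {
    abort("`target_size` must divide the mask side length (no fractional resampling).")
  }
  block <- S / target_size
  if (block == 1) return(mask)
  if (method == "max") {
    block_reduce_cpp(mask, as.integer(block), 0L)
  } else {
    (block_reduce_cpp(mask, as.integer(block), 1L) >= 0.5) * 1
  }
}

#' Build the multiscale supervision-mask pyramid
#'
#' Rasterizes the annotation points once at full resolution and downsamples to
#' every pyramid level, so each annotation point is positive at every level.
#'
#' @param annotations tibble with `x`, `y` columns (preprocessed coordinates),
#'   possibly empty.
#' @param config a [mask_config()].
#' @return A `supervision_pyramid`: list with `masks` (binary matrices, coarse
#'   to fine) and `omega` (per-level pixel counts).
#' @export
build_supervision_pyramid <- function(annotations, config = mask_config()) {
  stopifnot(inherits(config, "mask_config"))
  full <- points_to_mask(annotations, config$mask_size, config$radius_s)
  masks <- lapply(config$level_sizes, function(s) {
    downsample_mask(full, s, config$downsample)
  })
  structure(list(masks = masks,
                 omega = as.numeric(config$level_sizes)^2,
                 level_sizes = config$level_sizes),
            class = "supervision_pyramid")
}

#' @export
print.supervision_pyramid <- function(x, ...) {
  cat("<supervision_pyramid> levels:",
      paste(x$level_sizes, collapse = ", "),
      "| positives:", paste(vapply(x$masks, sum, numeric(1)), collapse = ", "),
      "\n")
  invisible(x)
}
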