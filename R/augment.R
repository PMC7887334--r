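#' Preprocess a raw image: pad to square, resize
#'
#' The short axis is zero-padded symmetrically to a square (the extra pixel of
#' an odd difference goes to the right/bottom), then the square is resized to
#' `target_size` with bilinear interpolation under the align-corners
#' convention. The pad offsets and the point scale factor
#' `scale = (target_size - 1) / (side - 1)` are recorded so raw annotation
#' coordinates map into preprocessed coordinates as
#' `p_pre = (p_raw + pad) * scale`, keeping corner pixel centres inside the
#' canvas.
#'
#' @param raw_image numeric matrix or [image_record()].
#' @param target_size output side in pixels.
#' @return An [image_record()] of side `target_size` with provenance fields.
#' @export
preprocess_image <- function(raw_image, target_size = 1024) {
  px <- if (inherits(raw_image, "image_record")) raw_image$pixels else raw_image
  h <- nrow(px); w <- ncol(px)
  if (is.null(h) || h == 0 || w == 0) abort("raw image has a zero dimension.")
  side <- max(h, w)
  pad_x <- floor((side - w) / 2)
  pad_y <- floor((side - h) / 2)
  sq <- matrix(0, side, side)
  sq[pad_y + seq_len(h), pad_x + seq_len(w)] <- px
  scale <- (target_size - 1) / (side - 1)
  out <- if (side == target_size) sq else {
    warp_matrix(sq, affine_scale_resize(side, target_size),
                target_size, target_size, fill = 0)
  }
  image_record(out, orig_width = w, orig_height = h,
               pad_x = pad_x, pad_y = pad_y, scale = scale)
}

# align-corners resize transform: p' = p * (out - 1) / (in - 1), so corner
# pixel centres map exactly onto corner pixel centres
affine_scale_resize <- function(side_in, side_out) {
  k <- (side_out - 1) / (side_in - 1)
  affine_new(diag(2) * k, c(0, 0))
}

#' Map raw-image points into preprocessed coordinates
#'
#' @param points tibble with `x`, `y` (raw-image, 0-based) or 2-column matrix.
#' @param record the [image_record()] returned by [preprocess_image()].
#' @return Tibble with mapped `x`, `y` (other columns preserved).
#' @export
map_points_to_preprocessed <- function(points, record) {
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0) return(tibble(x = numeric(0), y = numeric(0)))
  x <- (pts[, 1] + record$pad_x) * record$scale
  y <- (pts[, 2] + record$pad_y) * record$scale
  out <- tibble(x = x, y = y)
  if (is.data.frame(points)) {
    extra <- points[setdiff(names(points), c("x", "y"))]
    out <- dplyr::bind_cols(out, extra)
  }
  out
}

#' Augmentation specifications
#'
#' A spec fully determines one spatial-plus-intensity transform and its
#' spatial inverse: translation, isotropic rescaling, horizontal flip,
#' rotation about the image centre, and brightness/contrast jitter.
#'
#' @param dx,dy translation in pixels.
#' @param scale rescaling ratio.
#' @param hflip logical, horizontal mirror.
#' @param rotation degrees about the image centre.
#' @param brightness,contrast intensity ratios (1 = unchanged).
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(dx = 0, dy = 0, scale = 1, hflip = FALSE,
                              rotation = 0, brightness = 1, contrast = 1) {
  structure(list(dx = dx, dy = dy, scale = scale, hflip = hflip,
                 rotation = rotation, brightness = brightness,
                 contrast = contrast),
            class = "augmentation_spec")
}

is_identity_spec <- function(spec) {
  spec$dx == 0 && spec$dy == 0 && spec$scale == 1 && !spec$hflip &&
    spec$rotation == 0 && spec$brightness == 1 && spec$contrast == 1
}

# the forward point transform of a spec on a size-S image:
# hflip, then rotation+scale about the centre, then translation
spec_affine <- function(spec, S) {
  af <- affine_identity()
  if (isTRUE(spec$hflip)) af <- affine_compose(affine_hflip(S), af)
  if (spec$rotation != 0 || spec$scale != 1) {
    af <- affine_compose(affine_rot_scale(spec$rotation, spec$scale, S, S), af)
  }
  if (spec$dx != 0 || spec$dy != 0) {
    af <- affine_compose(affine_translate(spec$dx, spec$dy), af)
  }
  af
}

#' Sample a random augmentation
#'
#' Each field is uniform over its configured range. Ranges default to the
#' full-scale training settings (translation within ±100 px at a 1024 input,
#' scale 0.9–1.1, rotation ±15°, brightness/contrast 0.75–1.25, flip
#' probability 0.5); pixel ranges scale linearly with `input_size`.
#'
#' @param config a [train_config()].
#' @param seed integer seed; the draw is reproducible from it.
#' @param input_size image side the pixel ranges refer to.
#' @return An [augmentation_spec()].
#' @export
sample_augmentation <- function(config = train_config(), seed = 1,
                                input_size = config$input_size) {
  r <- config$augmentation
  px_scale <- input_size / 1024
  with_seed(seed, {
    augmentation_spec(
      dx = stats::runif(1, -r$translate_px, r$translate_px) * px_scale,
      dy = stats::runif(1, -r$translate_px, r$translate_px) * px_scale,
      scale = stats::runif(1, r$scale[1], r$scale[2]),
      hflip = stats::runif(1) < r$hflip_prob,
      rotation = stats::runif(1, r$rotation[1], r$rotation[2]),
      brightness = stats::runif(1, r$brightness[1], r$brightness[2]),
      contrast = stats::runif(1, r$contrast[1], r$contrast[2]))
  })
}

#' Apply an augmentation to an image and its annotation points
#'
#' Spatial components warp the image (bilinear, zero fill) and map the points
#' through the same affine transform; points leaving the canvas are dropped
#' (the count is attached as attribute `"dropped"`). Brightness multiplies
#' intensities and contrast stretches about mid-gray; the result is clipped to
#' `[0, 1]`.
#'
#' @param image [image_record()] or matrix.
#' @param points tibble with `x`, `y` (may be empty).
#' @param spec an [augmentation_spec()].
#' @return List with `image` ([image_record()]) and `points` (tibble).
#' @export
apply_augmentation <- function(image, points, spec) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  S <- nrow(px)
  af <- spec_affine(spec, S)
  out_px <- if (is_identity_spatial(spec)) px else warp_matrix(px, af, fill = 0)
  out_px <- apply_intensity(out_px, spec)
  pts <- as_point_matrix(points)
  dropped <- 0L
  if (nrow(pts) > 0) {
    mapped <- affine_apply_points(af, pts)
    keep <- mapped[, 1] >= 0 & mapped[, 1] <= S - 1 &
            mapped[, 2] >= 0 & mapped[, 2] <= S - 1
    dropped <- sum(!keep)
    out_pts <- tibble(x = mapped[keep, 1], y = mapped[keep, 2])
    if (is.data.frame(points) && ncol(points) > 2) {
      extra <- points[keep, setdiff(names(points), c("x", "y")), drop = FALSE]
      out_pts <- dplyr::bind_cols(out_pts, extra)
    }
  } else {
    out_pts <- tibble(x = numeric(0), y = numeric(0))
  }
  attr(out_pts, "dropped") <- dropped
  rec <- if (inherits(image, "image_record")) {
    image_record(out_px, image$orig_width, image$orig_height,
                 image$pad_x, image$pad_y, image$scale)
  } else image_record(out_px)
  list(image = rec, points = out_pts)
}

is_identity_spatial <- function(spec) {
  spec$dx == 0 && spec$dy == 0 && spec$scale == 1 && !spec$hflip &&
    spec$rotation == 0
}

apply_intensity <- function(px, spec) {
  if (spec$brightness != 1) px <- px * spec$brightness
  if (spec$contrast != 1) px <- (px - 0.5) * spec$contrast + 0.5
  if (spec$brightness != 1 || spec$contrast != 1) px <- pmin(pmax(px, 0), 1)
  px
}
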