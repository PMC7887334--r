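#' Test-time-augmentation configuration
#'
#' Exactly five predefined augmentations drawn from the horizontal-flip /
#' rotation / contrast families; the first is the identity and every spec is
#' spatially invertible. The default set is identity, horizontal flip,
#' rotation +10°, rotation -10°, and contrast 1.15.
#'
#' @param specs list of 5 [augmentation_spec()]s.
#' @return A `tta_config`.
#' @export
tta_config <- function(specs = list(
  augmentation_spec(),
  augmentation_spec(hflip = TRUE),
  augmentation_spec(rotation = 10),
  augmentation_spec(rotation = -10),
  augmentation_spec(contrast = 1.15))) {
  if (length(specs) != 5) abort("a TTA configuration holds exactly 5 specs.")
  if (!is_identity_spec(specs[[1]])) abort("the first TTA spec must be the identity.")
  for (s in specs) {
    if (s$dx != 0 || s$dy != 0) {
      abort("TTA specs use only flip/rotation/scale/contrast (no translation).")
    }
  }
  structure(list(specs = specs), class = "tta_config")
}

#' Invert the spatial part of an augmentation on a saliency map
#'
#' Applies the inverse flip/rotation/scale so member maps align with the
#' un-augmented input; intensity components (brightness/contrast) are spatial
#' no-ops. Pixels with no source after inversion are filled with the map's
#' minimum, so borders do not masquerade as confident calls in either
#' direction.
#'
#' @param map numeric matrix (saliency in sigmoid or logit domain).
#' @param spec the [augmentation_spec()] that produced the map's input.
#' @return Matrix of the same size.
#' @export
invert_augmentation <- function(map, spec) {
  if (spec$dx != 0 || spec$dy != 0) {
    abort("translation is not an invertible TTA component here.")
  }
  if (is_identity_spatial(spec)) return(map)
  s <- nrow(map)
  af <- affine_identity()
  if (isTRUE(spec$hflip)) af <- affine_compose(affine_hflip(s), af)
  if (spec$rotation != 0 || spec$scale != 1) {
    af <- affine_compose(affine_rot_scale(spec$rotation, spec$scale, s, s), af)
  }
  inv <- affine_invert(af)
  warp_matrix(map, inv, fill = min(map))
}

#' Bagged test-time-augmentation ensemble prediction
#'
#' Every fold model is applied to every augmented copy of the input (5 models
#' x 5 augmentations = 25 members by default). Each member contributes the
#' maximum of its sigmoid-transformed output map; the image-level probability
#' is the plain mean of the member maxima:
#' \deqn{p = \frac{1}{N}\sum_{n=1}^{N} \max_{i,j} \sigma(P^n(i,j)).}
#' For localization, each member map is inverse-transformed to align with the
#' input and the aligned maps are averaged pixel-wise into `fused_map`.
#'
#' @param models list of `detector_model`s sharing one configuration.
#' @param image [image_record()] (or matrix) at the models' input size.
#' @param tta a [tta_config()].
#' @param level optional output-level override passed to the member maps.
#' @return An `ensemble_output`: `probability`, `member_maps` (the raw member
#'   sigmoid maps, before inversion, so `probability` is exactly the mean of
#'   their maxima), `fused_map` (aligned average), `n_members`.
#' @export
ensemble_predict <- function(models, image, tta = tta_config(), level = NULL) {
  if (length(models) < 1) abort("need at least one model.")
  cfg0 <- models[[1]]$config
  for (m in models) {
    for (fld in c("backbone", "input_size", "pyramid_levels", "output_level")) {
      if (!identical(m$config[[fld]], cfg0[[fld]])) {
        abort(sprintf("heterogeneous model configs: field `%s` differs.", fld))
      }
    }
  }
  rec <- if (inherits(image, "image_record")) image else image_record(image)
  member_maps <- list()
  aligned_sum <- NULL
  maxima <- numeric(0)
  for (m in models) {
    for (spec in tta$specs) {
      aug <- apply_augmentation(rec, NULL, spec)
      pyr <- forward_saliency(m, aug$image)
      smap <- sigmoid(output_map(pyr, level))
      member_maps[[length(member_maps) + 1]] <- smap
      maxima <- c(maxima, max(smap))
      aligned <- invert_augmentation(smap, spec)
      aligned_sum <- if (is.null(aligned_sum)) aligned else aligned_sum + aligned
    }
  }
  n <- length(member_maps)
  structure(list(probability = mean(maxima),
                 member_maps = member_maps,
                 member_maxima = maxima,
                 fused_map = aligned_sum / n,
                 n_members = n),
            class = "ensemble_output")
}

#' @export
print.ensemble_output <- function(x, ...) {
  cat(sprintf("<ensemble_output> p = %.4f from %d members (fused %dx%d)\n",
              x$probability, x$n_members, nrow(x$fused_map), ncol(x$fused_map)))
  invisible(x)
}

#' Score every image of a manifest with an ensemble
#'
#' @param models list of fold models (e.g. from [run_cross_validation()]).
#' @param manifest a `dataset_manifest`.
#' @param tta a [tta_config()].
#' @param level optional output-level override for the member maps.
#' @param images optional pre-loaded raw images.
#' @return A scored-cohort tibble: `image_id`, `score`, `label`, `categories`
#'   (semicolon-separated, `""` for negatives).
#' @export
predict_manifest <- function(models, manifest, tta = tta_config(),
                             level = NULL, images = NULL) {
  if (is.null(images)) images <- load_manifest_images(manifest)
  S <- models[[1]]$config$input_size
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- preprocess_image(images[[i]], S)
    eo <- ensemble_predict(models, rec, tta, level = level)
    cats <- unique(manifest$points[[i]]$category)
    tibble(image_id = manifest$image[i], score = eo$probability,
           label = manifest$label[i],
           categories = paste(cats[!is.na(cats)], collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Render a localization overlay
#'
#' Upsamples the fused saliency map to the image size, maps it through a
#' red-emphasis blend (red where probability is high) and writes the
#' alpha-blended result as an RGB PNG of the input's dimensions.
#'
#' @param image [image_record()] or grayscale matrix.
#' @param fused_map saliency map in `[0, 1]` aligned to the image.
#' @param out_path output PNG path.
#' @param alpha maximum blend weight of the overlay.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(image, fused_map, out_path, alpha = 0.6) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  S <- nrow(px)
  up <- if (nrow(fused_map) == S) fused_map else {
    warp_matrix(fused_map, affine_scale_resize(nrow(fused_map), S), S, S,
                fill = min(fused_map))
  }
  up <- pmin(pmax(up, 0), 1)
  a <- alpha * up
  rgb <- array(0, dim = c(S, ncol(px), 3))
  rgb[, , 1] <- (1 - a) * px + a          # red channel saturates with saliency
  rgb[, , 2] <- (1 - a) * px
  rgb[, , 3] <- (1 - a) * px
  png::writePNG(pmin(pmax(rgb, 0), 1), target = out_path)
  invisible(out_path)
}

#' Locate the peak of a saliency map in input-image coordinates
#'
#' A map at stride `input_size / nrow(map)` has its (i, j) cell centred at
#' input coordinate `(j * stride + (stride - 1) / 2, i * stride + (stride -
#' 1) / 2)` (0-based). Returns the centre of the maximum cell; ties break
#' toward the first in column-major order.
#'
#' @param map saliency matrix (fused or single-member).
#' @param input_size side of the input image the map aligns to.
#' @return Tibble with `x`, `y` (input coordinates) and `value`.
#' @export
saliency_peak <- function(map, input_size) {
  st <- input_size / nrow(map)
  idx <- which.max(map)
  i <- (idx - 1) %% nrow(map)         # 0-based row
  j <- (idx - 1) %/% nrow(map)        # 0-based col
  tibble(x = j * st + (st - 1) / 2, y = i * st + (st - 1) / 2,
         value = map[idx])
}

#' Plot an ensemble output
#'
#' @param object an `ensemble_output`.
#' @param ... unused.
#' @return A ggplot heatmap of the fused localization map.
#' @importFrom ggplot2 autoplot ggplot aes geom_raster scale_fill_gradient
#'   coord_fixed labs theme_minimal
#' @export
autoplot.ensemble_output <- function(object, ...) {
  m <- object$fused_map
  df <- tibble(
    x = rep(0:(ncol(m) - 1), each = nrow(m)),
    y = rep((nrow(m) - 1):0, times = ncol(m)),
    p = as.vector(m))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$p)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "red", limits = c(0, 1)) +
    coord_fixed() +
    labs(title = sprintf("fused saliency (p = %.3f)", object$probability),
         fill = "saliency") +
    theme_minimal()
}
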