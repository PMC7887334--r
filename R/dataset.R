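#' Generate a synthetic phantom dataset
#'
#' Writes `n` phantom PNGs plus a JSON-lines annotation file and returns the
#' dataset manifest as a tibble. The positive count is `round(n *
#' positive_fraction)`; which images are positive is a seeded draw. Positive
#' images carry 1–7 annotation points (median 1, mirroring the skewed
#' point-count distribution of clinical point annotation), negatives carry
#' none. Fully reproducible: identical `(n, positive_fraction, config, seed)`
#' regenerate byte-identical files.
#'
#' @param n number of images (>= 1).
#' @param positive_fraction proportion of images with at least one lesion.
#' @param config a [phantom_config()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param split split tag stored in the manifest (default `"train"`).
#' @return A `dataset_manifest` tibble with columns `image` (path relative to
#'   `out_dir`), `points` (list of tibbles with `x`, `y`, `category`), `label`
#'   (1 = positive), `split`; attributes `out_dir`, `seed`,
#'   `positive_fraction`, `config`.
#' @export
generate_dataset <- function(n, positive_fraction, config = phantom_config(),
                             seed = 1, out_dir, split = "train") {
  if (n < 1) abort("`n` must be >= 1.")
  if (positive_fraction < 0 || positive_fraction > 1) {
    abort("`positive_fraction` must be in [0, 1].")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  n_pos <- round(n * positive_fraction)
  pos_idx <- with_seed(derive_seed(seed, 0), sample.int(n, n_pos))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    phantom <- generate_phantom(config, derive_seed(seed, i, 1))
    k <- 0L
    if (i %in% pos_idx) {
      k <- with_seed(derive_seed(seed, i, 2),
                     min(7L, 1L + stats::rpois(1, 0.45)))
    }
    specs <- sample_lesion_specs(phantom, k, seed = derive_seed(seed, i, 3))
    res <- inject_lesions(phantom, specs)
    fname <- sprintf("img_%05d.png", i)
    write_image(res$image, file.path(out_dir, fname))
    rows[[i]] <- tibble(image = fname, points = list(res$annotations),
                        label = as.integer(k > 0), split = split)
  }
  manifest <- dplyr::bind_rows(rows)
  class(manifest) <- c("dataset_manifest", class(manifest))
  attr(manifest, "out_dir") <- out_dir
  attr(manifest, "seed") <- seed
  attr(manifest, "positive_fraction") <- positive_fraction
  attr(manifest, "config") <- config
  write_annotations(manifest, file.path(out_dir, "annotations.jsonl"))
  manifest
}

#' Write point annotations as JSON-lines
#'
#' One object per image: `{"image": "...", "points": [[x, y], ...],
#' "categories": ["fracture_line", ...]}`, with empty lists for negatives.
#'
#' @param manifest a `dataset_manifest` tibble (or any tibble with `image` and
#'   `points` columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(manifest, path) {
  lines <- vapply(seq_len(nrow(manifest)), function(i) {
    pts <- manifest$points[[i]]
    obj <- list(
      image = manifest$image[i],
      points = if (nrow(pts) == 0) list() else
        lapply(seq_len(nrow(pts)), function(j) c(pts$x[j], pts$y[j])),
      categories = if (nrow(pts) == 0) list() else as.list(pts$category))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines annotation file into a manifest tibble
#'
#' @param path annotation file.
#' @param dir directory the image paths are relative to (defaults to the
#'   annotation file's directory).
#' @return A `dataset_manifest` tibble (see [generate_dataset()]).
#' @export
read_annotations <- function(path, dir = dirname(path)) {
  lines <- readLines(path)
  rows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    np <- length(obj$points)
    pts <- if (np == 0) {
      tibble(x = numeric(0), y = numeric(0), category = character(0))
    } else {
      tibble(
        x = vapply(obj$points, function(p) as.numeric(p[[1]]), numeric(1)),
        y = vapply(obj$points, function(p) as.numeric(p[[2]]), numeric(1)),
        category = if (length(obj$categories) == np) {
          vapply(obj$categories, as.character, character(1))
        } else rep(NA_character_, np))
    }
    tibble(image = obj$image, points = list(pts),
           label = as.integer(np > 0), split = "train")
  })
  manifest <- dplyr::bind_rows(rows)
  class(manifest) <- c("dataset_manifest", class(manifest))
  attr(manifest, "out_dir") <- dir
  manifest
}

manifest_image_path <- function(manifest, i) {
  file.path(attr(manifest, "out_dir"), manifest$image[i])
}

#' Load the images of a manifest into memory
#'
#' @param manifest a `dataset_manifest`.
#' @return List of [image_record()]s, in manifest order.
#' @export
load_manifest_images <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    read_image(manifest_image_path(manifest, i))
  })
}
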