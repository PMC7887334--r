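#' Configuration for synthetic pelvis phantoms
#'
#' Describes a pelvis-like phantom: a bright ring (the pelvic annulus), two
#' femoral heads, and two femoral shafts on a dark background, softened by
#' Gaussian blur and corrupted by additive Gaussian noise. The phantom is not
#' anatomically realistic; it provides bright bone-like primitives with edges
#' so that lesion detection is nontrivial.
#'
#' Geometry is specified in fractions of the image side so one configuration
#' works at any size. Defaults put all primitives inside the canvas.
#'
#' @param image_size pixels per side; at least 64 and divisible by 32.
#'   256 is the desk-scale default; 1024 matches full-scale radiographs.
#' @param bone_intensity,background_intensity gray levels in `[0, 1]` with
#'   `background_intensity < bone_intensity`.
#' @param ring_geometry list with `cx`, `cy`, `r_outer`, `r_inner` (fractions
#'   of the side).
#' @param femur_geometry list with `head_r`, `shaft_r`, and per-side socket and
#'   shaft-end positions (fractions of the side).
#' @param noise_sd additive Gaussian noise standard deviation (gray levels).
#' @param blur_sigma Gaussian smoothing sigma in pixels; `NULL` scales with the
#'   image (`0.006 * image_size`).
#' @param jitter geometry jitter amplitude (fraction of side) applied per seed
#'   so phantoms vary between images; 0 disables.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 256,
                           bone_intensity = 0.85,
                           background_intensity = 0.12,
                           ring_geometry = list(cx = 0.50, cy = 0.42,
                                                r_outer = 0.33, r_inner = 0.23),
                           femur_geometry = list(
                             head_r = 0.065, shaft_r = 0.042,
                             socket_x = 0.27, socket_y = 0.55,
                             shaft_x = 0.37, shaft_y = 0.94),
                           noise_sd = 0.02,
                           blur_sigma = NULL,
                           jitter = 0.012) {
  if (image_size < 64 || image_size %% 32 != 0) {
    abort("`image_size` must be >= 64 and divisible by 32.")
  }
  if (!(background_intensity >= 0 && background_intensity < bone_intensity &&
        bone_intensity <= 1)) {
    abort("need 0 <= background_intensity < bone_intensity <= 1.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (is.null(blur_sigma)) blur_sigma <- 0.006 * image_size
  cfg <- structure(
    list(image_size = as.integer(image_size),
         bone_intensity = bone_intensity,
         background_intensity = background_intensity,
         ring_geometry = ring_geometry, femur_geometry = femur_geometry,
         noise_sd = noise_sd, blur_sigma = blur_sigma, jitter = jitter),
    class = "phantom_config")
  validate_phantom_geometry(cfg)
  cfg
}

validate_phantom_geometry <- function(cfg) {
  rg <- cfg$ring_geometry
  if (rg$r_inner >= rg$r_outer) abort("ring_geometry: r_inner must be < r_outer.")
  if (rg$cx - rg$r_outer < 0 || rg$cx + rg$r_outer > 1 ||
      rg$cy - rg$r_outer < 0 || rg$cy + rg$r_outer > 1) {
    abort("ring_geometry: annulus extends outside the canvas.")
  }
  fg <- cfg$femur_geometry
  for (fld in c("socket_x", "socket_y", "shaft_x", "shaft_y")) {
    if (fg[[fld]] < 0 || fg[[fld]] > 1) {
      abort(paste0("femur_geometry: field `", fld, "` outside the canvas."))
    }
  }
  if (0.5 - fg$shaft_x - fg$shaft_r < 0 || fg$shaft_y + fg$shaft_r > 1) {
    abort("femur_geometry: shaft primitive extends outside the canvas.")
  }
  invisible(cfg)
}

# Resolve fractional geometry to pixel coordinates, with seeded jitter.
resolve_geometry <- function(cfg, jit = 0) {
  S <- cfg$image_size
  j <- function() if (jit > 0) stats::runif(1, -jit, jit) * S else 0
  rg <- cfg$ring_geometry
  fg <- cfg$femur_geometry
  ring <- list(cx = rg$cx * S + j(), cy = rg$cy * S + j(),
               r_outer = rg$r_outer * S * (1 + if (jit > 0) stats::runif(1, -0.03, 0.03) else 0),
               r_inner = rg$r_inner * S)
  ring$r_inner <- min(ring$r_inner, ring$r_outer - 2)
  sides <- list()
  for (sgn in c(-1, 1)) {
    sides[[length(sides) + 1]] <- list(
      head = c(0.5 * S + sgn * fg$socket_x * S + j(), fg$socket_y * S + j()),
      head_r = fg$head_r * S,
      shaft_a = c(0.5 * S + sgn * (fg$socket_x + 0.01) * S, (fg$socket_y + 0.03) * S),
      shaft_b = c(0.5 * S + sgn * fg$shaft_x * S + j(), fg$shaft_y * S),
      shaft_r = fg$shaft_r * S)
  }
  list(ring = ring, femurs = sides, size = S)
}

# squared distance from every pixel centre to a segment a-b (vectorized)
dist_to_segment <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  tt <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (a[1] + tt * ab[1]))^2 + (py - (a[2] + tt * ab[2]))^2)
}

pixel_grids <- function(S) {
  list(x = matrix(rep(0:(S - 1), each = S), nrow = S),
       y = matrix(rep(0:(S - 1), times = S), nrow = S))
}

# logical bone-support mask for a resolved geometry
geometry_bone_mask <- function(geom) {
  S <- geom$size
  g <- pixel_grids(S)
  r <- sqrt((g$x - geom$ring$cx)^2 + (g$y - geom$ring$cy)^2)
  bone <- r <= geom$ring$r_outer & r >= geom$ring$r_inner
  for (f in geom$femurs) {
    bone <- bone | (sqrt((g$x - f$head[1])^2 + (g$y - f$head[2])^2) <= f$head_r)
    bone <- bone | (dist_to_segment(g$x, g$y, f$shaft_a, f$shaft_b) <= f$shaft_r)
  }
  bone
}

#' Generate a lesion-free pelvis phantom
#'
#' Deterministic given `(config, seed)`: the seed drives geometry jitter and
#' the additive noise field.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return An [image_record()] with the resolved pixel-space geometry attached
#'   as attribute `"geometry"`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1) {
  stopifnot(inherits(config, "phantom_config"))
  S <- config$image_size
  with_seed(seed, {
    geom <- resolve_geometry(config, config$jitter)
    bone <- geometry_bone_mask(geom)
    px <- matrix(config$background_intensity, S, S)
    px[bone] <- config$bone_intensity
    if (config$blur_sigma > 0) px <- gaussian_blur_cpp(px, config$blur_sigma)
    if (config$noise_sd > 0) px <- px + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)
    px <- pmin(pmax(px, 0), 1)
    rec <- image_record(px)
    attr(rec, "geometry") <- geom
    rec
  })
}

#' Bone-support mask of a generated phantom
#'
#' @param image an [image_record()] produced by [generate_phantom()].
#' @return Logical matrix marking pixels on a bone primitive.
#' @export
phantom_bone_mask <- function(image) {
  geom <- attr(image, "geometry")
  if (is.null(geom)) abort("image carries no phantom geometry.")
  geometry_bone_mask(geom)
}

lesion_categories <- c("fracture_line", "fracture_gap", "dislocation",
                       "periprosthetic", "shaft_fracture")

#' Lesion specifications
#'
#' @param category one of `"fracture_line"`, `"fracture_gap"`,
#'   `"dislocation"`, `"periprosthetic"`, `"shaft_fracture"` (mirroring the
#'   clinical finding vocabulary: hip/pelvic fracture lines, displaced
#'   fragments, hip dislocation, periprosthetic fracture, femoral shaft
#'   fracture).
#' @param x,y anchor point (0-based pixel coordinates) on a bone primitive;
#'   this is also the annotation point of the rendered lesion.
#' @param magnitude severity scalar in `(0, 1]` scaling the contrast change.
#' @param orientation lesion orientation in degrees.
#' @return A one-row tibble.
#' @export
lesion_spec <- function(category, x, y, magnitude = 0.7, orientation = 0) {
  category <- match.arg(category, lesion_categories)
  if (magnitude <= 0 || magnitude > 1) abort("`magnitude` must be in (0, 1].")
  tibble(category = category, x = x, y = y,
         magnitude = magnitude, orientation = orientation)
}

#' Sample random lesion specs anchored on bone
#'
#' Anchors are drawn from the phantom's bone support: `shaft_fracture` on a
#' femoral shaft, `dislocation`/`periprosthetic` near a femoral head, other
#' categories anywhere on bone. Category frequencies default to a mix
#' dominated by fracture lines, echoing the clinical predominance of hip and
#' pelvic-area fractures.
#'
#' @param image phantom [image_record()] with geometry.
#' @param n number of lesions.
#' @param seed integer seed.
#' @param categories optional character vector to sample from.
#' @return Tibble of lesion specs (`category`, `x`, `y`, `magnitude`,
#'   `orientation`).
#' @export
sample_lesion_specs <- function(image, n, seed = 1, categories = NULL) {
  geom <- attr(image, "geometry")
  if (is.null(geom)) abort("image carries no phantom geometry.")
  S <- geom$size
  if (n == 0) return(lesion_spec("fracture_line", 0, 0)[0, ])
  probs <- c(fracture_line = 0.45, fracture_gap = 0.2, dislocation = 0.12,
             periprosthetic = 0.08, shaft_fracture = 0.15)
  with_seed(seed, {
    cats <- if (is.null(categories)) {
      sample(names(probs), n, replace = TRUE, prob = probs)
    } else sample(categories, n, replace = TRUE)
    specs <- vector("list", n)
    margin <- round(0.08 * S)
    for (i in seq_len(n)) {
      f <- geom$femurs[[sample(2, 1)]]
      anchor <- switch(
        cats[i],
        shaft_fracture = {
          tt <- stats::runif(1, 0.25, 0.85)
          f$shaft_a + tt * (f$shaft_b - f$shaft_a)
        },
        dislocation = f$head,
        periprosthetic = f$head + c(0, 0.06 * S),
        {
          # on the pelvic ring mid-circle
          th <- stats::runif(1, 0, 2 * pi)
          rmid <- (geom$ring$r_outer + geom$ring$r_inner) / 2
          c(geom$ring$cx + rmid * cos(th), geom$ring$cy + rmid * sin(th))
        })
      anchor <- pmin(pmax(anchor, margin), S - 1 - margin)
      specs[[i]] <- lesion_spec(cats[i], round(anchor[1]), round(anchor[2]),
                                magnitude = stats::runif(1, 0.55, 1.0),
                                orientation = stats::runif(1, 0, 180))
    }
    dplyr::bind_rows(specs)
  })
}

# render one lesion's additive delta onto `delta` (same size as image);
# all edits are later clipped to a disk of radius `extent` around the anchor
render_lesion_delta <- function(spec, S, extent, g) {
  d <- matrix(0, S, S)
  a <- c(spec$x, spec$y)
  th <- spec$orientation * pi / 180
  u <- c(cos(th), sin(th))
  mag <- spec$magnitude
  lw <- max(1.3, S / 110)               # thin-line half width
  seg_in <- function(from, to, w, val) {
    dd <- dist_to_segment(g$x, g$y, from, to) <= w
    d[dd] <<- d[dd] + val
  }
  switch(
    spec$category,
    fracture_line = {
      # jagged dark polyline through the anchor
      v <- c(-u[2], u[1])
      p1 <- a - 0.8 * extent * u
      p2 <- a - 0.25 * extent * u + 0.2 * extent * v
      p3 <- a + 0.25 * extent * u - 0.2 * extent * v
      p4 <- a + 0.8 * extent * u
      seg_in(p1, p2, lw, -0.6 * mag)
      seg_in(p2, p3, lw, -0.6 * mag)
      seg_in(p3, p4, lw, -0.6 * mag)
    },
    fracture_gap = {
      # wider dark band: displaced fragment gap
      seg_in(a - 0.6 * extent * u, a + 0.6 * extent * u, 2.2 * lw, -0.6 * mag)
    },
    dislocation = {
      # head displaced: bright disk offset, dark where it came from
      off <- 0.45 * extent * u
      dd <- sqrt((g$x - (a[1] + off[1]))^2 + (g$y - (a[2] + off[2]))^2) <= 0.45 * extent
      d[dd] <- d[dd] + 0.5 * mag
      dd <- sqrt((g$x - (a[1] - off[1]))^2 + (g$y - (a[2] - off[2]))^2) <= 0.45 * extent
      d[dd] <- d[dd] - 0.5 * mag
    },
    periprosthetic = {
      # bright implant stem plus adjacent dark fracture line
      seg_in(a - 0.7 * extent * u, a + 0.7 * extent * u, 2.5 * lw, 0.6 * mag)
      v <- c(-u[2], u[1])
      b0 <- a + 0.35 * extent * v
      seg_in(b0 - 0.5 * extent * u, b0 + 0.5 * extent * u, lw, -0.6 * mag)
    },
    shaft_fracture = {
      seg_in(a - 0.7 * extent * u, a + 0.7 * extent * u, 1.4 * lw, -0.6 * mag)
    })
  d
}

#' Inject lesions into a phantom
#'
#' Renders one lesion per spec, each centred at its anchor; the anchor is the
#' returned annotation point. All pixel modifications are confined to a disk
#' of radius `0.07 * image_size` around the anchor (comfortably inside the
#' supervision-mask radius at the matching scale). An empty spec list returns
#' the image unchanged with an empty annotation set: a negative example.
#'
#' @param image phantom [image_record()].
#' @param specs tibble of lesion specs (see [lesion_spec()]); may have 0 rows.
#' @param seed integer seed (reserved for stochastic texture; rendering is
#'   currently deterministic given the specs).
#' @return List with `image` (modified [image_record()]) and `annotations`
#'   (tibble with `x`, `y`, `category`, one row per spec).
#' @export
inject_lesions <- function(image, specs, seed = 1) {
  stopifnot(inherits(image, "image_record"))
  px <- image$pixels
  S <- nrow(px)
  if (is.null(specs) || nrow(specs) == 0) {
    return(list(image = image,
                annotations = tibble(x = numeric(0), y = numeric(0),
                                     category = character(0))))
  }
  if (any(specs$x < 0 | specs$x >= S | specs$y < 0 | specs$y >= S)) {
    abort("lesion anchor outside image bounds.")
  }
  extent <- round(0.07 * S)
  g <- pixel_grids(S)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    delta <- render_lesion_delta(sp, S, extent, g)
    within <- sqrt((g$x - sp$x)^2 + (g$y - sp$y)^2) <= extent
    px <- px + delta * within
  }
  px <- pmin(pmax(px, 0), 1)
  out <- image_record(px, image$orig_width, image$orig_height,
                      image$pad_x, image$pad_y, image$scale)
  attr(out, "geometry") <- attr(image, "geometry")
  list(image = out,
       annotations = tibble(x = as.numeric(specs$x), y = as.numeric(specs$y),
                            category = specs$category))
}
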