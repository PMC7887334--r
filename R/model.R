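#' Detector model configuration
#'
#' The detector maps one preprocessed square grayscale image to K saliency
#' logit maps at strides 32, 16, 8 and 4 (coarse to fine): a bottom-up strided
#' convolutional encoder produces feature taps at those strides, a top-down
#' path fuses them (1x1 lateral convolutions, nearest-neighbour upsampling,
#' elementwise addition), and a per-level 1x1 head emits one logit channel.
#'
#' Two named configurations are provided. `"densenet169_fpn"` is the
#' full-scale configuration (1024-pixel input, 256 fusion channels, wide
#' encoder) honouring the published four-level resolution contract of
#' 32/64/128/256-pixel maps; the encoder abstracts the reference backbone
#' behind that contract. `"tiny_fpn"` is a desk-scale configuration (256-pixel
#' default input, narrow encoder) with the same stride schedule. Pretrained
#' encoder weights are not bundled; `pretrained = TRUE` requires a checkpoint
#' via the `weights` argument of [build_model()].
#'
#' @param backbone `"tiny_fpn"` or `"densenet169_fpn"`.
#' @param input_size input side in pixels, divisible by 32; defaults to 256
#'   (tiny) or 1024 (full scale).
#' @param pyramid_levels number of saliency levels K (default 4).
#' @param fpn_channels top-down fusion width; defaults to 16 (tiny) or 256.
#' @param output_level `"coarsest"` (stride-32 map; the image-level
#'   probability heatmap) or `"finest"` (stride-4 map; the localization map).
#' @param pretrained whether encoder weights come from a checkpoint.
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = c("tiny_fpn", "densenet169_fpn"),
                         input_size = NULL, pyramid_levels = 4,
                         fpn_channels = NULL,
                         output_level = c("coarsest", "finest"),
                         pretrained = FALSE) {
  backbone <- match.arg(backbone)
  output_level <- match.arg(output_level)
  defaults <- switch(backbone,
    tiny_fpn = list(input_size = 256, fpn_channels = 16,
                    enc_channels = c(8, 16, 24, 32, 40)),
    densenet169_fpn = list(input_size = 1024, fpn_channels = 256,
                           enc_channels = c(32, 64, 128, 256, 384)))
  if (is.null(input_size)) input_size <- defaults$input_size
  if (is.null(fpn_channels)) fpn_channels <- defaults$fpn_channels
  if (input_size %% 32 != 0) abort("`input_size` must be divisible by 32.")
  if (pyramid_levels != 4) abort("only 4 pyramid levels are supported.")
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 pyramid_levels = as.integer(pyramid_levels),
                 fpn_channels = as.integer(fpn_channels),
                 enc_channels = defaults$enc_channels,
                 output_level = output_level, pretrained = pretrained),
            class = "model_config")
}

init_conv <- function(k, cin, cout) {
  W <- matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              nrow = k * k * cin, ncol = cout)
  list(W = W, b = numeric(cout), k = as.integer(k))
}

#' Build a detector model
#'
#' Parameter initialization (He-scaled normal weights, zero biases) is
#' deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed for initialization.
#' @param weights optional checkpoint path supplying initial parameters
#'   (required when `config$pretrained` is `TRUE`).
#' @return A `detector_model` (config plus parameter list).
#' @export
build_model <- function(config = model_config(), seed = 1, weights = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (isTRUE(config$pretrained) && is.null(weights)) {
    abort("pretrained weights are not bundled with the package; pass a checkpoint via `weights` or set pretrained = FALSE.")
  }
  if (!is.null(weights)) {
    ck <- load_checkpoint(weights)
    return(structure(list(config = config, params = ck$params),
                     class = "detector_model"))
  }
  ch <- config$enc_channels
  params <- with_seed(seed, {
    enc <- list()
    cin <- 1
    for (l in seq_along(ch)) {
      enc[[l]] <- init_conv(3, cin, ch[l])
      cin <- ch[l]
    }
    # levels 1..4 coarse -> fine tap encoder stages 5, 4, 3, 2
    tap_ch <- ch[c(5, 4, 3, 2)]
    lat <- lapply(tap_ch, function(c_in) init_conv(1, c_in, config$fpn_channels))
    head <- lapply(1:4, function(k) {
      hd <- init_conv(1, config$fpn_channels, 1)
      hd$W <- hd$W * 0.1   # temper initial logit scale
      hd
    })
    list(enc = enc, lat = lat, head = head)
  })
  structure(list(config = config, params = params), class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> %s, input %d, %d levels, fpn width %d\n",
              x$config$backbone, x$config$input_size, x$config$pyramid_levels,
              x$config$fpn_channels))
  invisible(x)
}

as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1))

relu <- function(a) { a[a < 0] <- 0; a }

# Full forward pass; returns logits (matrices, coarse -> fine) and, when
# `keep_cache`, the intermediates needed for backprop.
model_forward <- function(model, pixels, keep_cache = FALSE) {
  p <- model$params
  acts <- vector("list", 6)   # a0 .. a5 (post-relu)
  zs <- vector("list", 5)     # pre-relu encoder outputs
  acts[[1]] <- as_cube(pixels)
  for (l in 1:5) {
    z <- conv2d_fwd_cpp(acts[[l]], p$enc[[l]]$W, p$enc[[l]]$b, 3L, 2L, 1L)
    zs[[l]] <- if (keep_cache) z else NULL
    acts[[l + 1]] <- relu(z)
  }
  taps <- list(acts[[6]], acts[[5]], acts[[4]], acts[[3]])  # coarse -> fine
  Ts <- vector("list", 4)
  for (k in 1:4) {
    latk <- conv2d_fwd_cpp(taps[[k]], p$lat[[k]]$W, p$lat[[k]]$b, 1L, 1L, 0L)
    Ts[[k]] <- if (k == 1) latk else latk + upsample2_cpp(Ts[[k - 1]])
  }
  logits <- lapply(1:4, function(k) {
    conv2d_fwd_cpp(Ts[[k]], p$head[[k]]$W, p$head[[k]]$b, 1L, 1L, 0L)[, , 1]
  })
  out <- list(logits = logits)
  if (keep_cache) out$cache <- list(acts = acts, zs = zs, taps = taps, Ts = Ts)
  out
}

# Backward pass: dlogits is a list of matrices (coarse -> fine).
# Returns gradients with the same structure as params.
model_backward <- function(model, fwd, dlogits) {
  p <- model$params
  cache <- fwd$cache
  gh <- vector("list", 4); gl <- vector("list", 4)
  gT <- vector("list", 4)
  for (k in 1:4) {
    bw <- conv2d_bwd_cpp(cache$Ts[[k]], p$head[[k]]$W, as_cube(dlogits[[k]]),
                         1L, 1L, 0L)
    gh[[k]] <- list(W = bw$gW, b = bw$gb)
    gT[[k]] <- bw$gx
  }
  # reverse the top-down chain: T_k = lat_k + up2(T_{k-1})
  gtap <- vector("list", 4)
  for (k in 4:1) {
    bw <- conv2d_bwd_cpp(cache$taps[[k]], p$lat[[k]]$W, gT[[k]], 1L, 1L, 0L)
    gl[[k]] <- list(W = bw$gW, b = bw$gb)
    gtap[[k]] <- bw$gx
    if (k > 1) gT[[k - 1]] <- gT[[k - 1]] + upsample2_bwd_cpp(gT[[k]])
  }
  # encoder: taps (coarse->fine) sit at acts 6, 5, 4, 3
  genc <- vector("list", 5)
  ga <- gtap[[1]]                       # grad wrt acts[[6]]
  for (l in 5:1) {
    gz <- ga * (cache$zs[[l]] > 0)      # relu
    bw <- conv2d_bwd_cpp(cache$acts[[l]], p$enc[[l]]$W, gz, 3L, 2L, 1L)
    genc[[l]] <- list(W = bw$gW, b = bw$gb)
    ga <- bw$gx
    tap_idx <- match(l, c(5, 4, 3))     # acts index l corresponds to tap k+1
    if (!is.na(tap_idx)) ga <- ga + gtap[[tap_idx + 1]]
  }
  list(enc = genc, lat = gl, head = gh)
}

#' Forward pass: image to saliency pyramid
#'
#' A pure function of the model parameters and the image: there are no
#' stochastic layers, so repeated calls give identical logits.
#'
#' @param model a [build_model()] result.
#' @param image an [image_record()] or square matrix whose side equals the
#'   model's `input_size`.
#' @return A `saliency_pyramid`: list with `logits` (matrices, coarse to
#'   fine), `level_sizes`, and `output_level`.
#' @export
forward_saliency <- function(model, image) {
  stopifnot(inherits(model, "detector_model"))
  px <- if (inherits(image, "image_record")) image$pixels else image
  S <- model$config$input_size
  if (nrow(px) != S || ncol(px) != S) {
    abort(sprintf("image size %d x %d does not match model input_size %d.",
                  nrow(px), ncol(px), S))
  }
  fwd <- model_forward(model, px, keep_cache = FALSE)
  new_saliency_pyramid(fwd$logits, model$config$output_level)
}

new_saliency_pyramid <- function(logits, output_level = "coarsest") {
  structure(list(logits = logits,
                 level_sizes = vapply(logits, nrow, numeric(1)),
                 output_level = output_level),
            class = "saliency_pyramid")
}

#' @export
print.saliency_pyramid <- function(x, ...) {
  cat("<saliency_pyramid> levels:", paste(x$level_sizes, collapse = ", "),
      "| output:", x$output_level, "\n")
  invisible(x)
}

# pick the designated output map from a pyramid
output_map <- function(pyramid, level = NULL) {
  if (is.null(level)) level <- pyramid$output_level
  k <- if (is.numeric(level)) level else
    switch(level, coarsest = 1L, finest = length(pyramid$logits),
           abort("`level` must be 'coarsest', 'finest' or an index."))
  pyramid$logits[[k]]
}

#' Image-level probability from a saliency map
#'
#' The image-level score is the maximum sigmoid-transformed logit over the
#' designated output map (default: the model's `output_level`).
#'
#' @param x a `saliency_pyramid` or a logit matrix.
#' @param level optional override: `"coarsest"`, `"finest"` or a level index.
#' @return Probability in `[0, 1]`.
#' @export
image_probability <- function(x, level = NULL) {
  m <- if (inherits(x, "saliency_pyramid")) output_map(x, level) else x
  if (length(m) == 0) abort("empty saliency map.")
  max(sigmoid(m))
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the parameters with the embedded
#' model configuration; loading against an expected configuration rejects
#' mismatches.
#'
#' @param model a `detector_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint()`: `path`, invisibly. `load_checkpoint()`: a
#'   `detector_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "detector_model"))
  saveRDS(list(config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_config optional [model_config()]; loading fails if the
#'   checkpoint's backbone, input size or level count differ.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  if (!file.exists(path)) abort(paste0("checkpoint not found: ", path))
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$config) || is.null(ck$params)) {
    abort("not a detector checkpoint.")
  }
  if (!is.null(expect_config)) {
    for (fld in c("backbone", "input_size", "pyramid_levels")) {
      if (!identical(ck$config[[fld]], expect_config[[fld]])) {
        abort(sprintf("checkpoint config mismatch on `%s` (%s vs %s).", fld,
                      ck$config[[fld]], expect_config[[fld]]))
      }
    }
  }
  structure(list(config = ck$config, params = ck$params),
            class = "detector_model")
}
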