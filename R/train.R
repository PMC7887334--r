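#' Training configuration
#'
#' Defaults follow the full-scale training recipe: Adam, 100 epochs, batch
#' size 8, starting learning rate 1e-5, fivefold cross-validation, and
#' stochastic augmentation with translation within ±100 px (at a 1024-pixel
#' input; pixel ranges scale linearly with `input_size`), rescaling 0.9–1.1,
#' horizontal flip with probability 0.5, rotation ±15° and
#' brightness/contrast jitter 0.75–1.25. Desk-scale runs on the tiny backbone
#' typically raise the learning rate (around 1e-3) since the network is small
#' and randomly initialized.
#'
#' @param epochs training epochs per fold.
#' @param batch_size images per optimizer step.
#' @param learning_rate Adam step size.
#' @param folds cross-validation folds (>= 2).
#' @param seed master seed; per-fold, per-epoch and per-image streams are
#'   derived from it deterministically.
#' @param input_size training input side in pixels.
#' @param augmentation list of sampling ranges (see Details).
#' @param mask_downsample supervision-mask downsampling operator
#'   (`"max"` or `"area_threshold"`).
#' @param mask_radius disk radius at `input_size` resolution; default scales
#'   the full-scale 75-pixel radius linearly.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 8, learning_rate = 1e-5,
                         folds = 5, seed = 1, input_size = 1024,
                         augmentation = list(
                           translate_px = 100, scale = c(0.9, 1.1),
                           hflip_prob = 0.5, rotation = c(-15, 15),
                           brightness = c(0.75, 1.25),
                           contrast = c(0.75, 1.25)),
                         mask_downsample = "max",
                         mask_radius = 75 * input_size / 1024) {
  if (folds < 2) abort("`folds` must be >= 2.")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, folds = as.integer(folds),
                 seed = as.integer(seed), input_size = as.integer(input_size),
                 augmentation = augmentation, mask_downsample = mask_downsample,
                 mask_radius = mask_radius),
            class = "train_config")
}

#' Multiscale pixel-wise binary cross-entropy loss
#'
#' The training loss sums, over the K pyramid levels, the per-level mean of
#' the pixel-wise binary cross-entropy between the sigmoid of the saliency
#' logits and the binary supervision mask:
#' \deqn{L = \sum_k \frac{1}{\Omega_k} \sum_{i,j} -[M_k \log\sigma(P_k) +
#'   (1-M_k)\log(1-\sigma(P_k))]}
#' where \eqn{\Omega_k} is the pixel count of level k. Evaluated in the
#' numerically stabilized logit form, so it is finite for any finite logits.
#'
#' @param saliency a `saliency_pyramid` (or list of logit matrices).
#' @param masks a `supervision_pyramid` (or list of binary matrices) with
#'   matching per-level sizes.
#' @return Nonnegative scalar loss.
#' @export
multiscale_bce_loss <- function(saliency, masks) {
  P <- if (inherits(saliency, "saliency_pyramid")) saliency$logits else saliency
  M <- if (inherits(masks, "supervision_pyramid")) masks$masks else masks
  if (length(P) != length(M)) abort("saliency and mask level counts differ.")
  total <- 0
  for (k in seq_along(P)) {
    if (!all(dim(P[[k]]) == dim(M[[k]]))) {
      abort(sprintf("level %d size mismatch: logits %dx%d vs mask %dx%d.", k,
                    nrow(P[[k]]), ncol(P[[k]]), nrow(M[[k]]), ncol(M[[k]])))
    }
    p <- P[[k]]; m <- M[[k]]
    # -[m log sigma(p) + (1-m) log(1-sigma(p))] = max(p,0) - p*m + log(1+exp(-|p|))
    pix <- pmax(p, 0) - p * m + log1p(exp(-abs(p)))
    total <- total + sum(pix) / length(p)
  }
  total
}

# gradient of multiscale_bce_loss wrt each logit map
multiscale_bce_grad <- function(P, M) {
  lapply(seq_along(P), function(k) (sigmoid(P[[k]]) - M[[k]]) / length(P[[k]]))
}

# ---- Adam over the fixed parameter tree (enc / lat / head, leaves W and b) ----

adam_init <- function(params) {
  zero_like <- function(grp) lapply(grp, function(ly) {
    list(W = ly$W * 0, b = ly$b * 0)
  })
  list(m = list(enc = zero_like(params$enc), lat = zero_like(params$lat),
                head = zero_like(params$head)),
       v = list(enc = zero_like(params$enc), lat = zero_like(params$lat),
                head = zero_like(params$head)),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (grp in c("enc", "lat", "head")) {
    for (l in seq_along(params[[grp]])) {
      for (leaf in c("W", "b")) {
        g <- grads[[grp]][[l]][[leaf]]
        m <- beta1 * st$m[[grp]][[l]][[leaf]] + (1 - beta1) * g
        v <- beta2 * st$v[[grp]][[l]][[leaf]] + (1 - beta2) * g^2
        st$m[[grp]][[l]][[leaf]] <- m
        st$v[[grp]][[l]][[leaf]] <- v
        params[[grp]][[l]][[leaf]] <-
          params[[grp]][[l]][[leaf]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      }
    }
  }
  list(params = params, state = st)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (grp in c("enc", "lat", "head"))
    for (l in seq_along(a[[grp]]))
      for (leaf in c("W", "b"))
        a[[grp]][[l]][[leaf]] <- a[[grp]][[l]][[leaf]] + b[[grp]][[l]][[leaf]]
  a
}

grads_scale <- function(a, s) {
  for (grp in c("enc", "lat", "head"))
    for (l in seq_along(a[[grp]]))
      for (leaf in c("W", "b"))
        a[[grp]][[l]][[leaf]] <- a[[grp]][[l]][[leaf]] * s
  a
}

# ---- fold training ----

# images: list of image_record at model input size; points_list: list of
# tibbles in preprocessed coordinates; labels: 0/1 vector.
train_one_fold <- function(images, points_list, labels, train_idx, val_idx,
                           model_cfg, train_cfg, fold_seed, fold_index = 1L,
                           checkpoint = NULL, verbose = FALSE) {
  model <- build_model(model_cfg, seed = fold_seed)
  mcfg <- mask_config_for_input(model_cfg$input_size,
                                radius_s = train_cfg$mask_radius,
                                downsample = train_cfg$mask_downsample)
  opt <- adam_init(model$params)
  history <- vector("list", train_cfg$epochs)
  best <- list(auroc = -Inf, epoch = NA_integer_, params = model$params)
  S <- model_cfg$input_size
  for (epoch in seq_len(train_cfg$epochs)) {
    order <- with_seed(derive_seed(fold_seed, epoch, 0),
                       sample(train_idx, length(train_idx)))
    epoch_loss <- 0
    batch_grads <- NULL; batch_n <- 0L
    for (ii in seq_along(order)) {
      i <- order[ii]
      spec <- sample_augmentation(train_cfg, derive_seed(fold_seed, epoch, ii),
                                  input_size = S)
      aug <- apply_augmentation(images[[i]], points_list[[i]], spec)
      pyr <- build_supervision_pyramid(aug$points, mcfg)
      fwd <- model_forward(model, aug$image$pixels, keep_cache = TRUE)
      epoch_loss <- epoch_loss + multiscale_bce_loss(fwd$logits, pyr$masks)
      dlog <- multiscale_bce_grad(fwd$logits, pyr$masks)
      batch_grads <- grads_add(batch_grads, model_backward(model, fwd, dlog))
      batch_n <- batch_n + 1L
      if (batch_n == train_cfg$batch_size || ii == length(order)) {
        step <- adam_step(model$params, grads_scale(batch_grads, 1 / batch_n),
                          opt, train_cfg$learning_rate)
        model$params <- step$params
        opt <- step$state
        batch_grads <- NULL; batch_n <- 0L
      }
    }
    val_scores <- vapply(val_idx, function(i) {
      image_probability(forward_saliency(model, images[[i]]))
    }, numeric(1))
    val_auroc <- auroc(tibble(score = val_scores, label = labels[val_idx]))
    history[[epoch]] <- tibble(epoch = epoch,
                               train_loss = epoch_loss / length(order),
                               val_auroc = val_auroc)
    if (val_auroc > best$auroc) {
      best <- list(auroc = val_auroc, epoch = epoch, params = model$params)
    }
    if (verbose) {
      message(sprintf("fold %d epoch %d loss %.4f val AUROC %.3f",
                      fold_index, epoch, epoch_loss / length(order), val_auroc))
    }
  }
  model$params <- best$params
  ck_path <- NULL
  if (!is.null(checkpoint)) {
    save_checkpoint(model, checkpoint)
    ck_path <- checkpoint
  }
  structure(list(fold_index = fold_index, best_epoch = best$epoch,
                 best_validation_auroc = best$auroc, model = model,
                 checkpoint = ck_path, history = dplyr::bind_rows(history),
                 val_idx = val_idx),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> fold %d: best epoch %d, val AUROC %.3f\n",
              x$fold_index, x$best_epoch, x$best_validation_auroc))
  invisible(x)
}

# stratified fold assignment; returns integer fold id per row
stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  fold_id <- integer(n)
  with_seed(seed, {
    pos <- sample(which(labels == 1))
    neg <- sample(which(labels == 0))
    fold_id[pos] <- rep_len(seq_len(folds), length(pos))
    # continue the cycle so overall fold sizes differ by at most one
    offset <- length(pos) %% folds
    fold_id[neg] <- ((seq_along(neg) - 1 + offset) %% folds) + 1
  })
  fold_id
}

#' Fivefold cross-validation training
#'
#' Splits the manifest into stratified folds (each validation fold keeps both
#' classes; fold sizes differ by at most one), trains one detector per fold
#' on the remaining folds, logs the validation AUROC (image-level probability
#' versus image-level label, on un-augmented validation images, single model,
#' no test-time augmentation) after every epoch, and keeps the
#' maximum-AUROC checkpoint per fold.
#'
#' @param manifest a `dataset_manifest` (see [generate_dataset()]).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param out_dir optional directory for per-fold checkpoints
#'   (`fold_1.rds` ...).
#' @param images optional pre-loaded list of raw [image_record()]s matching
#'   the manifest rows (read from disk when omitted).
#' @param verbose print per-epoch progress.
#' @return A `cv_result`: list of `fold_result`s. [tidy()] gives one row per
#'   fold; [glance()] the across-fold summary.
#' @export
run_cross_validation <- function(manifest, model_cfg, train_cfg,
                                 out_dir = NULL, images = NULL,
                                 verbose = FALSE) {
  n <- nrow(manifest)
  if (n < train_cfg$folds) abort("fewer images than folds.")
  labels <- manifest$label
  if (sum(labels == 1) < train_cfg$folds || sum(labels == 0) < train_cfg$folds) {
    abort(paste("each validation fold needs both classes; too few positives",
                "or negatives for a stratified split. Provide more data or",
                "fewer folds."))
  }
  fold_id <- stratified_folds(labels, train_cfg$folds,
                              derive_seed(train_cfg$seed, 7))
  prep <- prepare_training_inputs(manifest, model_cfg, images)
  results <- vector("list", train_cfg$folds)
  for (f in seq_len(train_cfg$folds)) {
    val_idx <- which(fold_id == f)
    if (length(unique(labels[val_idx])) < 2) {
      abort("degenerate fold (single-class validation); reshuffle with a stratified split.")
    }
    ck <- if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      file.path(out_dir, sprintf("fold_%d.rds", f))
    } else NULL
    results[[f]] <- train_one_fold(
      prep$images, prep$points, labels,
      train_idx = which(fold_id != f), val_idx = val_idx,
      model_cfg = model_cfg, train_cfg = train_cfg,
      fold_seed = derive_seed(train_cfg$seed, 100, f),
      fold_index = f, checkpoint = ck, verbose = verbose)
  }
  structure(list(folds = results, fold_id = fold_id, model_cfg = model_cfg,
                 train_cfg = train_cfg),
            class = "cv_result")
}

# preprocess manifest images to the model input size and map points
prepare_training_inputs <- function(manifest, model_cfg, images = NULL) {
  if (is.null(images)) images <- load_manifest_images(manifest)
  S <- model_cfg$input_size
  recs <- vector("list", nrow(manifest))
  pts <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    recs[[i]] <- preprocess_image(images[[i]], S)
    pts[[i]] <- map_points_to_preprocessed(manifest$points[[i]], recs[[i]])
  }
  list(images = recs, points = pts)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean val AUROC %.3f\n", length(x$folds),
              mean(vapply(x$folds, `[[`, numeric(1), "best_validation_auroc"))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$folds, function(f) {
    tibble(fold = f$fold_index, best_epoch = f$best_epoch,
           best_validation_auroc = f$best_validation_auroc,
           checkpoint = f$checkpoint %||% NA_character_)
  }))
}

#' @export
glance.cv_result <- function(x, ...) {
  aur <- vapply(x$folds, `[[`, numeric(1), "best_validation_auroc")
  tibble(folds = length(x$folds), mean_val_auroc = mean(aur),
         min_val_auroc = min(aur), max_val_auroc = max(aur))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cv_models <- function(cv) lapply(cv$folds, `[[`, "model")

#' Training-set-size ablation
#'
#' Trains on nested subsets of the manifest (a smaller fraction is contained
#' in every larger one; the nesting is a seeded draw) and evaluates each
#' trained ensemble on a held-out test manifest, returning the AUROC/AUPRC
#' trend as the annotation budget grows.
#'
#' @param manifest training `dataset_manifest`.
#' @param fractions proportions in (0, 1]; `1` uses the full manifest and
#'   reproduces [run_cross_validation()] under the same seed.
#' @param model_cfg,train_cfg model and training configuration.
#' @param test_manifest held-out `dataset_manifest` for evaluation.
#' @param tta a [tta_config()] for ensemble inference.
#' @param verbose print progress.
#' @return Tibble with columns `fraction`, `n`, `auroc`, `auprc`, and a
#'   list-column `subset` of the manifest row indices used.
#' @export
train_fraction_ablation <- function(manifest, fractions, model_cfg, train_cfg,
                                    test_manifest, tta = tta_config(),
                                    verbose = FALSE) {
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must be in (0, 1].")
  n <- nrow(manifest)
  ord <- with_seed(derive_seed(train_cfg$seed, 999), sample.int(n, n))
  test_images <- load_manifest_images(test_manifest)
  out <- vector("list", length(fractions))
  for (j in seq_along(fractions)) {
    f <- fractions[j]
    k <- round(f * n)
    if (k < train_cfg$folds) {
      abort(sprintf("fraction %.2f yields %d images, fewer than %d folds.",
                    f, k, train_cfg$folds))
    }
    idx <- sort(ord[seq_len(k)])   # nested; fraction 1 is the identity subset
    sub <- manifest[idx, ]
    class(sub) <- class(manifest)
    attr(sub, "out_dir") <- attr(manifest, "out_dir")
    cv <- run_cross_validation(sub, model_cfg, train_cfg, verbose = verbose)
    scores <- vapply(seq_len(nrow(test_manifest)), function(i) {
      rec <- preprocess_image(test_images[[i]], model_cfg$input_size)
      ensemble_predict(cv_models(cv), rec, tta)$probability
    }, numeric(1))
    cohort <- tibble(score = scores, label = test_manifest$label)
    out[[j]] <- tibble(fraction = f, n = k, auroc = auroc(cohort),
                       auprc = auprc(cohort), subset = list(idx))
  }
  dplyr::bind_rows(out)
}
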