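test_that("preprocessing records exact pad/scale bookkeeping", {
  # square input: identity
  sq <- matrix(runif(64 * 64), 64, 64)
  rec <- preprocess_image(sq, 64)
  expect_equal(rec$pixels, sq)
  expect_equal(c(rec$pad_x, rec$pad_y, rec$scale), c(0, 0, 1))

  # tall input: symmetric zero columns, no resize
  tall <- matrix(1, 128, 64)
  rec2 <- preprocess_image(tall, 128)
  expect_equal(dim(rec2$pixels), c(128, 128))
  expect_equal(rec2$pad_x, 32)
  expect_true(all(rec2$pixels[, 1:32] == 0))
  pt <- map_points_to_preprocessed(tibble::tibble(x = 0, y = 0), rec2)
  expect_equal(c(pt$x, pt$y), c(32, 0))

  # pad then resize: corners stay inside [0, target)
  wide <- matrix(1, 100, 40)
  rec3 <- preprocess_image(wide, 64)
  expect_equal(dim(rec3$pixels), c(64, 64))
  expect_equal(rec3$scale, 63 / 99)
  corners <- map_points_to_preprocessed(
    tibble::tibble(x = c(0, 39, 0, 39), y = c(0, 0, 99, 99)), rec3)
  expect_true(all(corners$x >= 0 & corners$x < 64))
  expect_true(all(corners$y >= 0 & corners$y < 64))
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "zero")
})

test_that("augmentation sampling covers its configured ranges uniformly", {
  tc <- train_config(input_size = 1024)
  rot <- vapply(1:2000, function(i) {
    sample_augmentation(tc, seed = i)$rotation
  }, numeric(1))
  expect_gte(min(rot), -15); expect_lte(max(rot), 15)
  expect_lt(min(rot), -14); expect_gt(max(rot), 14)

  expect_identical(sample_augmentation(tc, seed = 3),
                   sample_augmentation(tc, seed = 3))

  tc0 <- train_config(augmentation = list(
    translate_px = 0, scale = c(1, 1), hflip_prob = 0, rotation = c(0, 0),
    brightness = c(1, 1), contrast = c(1, 1)))
  spec <- sample_augmentation(tc0, seed = 1)
  expect_true(pxsal:::is_identity_spec(spec))
})

test_that("identity augmentation leaves image and points unchanged", {
  res <- tiny_positive(size = 96, n_lesions = 1, seed = 3)
  out <- apply_augmentation(res$image, res$annotations, augmentation_spec())
  expect_equal(out$image$pixels, res$image$pixels)
  expect_equal(out$points$x, res$annotations$x)
})

test_that("horizontal flip maps (x, y) to (S-1-x, y)", {
  img <- matrix(runif(64 * 64), 64, 64)
  pts <- tibble::tibble(x = c(3, 60), y = c(10, 20))
  out <- apply_augmentation(img, pts, augmentation_spec(hflip = TRUE))
  expect_equal(out$points$x, 63 - pts$x)
  expect_equal(out$points$y, pts$y)
  expect_equal(out$image$pixels, img[, 64:1], tolerance = 1e-12)
})

test_that("rotated points match an independent rotation-matrix computation", {
  S <- 96
  pts <- tibble::tibble(x = c(20, 70, 48), y = c(30, 50, 10))
  spec <- augmentation_spec(rotation = 15)
  out <- apply_augmentation(matrix(0, S, S), pts, spec)
  th <- 15 * pi / 180
  ctr <- (S - 1) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expected <- t(R %*% rbind(pts$x - ctr, pts$y - ctr)) +
    matrix(ctr, nrow(pts), 2)
  expect_lt(max(abs(out$points$x - expected[, 1])), 0.5)
  expect_lt(max(abs(out$points$y - expected[, 2])), 0.5)
})

test_that("points leaving the canvas are dropped with a count", {
  pts <- tibble::tibble(x = c(2, 50), y = c(2, 50))
  out <- apply_augmentation(matrix(0, 64, 64), pts,
                            augmentation_spec(dx = -10, dy = -10))
  expect_equal(nrow(out$points), 1)
  expect_equal(attr(out$points, "dropped"), 1)
})

test_that("a rendered disk co-transforms with its centre point", {
  # render a bright disk, transform image and point, re-find the disk centre
  S <- 96
  for (spec in list(augmentation_spec(rotation = 12),
                    augmentation_spec(hflip = TRUE, dx = 6, dy = -4),
                    augmentation_spec(scale = 1.08, rotation = -8))) {
    img <- matrix(0, S, S)
    ctr0 <- c(40, 56)
    g <- pxsal:::pixel_grids(S)
    img[sqrt((g$x - ctr0[1])^2 + (g$y - ctr0[2])^2) <= 5] <- 1
    out <- apply_augmentation(img, tibble::tibble(x = ctr0[1], y = ctr0[2]), spec)
    w <- out$image$pixels
    cx <- sum(g$x * w) / sum(w); cy <- sum(g$y * w) / sum(w)
    expect_lt(abs(cx - out$points$x), 1)
    expect_lt(abs(cy - out$points$y), 1)
  }
})

test_that("multiscale BCE matches closed forms and a per-pixel oracle", {
  # all-zero masks and logits, K = 4: sum of four ln2 terms
  z <- lapply(c(2, 4, 8, 16), function(s) matrix(0, s, s))
  expect_equal(multiscale_bce_loss(z, z), 4 * log(2), tolerance = 1e-12)

  # saturated, sign-consistent logits: essentially zero loss
  m <- lapply(c(2, 4), function(s) matrix(rbinom(s * s, 1, 0.5), s, s))
  p <- lapply(m, function(mm) (2 * mm - 1) * 50)
  expect_lt(multiscale_bce_loss(p, m), 1e-15)

  # fixed 2x2 single-level case against direct per-pixel arithmetic
  M <- matrix(c(1, 0, 0, 0), 2, 2)
  P <- matrix(c(2, 0, -1, 1), 2, 2)   # column-major: [[2,-1],[0,1]]
  expect_equal(multiscale_bce_loss(list(P), list(M)), bce_oracle(list(P), list(M)),
               tolerance = 1e-12)

  # random small instances, all levels, 1e-10 agreement
  for (seed in 1:20) {
    sizes <- withr::with_seed(seed, sample(1:4, sample(1:4, 1)))
    Ms <- withr::with_seed(seed + 100,
                           lapply(sizes, function(s) matrix(rbinom(s * s, 1, 0.4), s, s)))
    Ps <- withr::with_seed(seed + 200,
                           lapply(sizes, function(s) matrix(rnorm(s * s, 0, 3), s, s)))
    expect_equal(multiscale_bce_loss(Ps, Ms), bce_oracle(Ps, Ms),
                 tolerance = 1e-10)
  }

  expect_error(multiscale_bce_loss(list(matrix(0, 2, 2)), list(matrix(0, 4, 4))),
               "mismatch")
})

test_that("perturbing a logit against its mask strictly increases the loss", {
  M <- list(matrix(c(1, 0, 0, 1), 2, 2))
  P <- list(matrix(c(5, -5, -5, 5), 2, 2))
  base <- multiscale_bce_loss(P, M)
  for (i in 1:4) {
    P2 <- P
    P2[[1]][i] <- -P2[[1]][i]
    expect_gt(multiscale_bce_loss(P2, M), base)
  }
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  labels <- rep(c(0, 1), each = 25)
  id <- pxsal:::stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(id)), 1:5)
  expect_true(all(table(id) == 10))
  for (f in 1:5) expect_equal(sum(labels[id == f]), 5)
})

test_that("cross-validation rejects datasets that cannot stratify", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(10, 0.1, phantom_config(image_size = 64), seed = 2,
                          out_dir = dir)
  mc <- model_config("tiny_fpn", input_size = 64)
  tc <- train_config(epochs = 1, folds = 5, input_size = 64)
  expect_error(run_cross_validation(man, mc, tc), "both classes")
})

test_that("fold training selects the best epoch by validation AUROC", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(20, 0.5, phantom_config(image_size = 64), seed = 5,
                          out_dir = dir)
  mc <- model_config("tiny_fpn", input_size = 64, output_level = "finest")
  tc <- train_config(epochs = 3, batch_size = 4, learning_rate = 1e-3,
                     folds = 2, seed = 1, input_size = 64)
  cv <- run_cross_validation(man, mc, tc, out_dir = file.path(dir, "ck"))
  expect_length(cv$folds, 2)
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  for (f in cv$folds) {
    expect_equal(f$best_validation_auroc, max(f$history$val_auroc))
    expect_equal(f$best_epoch,
                 f$history$epoch[which.max(f$history$val_auroc)])
    expect_true(file.exists(f$checkpoint))
  }
  # folds are disjoint and exhaustive
  idx <- unlist(lapply(cv$folds, `[[`, "val_idx"))
  expect_setequal(idx, 1:20)
  expect_equal(length(idx), 20)
})

test_that("ablation subsets are nested and fraction 1 is the identity subset", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(20, 0.5, phantom_config(image_size = 64), seed = 6,
                          out_dir = dir)
  tdir <- withr::local_tempdir()
  tman <- generate_dataset(8, 0.5, phantom_config(image_size = 64), seed = 7,
                           out_dir = tdir)
  mc <- model_config("tiny_fpn", input_size = 64, output_level = "finest")
  tc <- train_config(epochs = 1, batch_size = 4, learning_rate = 1e-3,
                     folds = 2, seed = 2, input_size = 64)
  tab <- train_fraction_ablation(man, c(0.5, 1), mc, tc, tman)
  expect_equal(tab$n, c(10, 20))
  expect_true(all(tab$subset[[1]] %in% tab$subset[[2]]))
  expect_equal(tab$subset[[2]], 1:20)
  expect_true(all(tab$auroc >= 0 & tab$auroc <= 1))
  expect_error(train_fraction_ablation(man, c(0.05), mc, tc, tman), "folds")
})
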