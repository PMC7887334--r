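test_that("level sizes follow the input/32 .. input/4 contract", {
  mc <- model_config("tiny_fpn", input_size = 256)
  mod <- build_model(mc, seed = 1)
  sal <- forward_saliency(mod, matrix(0, 256, 256))
  expect_equal(sal$level_sizes, c(8, 16, 32, 64))
  expect_true(all(vapply(sal$logits, function(m) all(is.finite(m)), logical(1))))

  mc2 <- model_config("tiny_fpn", input_size = 160)
  sal2 <- forward_saliency(build_model(mc2, seed = 1), matrix(0.5, 160, 160))
  expect_equal(sal2$level_sizes, 160 / c(32, 16, 8, 4))
})

test_that("unknown backbones and bad sizes are configuration errors", {
  expect_error(model_config("resnet"), "arg")
  expect_error(model_config("tiny_fpn", input_size = 100), "divisible")
  mod <- build_model(model_config("tiny_fpn", input_size = 64), seed = 1)
  expect_error(forward_saliency(mod, matrix(0, 96, 96)), "96.*64|64.*96")
})

test_that("initialization is deterministic given the seed", {
  mc <- model_config("tiny_fpn", input_size = 64)
  a <- build_model(mc, seed = 5)
  b <- build_model(mc, seed = 5)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_model(mc, seed = 6)$params))
})

test_that("inference is a pure function of parameters and image", {
  mod <- build_model(model_config("tiny_fpn", input_size = 64), seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  s1 <- forward_saliency(mod, img)
  s2 <- forward_saliency(mod, img)
  expect_identical(s1$logits, s2$logits)
})

test_that("a constant-filter configuration gives constant interior logits", {
  # hand-checkable: all-zero weights with head bias b emit logit b everywhere
  mod <- constant_logit_model(1.25, input_size = 64)
  sal <- forward_saliency(mod, matrix(runif(64 * 64), 64, 64))
  for (m in sal$logits) expect_true(all(abs(m - 1.25) < 1e-12))
  # one uniform encoder weight on a constant image: interior of the first
  # feature map equals the direct convolution sum (9 taps x weight x value),
  # verified through the exported conv primitive
  x <- array(0.5, dim = c(8, 8, 1))
  W <- matrix(0.1, 9, 1)
  out <- pxsal:::conv2d_fwd_cpp(x, W, 0.2, 3L, 1L, 1L)
  expect_equal(out[3, 3, 1], 9 * 0.1 * 0.5 + 0.2, tolerance = 1e-12)
  expect_equal(out[1, 1, 1], 4 * 0.1 * 0.5 + 0.2, tolerance = 1e-12)
})

test_that("image_probability is the max sigmoid of the designated map", {
  mod0 <- constant_logit_model(0, input_size = 64)
  sal <- forward_saliency(mod0, matrix(0, 64, 64))
  expect_equal(image_probability(sal), 0.5)
  expect_equal(image_probability(matrix(c(-1, 0, 2), 1)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(image_probability(matrix(50, 2, 2)), 1, tolerance = 1e-9)
  expect_error(image_probability(matrix(numeric(0), 0, 0)), "empty")
})

test_that("backprop matches finite-difference gradients", {
  mc <- model_config("tiny_fpn", input_size = 32)
  mod <- build_model(mc, seed = 3)
  img <- withr::with_seed(4, matrix(runif(32 * 32), 32, 32))
  masks <- withr::with_seed(5, lapply(c(1, 2, 4, 8), function(s) {
    matrix(rbinom(s * s, 1, 0.3), s, s)
  }))
  lossfun <- function(m) {
    fwd <- pxsal:::model_forward(m, img, keep_cache = TRUE)
    list(loss = multiscale_bce_loss(fwd$logits, masks), fwd = fwd)
  }
  l0 <- lossfun(mod)
  gr <- pxsal:::model_backward(mod, l0$fwd,
                               pxsal:::multiscale_bce_grad(l0$fwd$logits, masks))
  eps <- 1e-6
  probes <- list(c("enc", 1, "W", 5), c("enc", 3, "W", 20), c("enc", 5, "b", 2),
                 c("lat", 2, "W", 7), c("lat", 4, "b", 1), c("head", 1, "W", 3),
                 c("head", 4, "b", 1))
  for (p in probes) {
    grp <- p[1]; l <- as.integer(p[2]); leaf <- p[3]; i <- as.integer(p[4])
    mp <- mod
    mp$params[[grp]][[l]][[leaf]][i] <- mp$params[[grp]][[l]][[leaf]][i] + eps
    num <- (lossfun(mp)$loss - l0$loss) / eps
    ana <- gr[[grp]][[l]][[leaf]][i]
    expect_lt(abs(num - ana) / max(1e-8, abs(num), abs(ana)), 1e-4)
  }
})

test_that("shifting a delta input shifts interior responses (translation covariance)", {
  mod <- build_model(model_config("tiny_fpn", input_size = 128), seed = 8)
  base <- matrix(0, 128, 128)
  a <- base; a[49, 49] <- 1         # delta at (x=48, y=48), 0-based
  b <- base; b[49 + 32, 49] <- 1    # shifted by one coarsest-level stride in y
  sa <- forward_saliency(mod, a)$logits
  sb <- forward_saliency(mod, b)$logits
  # the delta sits in coarsest cell (2, 2); shifted, in (3, 2); both cells'
  # receptive fields avoid the image boundary, so responses shift exactly
  expect_equal(sa[[1]][2, 2], sb[[1]][3, 2], tolerance = 1e-10)
  # at the finest level (stride 4) the shift is 8 cells
  expect_equal(sa[[4]][13, 13], sb[[4]][13 + 8, 13], tolerance = 1e-10)
})

test_that("checkpoints round-trip and reject config mismatches", {
  dir <- withr::local_tempdir()
  mc <- model_config("tiny_fpn", input_size = 64)
  mod <- build_model(mc, seed = 9)
  p <- file.path(dir, "m.rds")
  save_checkpoint(mod, p)
  back <- load_checkpoint(p, expect_config = mc)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward_saliency(back, img)$logits,
                   forward_saliency(mod, img)$logits)
  expect_error(load_checkpoint(p, expect_config = model_config("tiny_fpn",
                                                               input_size = 128)),
               "mismatch")
  expect_error(build_model(model_config("tiny_fpn", pretrained = TRUE)),
               "pretrained")
})
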