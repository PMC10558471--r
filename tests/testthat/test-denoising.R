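test_that("the network stack is Conv+ReLU, (depth-2) Conv+BN+ReLU, Conv", {
  m <- build_dncnn(dncnn_config(depth = 17, filters = 64, seed = 0))
  expect_length(m$layers, 17)
  expect_equal(sum(vapply(m$layers, function(l) !is.null(l$bn), logical(1))), 15)
  expect_true(m$layers[[1]]$relu && is.null(m$layers[[1]]$bn))
  expect_false(m$layers[[17]]$relu)
  expect_equal(m$layers[[1]]$c_in, 1L)
  expect_equal(m$layers[[17]]$c_out, 1L)
  expect_equal(dim(m$layers[[2]]$W), c(64L, 9L * 64L))

  expect_error(dncnn_config(depth = 2), "at least 3")
  expect_error(dncnn_config(kernel = 4), "odd")

  # same seed, same init
  m2 <- build_dncnn(dncnn_config(depth = 17, filters = 64, seed = 0))
  expect_identical(m$layers, m2$layers)
})

test_that("a zero final layer makes denoising the exact identity", {
  m <- build_dncnn(dncnn_config(depth = 5, filters = 8, seed = 1))
  L <- length(m$layers)
  m$layers[[L]]$W[] <- 0
  m$layers[[L]]$b[] <- 0
  m$trained <- TRUE
  withr::local_seed(4)
  px <- matrix(as.numeric(sample(0:255, 64 * 64, replace = TRUE)), 64, 64)
  ch <- flat_channel(px)
  out <- denoise(m, ch)
  expect_identical(out$pixels, px)

  # constant image through the zero-residual model stays constant
  cc <- flat_channel(matrix(120, 70, 50))
  expect_identical(denoise(m, cc)$pixels, matrix(120, 70, 50))
})

test_that("an untrained model refuses to denoise", {
  m <- build_dncnn(dncnn_config(depth = 3, filters = 4))
  expect_error(denoise(m, flat_channel(matrix(1, 64, 64))), "untrained")
})

test_that("training is deterministic and zero steps leave weights untouched", {
  withr::local_seed(5)
  patches <- lapply(1:10, function(i) matrix(runif(16 * 16), 16, 16))
  m <- build_dncnn(dncnn_config(depth = 3, filters = 4, seed = 2))

  r1 <- train_dncnn(m, patches, sigma = 15 / 255, steps = 8, seed = 7)
  r2 <- train_dncnn(m, patches, sigma = 15 / 255, steps = 8, seed = 7)
  expect_identical(r1$model$layers, r2$model$layers)
  expect_identical(r1$report, r2$report)

  r0 <- train_dncnn(m, patches, sigma = 15 / 255, steps = 0, seed = 7)
  expect_identical(r0$model$layers, m$layers)
  expect_s3_class(r0$report, "denoise_report")
  expect_gt(r0$report$n_eval_patches, 0)

  expect_error(train_dncnn(m, patches[1:4], steps = 1), "at least 8")
})

test_that("desk-scale training gains at least 1 dB held-out PSNR", {
  rep <- desk_model()$report
  expect_gte(rep$psnr_denoised - rep$psnr_noisy, 1)
  expect_equal(rep$n_eval_patches, 16)
})

test_that("denoising improves PSNR against the generator's clean image", {
  sec <- generate_section(synthetic_spec(shape = c(96L, 96L), seed = 31))
  noisy <- get_channel(sec$image, "pgp95_red")
  den <- denoise(desk_model()$model, noisy)
  p_noisy <- psnr(noisy$pixels / 255, sec$clean)
  p_den <- psnr(den$pixels / 255, sec$clean)
  expect_gt(p_den, p_noisy)
  expect_identical(dim(den$pixels), dim(noisy$pixels))
})

test_that("threshold denoising zeroes sub-cutoff pixels and is idempotent", {
  ch <- flat_channel(c(5, 10, 200))
  expect_equal(as.vector(threshold_denoise(ch, 50)$pixels), c(0, 0, 200))
  expect_equal(threshold_denoise(ch, 0)$pixels, ch$pixels)

  sat <- threshold_denoise(flat_channel(c(0, 128, 255)), 255)
  expect_equal(as.vector(sat$pixels), c(0, 0, 255))

  withr::local_seed(6)
  r <- flat_channel(matrix(sample(0:255, 100, TRUE), 10, 10))
  once <- threshold_denoise(r, 77)
  twice <- threshold_denoise(once, 77)
  expect_identical(once$pixels, twice$pixels)

  expect_error(threshold_denoise(ch, 300), "cutoff")
})

test_that("weights round trip exactly through the flat text container", {
  tr <- desk_model()
  f <- withr::local_tempfile(fileext = ".txt")
  save_dncnn_weights(tr$model, f)
  back <- load_dncnn_weights(f)
  expect_true(back$trained)
  for (l in seq_along(tr$model$layers)) {
    expect_identical(back$layers[[l]]$W, tr$model$layers[[l]]$W)
    expect_identical(back$layers[[l]]$b, tr$model$layers[[l]]$b)
    if (!is.null(tr$model$layers[[l]]$bn)) {
      expect_identical(back$layers[[l]]$bn, tr$model$layers[[l]]$bn)
    }
  }
  ch <- flat_channel(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  expect_identical(denoise(back, ch)$pixels, denoise(tr$model, ch)$pixels)
})

test_that("the threshold baseline never beats DnCNN on dim fibers", {
  fx <- dim_fiber_fixture(seed = 3)
  cmp <- suppressWarnings(
    compare_denoisers(fx, desk_model()$model, fx$suggested_cutoff))
  w <- cmp[cmp$compartment == "whole", ]
  expect_lte(w$density[w$method == "threshold"],
             w$density[w$method == "dncnn"])
})

test_that("both denoising paths recover a bright-fiber section within 20%", {
  fx <- bright_fiber_fixture(seed = 3)
  cmp <- suppressWarnings(
    compare_denoisers(fx, desk_model()$model, fx$suggested_cutoff))
  w <- cmp[cmp$compartment == "whole", ]
  truth <- w$area_fraction[w$method == "truth"]
  for (meth in c("threshold", "dncnn")) {
    expect_lt(abs(w$area_fraction[w$method == meth] / truth - 1), 0.20)
  }
})

test_that("a noiseless section gives matching densities under both paths", {
  sec <- generate_section(synthetic_spec(shape = c(96L, 96L),
                                         target_area_fraction = 0.08,
                                         noise_sigma = 0, seed = 32))
  cmp <- suppressWarnings(compare_denoisers(sec, desk_model()$model, 0))
  w <- cmp[cmp$compartment == "whole", ]
  d_th <- w$density[w$method == "threshold"]
  d_dn <- w$density[w$method == "dncnn"]
  expect_lt(abs(d_dn - d_th) / max(d_th, 1), 0.15)
})
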