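small_ckpt <- function(seed = 1) {
  init_generator(generator_spec(z_dim = 16, w_dim = 16, img_size = 32,
                                channels = c(12, 10, 8, 6)), seed = seed)
}

test_that("the mapping network honours its dimension and determinism contract", {
  ck <- small_ckpt()
  z <- rnorm(16)
  w1 <- map_latent(z, 0.3, ck)
  w2 <- map_latent(z, 0.3, ck)
  expect_identical(w1, w2)
  expect_length(w1, 16)

  # guarded normalisation: all-zero latent maps without error
  w0 <- map_latent(rep(0, 16), 0.2, ck)
  expect_true(all(is.finite(w0)))

  # the condition must reach w
  wa <- map_latent(z, 0, ck)
  wb <- map_latent(z, 0.5, ck)
  expect_gt(sqrt(sum((wa - wb)^2)), 0)

  expect_error(map_latent(z, 1.3, ck), class = "ki67gan_domain_error")
  expect_error(map_latent(z, -0.1, ck), class = "ki67gan_domain_error")
  expect_error(map_latent(rnorm(8), 0.1, ck),
               class = "ki67gan_domain_error")
})

test_that("synthesis is deterministic, finite and shape-correct", {
  ck <- small_ckpt()
  w <- map_latent(rnorm(16), 0.2, ck)
  img1 <- synthesize(w, ck)
  img2 <- synthesize(w, ck)
  expect_identical(img1, img2)
  expect_identical(dim(img1), c(32L, 32L, 3L))
  expect_true(all(is.finite(img1)))
  expect_true(all(img1 >= 0 & img1 <= 255))
  expect_error(synthesize(rnorm(5), ck), class = "ki67gan_domain_error")
})

test_that("zero-length training returns the initial checkpoint and empty log", {
  ds <- render_dataset(20, size = 32, seed = 61)
  fit <- train_cgan(ds, cgan_config(total_kimgs = 0, img_size = 32,
                                    z_dim = 16, w_dim = 16,
                                    channels = c(12, 10, 8, 6), seed = 2))
  expect_equal(fit$checkpoint$kimgs, 0)
  expect_equal(nrow(fit$log), 0)
})

test_that("training is reproducible under a fixed seed and logs metrics", {
  ds <- render_dataset(40, size = 32, seed = 62)
  cfg <- cgan_config(total_kimgs = 0.3, batch_size = 16, img_size = 32,
                     z_dim = 16, w_dim = 16, channels = c(12, 10, 8, 6),
                     metric_interval_kimgs = 0.1, metric_n = 32, seed = 3)
  fit1 <- train_cgan(ds, cfg)
  fit2 <- train_cgan(ds, cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$checkpoint$params, fit2$checkpoint$params)
  expect_gt(nrow(fit1$log), 1)
  expect_true(all(is.finite(fit1$log$fid)))
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_equal(glance(fit1)$kimgs, fit1$checkpoint$kimgs)
})

test_that("training rejects degenerate manifests", {
  ds <- render_dataset(10, size = 32,
                       spec = label_distribution("point-mass", value = 0.2),
                       seed = 63)
  ds$ki67_index <- 0.2   # exactly one distinct label
  expect_error(train_cgan(ds, cgan_config(img_size = 32)),
               class = "ki67gan_domain_error")
  expect_error(train_cgan(ds[0, ], cgan_config(img_size = 32)),
               class = "ki67gan_domain_error")
})

test_that("conditional generation returns n labelled images, reproducibly", {
  ck <- small_ckpt()
  g <- generate_conditional(ck, c = 0.25, n = 5, seed = 4)
  expect_length(g$images, 5)
  expect_identical(g$labels, rep(0.25, 5))
  g2 <- generate_conditional(ck, c = 0.25, n = 5, seed = 4)
  expect_identical(g$images, g2$images)
  expect_error(generate_conditional(ck, c = 2), class = "ki67gan_domain_error")

  gl <- generate_conditional(ck, n = 4, labels = c(0, 0.2, 0.4, 0.5),
                             seed = 5)
  expect_identical(gl$labels, c(0, 0.2, 0.4, 0.5))
})

test_that("checkpoints survive a save/load round trip", {
  ck <- small_ckpt()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  z <- rnorm(16)
  expect_identical(synthesize(map_latent(z, 0.3, ck), ck),
                   synthesize(map_latent(z, 0.3, ck2), ck2))
})
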