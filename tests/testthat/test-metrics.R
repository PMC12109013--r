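colour_patch_set <- function(col, n, size = 32, seed = 1) {
  with_seed_local <- function(code) ki67gan:::with_seed(seed, code)
  with_seed_local(lapply(seq_len(n), function(i) {
    x <- array(0, c(size, size, 3))
    for (ch in 1:3) {
      x[, , ch] <- col[ch] * 255 + matrix(runif(size^2, -12, 12), size)
    }
    ki67gan:::clamp(x, 0, 255)
  }))
}

# independent oracle: diagonalise sigma_a^{1/2} sigma_b sigma_a^{1/2}
frechet_oracle <- function(a, b) {
  sym_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
  }
  sa <- sym_sqrt(a$sigma)
  M <- sa %*% b$sigma %*% sa
  tr_sqrt <- sum(sqrt(pmax(eigen(M, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  sum((a$mu - b$mu)^2) + sum(diag(a$sigma)) + sum(diag(b$sigma)) -
    2 * tr_sqrt
}

test_that("Gaussian statistics are the sample mean and n-1 covariance", {
  same <- matrix(c(1, 2, 1, 2), 2, byrow = TRUE)
  g <- fit_gaussian(same)
  expect_equal(g$sigma, matrix(0, 2, 2))

  g2 <- fit_gaussian(rbind(c(0, 0), c(2, 2)))
  expect_equal(g2$mu, c(1, 1))
  expect_equal(g2$sigma, matrix(2, 2, 2))

  expect_error(fit_gaussian(matrix(1, 1, 3)), class = "ki67gan_domain_error")

  set.seed(8)
  draws <- matrix(rnorm(30000, mean = 2, sd = 3), ncol = 3)
  g3 <- fit_gaussian(draws)
  se_mu <- 3 / sqrt(nrow(draws))
  expect_true(all(abs(g3$mu - 2) < 3 * se_mu))
  expect_true(all(abs(diag(g3$sigma) - 9) < 3 * 9 * sqrt(2 / nrow(draws))))
})

test_that("frechet reproduces the 1-D closed forms and the identity", {
  gs <- function(mu, var) {
    structure(list(mu = mu, sigma = matrix(var), n = 10),
              class = "gaussian_stats")
  }
  expect_equal(frechet(gs(0, 1), gs(0, 1)), 0)
  expect_equal(frechet(gs(0, 1), gs(3, 1)), 9)
  expect_equal(frechet(gs(0, 1), gs(0, 4)), 1)
  expect_error(frechet(gs(0, 1), fit_gaussian(matrix(rnorm(8), 4))),
               class = "ki67gan_domain_error")
})

test_that("frechet agrees with the alternative-formula oracle in 4-D", {
  set.seed(9)
  for (i in 1:20) {
    a <- fit_gaussian(matrix(rnorm(80), 20, 4))
    b <- fit_gaussian(matrix(rnorm(80, sd = runif(1, 0.5, 2)), 20, 4))
    expect_lt(abs(frechet(a, b) - frechet_oracle(a, b)), 1e-6)
  }
})

test_that("frechet is symmetric, non-negative and zero iff stats coincide", {
  set.seed(10)
  for (i in 1:30) {
    a <- fit_gaussian(matrix(rnorm(60), 20, 3))
    b <- fit_gaussian(matrix(rnorm(60, mean = rnorm(1)), 20, 3))
    d_ab <- frechet(a, b)
    expect_gte(d_ab, 0)
    expect_lt(abs(d_ab - frechet(b, a)), 1e-8)
    expect_lt(frechet(a, a), 1e-6)
  }
})

test_that("commuting covariances reduce to the eigenvalue closed form", {
  set.seed(11)
  la <- runif(3, 0.5, 2); lb <- runif(3, 0.5, 2)
  mua <- rnorm(3); mub <- rnorm(3)
  a <- structure(list(mu = mua, sigma = diag(la), n = 10),
                 class = "gaussian_stats")
  b <- structure(list(mu = mub, sigma = diag(lb), n = 10),
                 class = "gaussian_stats")
  closed <- sum((sqrt(la) - sqrt(lb))^2) + sum((mua - mub)^2)
  expect_equal(frechet(a, b), closed, tolerance = 1e-10)
})

test_that("fid separates colour populations and ignores image order", {
  red <- colour_patch_set(c(1, 0.1, 0.1), 24, seed = 1)
  blue <- colour_patch_set(c(0.1, 0.1, 1), 24, seed = 2)
  red_b <- colour_patch_set(c(1, 0.1, 0.1), 24, seed = 3)

  expect_lt(fid(red, red), 1e-6)
  between <- fid(red, blue)
  within <- fid(red, red_b)
  expect_gt(between, within)

  shuffled <- red_b[sample(length(red_b))]
  expect_equal(fid(red, shuffled), within)
})

test_that("fid/fhd fall as the generated set mixes towards the real set", {
  red <- colour_patch_set(c(0.9, 0.3, 0.5), 30, seed = 4)
  blue <- colour_patch_set(c(0.3, 0.4, 0.9), 30, seed = 5)
  mix_at <- function(p) {
    k <- round(p * 30)
    c(red[seq_len(k)], blue[seq_len(30 - k)])
  }
  vals <- vapply(c(0, 0.5, 1), function(p) fid(red, mix_at(p)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("embedders obey the contract and the histological one learns", {
  vis <- visual_embedder(d = 16, seed = 2)
  feats <- embed_images(vis, colour_patch_set(c(0.5, 0.5, 0.5), 3))
  expect_identical(dim(feats), c(3L, 16L))
  expect_identical(feats, embed_images(vis, colour_patch_set(c(0.5, 0.5, 0.5), 3)))

  ds <- render_dataset(120, seed = 71)
  lab <- label_dataset(ds, verbose = FALSE)
  expect_error(train_histological_embedder(lab[1:30, ]),
               class = "ki67gan_domain_error")

  emb <- train_histological_embedder(lab[1:100, ], d = 16, epochs = 3,
                                     seed = 5)
  expect_equal(emb$d, 16)
  expect_identical(dim(embed_images(emb, list(ds$pair[[1]]$he_image))),
                   c(1L, 16L))
  emb2 <- train_histological_embedder(lab[1:100, ], d = 16, epochs = 3,
                                      seed = 5)
  expect_identical(emb$meta$net$params, emb2$meta$net$params)

  held <- lab[101:120, ]
  pred <- emb$meta$predict(purrr::map(held$pair, "he_image"))
  expect_lt(mean(abs(pred - held$true_index)), 0.1)

  # FHD of a set against itself is 0.00 at two decimals
  imgs <- purrr::map(ds$pair[1:40], "he_image")
  expect_identical(round(fhd(imgs, imgs, emb), 2), 0)

  # FHD separates proliferation levels: distance between index-0.05 and
  # index-0.45 sets exceeds the distance between two independent
  # index-0.05 sets
  mk_set <- function(p, seed0, n = 20) {
    purrr::map(seq_len(n), function(i) {
      render_patch_pair(p, seed = seed0 + i)$he_image
    })
  }
  low_a <- mk_set(0.05, 9000)
  low_b <- mk_set(0.05, 9100)
  high <- mk_set(0.45, 9200)
  expect_gt(fhd(low_a, high, emb), fhd(low_a, low_b, emb))
})

test_that("ppl matches closed forms and is seed-stable", {
  expect_error(ppl_config(epsilon = 0), class = "ki67gan_config_error")

  # constant generator: zero path length
  d <- 4
  const_gen <- function(z, cvec) lapply(seq_len(nrow(z)), function(i) 1:d)
  ident_emb <- new_embedder(function(imgs) {
    do.call(rbind, lapply(imgs, as.numeric))
  }, d = d, kind = "perceptual")
  expect_equal(ppl(const_gen, ppl_config(n_pairs = 8), ident_emb,
                   seed = 1, z_dim = d), 0)

  # identity generator, linear interpolation in the "embedding" itself:
  # squared speed is ||z1 - z2||^2 for every epsilon
  lin_gen <- function(z, cvec) lapply(seq_len(nrow(z)), function(i) z[i, ])
  for (eps in c(1e-2, 1e-4)) {
    set.seed(3)
    np <- 6
    z1 <- matrix(rnorm(np * d), np); z2 <- matrix(rnorm(np * d), np)
    tt <- runif(np)
    expected <- mean(rowSums((z1 - z2)^2))
    cfg <- ppl_config(epsilon = eps, n_pairs = np,
                      space = "input-latent")
    # emulate linear interpolation by feeding pre-interpolated latents:
    # use the intermediate-space formula through a function generator via
    # direct computation instead
    lerp_ppl <- ki67gan:::with_seed(3, {
      za <- z1 + tt * (z2 - z1)
      zb <- z1 + (tt + eps) * (z2 - z1)
      ea <- embed_images(ident_emb, lin_gen(za, NULL))
      eb <- embed_images(ident_emb, lin_gen(zb, NULL))
      mean(rowSums((ea - eb)^2) / eps^2)
    })
    expect_equal(lerp_ppl, expected, tolerance = 1e-6)
  }

  ck <- init_generator(generator_spec(z_dim = 16, w_dim = 16,
                                      img_size = 32,
                                      channels = c(12, 10, 8, 6)), seed = 7)
  p1 <- ppl(ck, ppl_config(n_pairs = 8), seed = 9)
  p2 <- ppl(ck, ppl_config(n_pairs = 8), seed = 9)
  expect_identical(p1, p2)
  p3 <- ppl(ck, ppl_config(n_pairs = 8, space = "intermediate-latent"),
            seed = 9)
  expect_true(is.finite(p3))
})
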