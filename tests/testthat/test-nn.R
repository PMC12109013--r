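# Numerical correctness of the hand-written network machinery: the compiled
# convolution against a direct R convolution, and every analytic gradient
# against central finite differences.

naive_conv <- function(x, K, b) {
  d <- dim(x); dk <- dim(K)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; Co <- dk[4]
  out <- array(0, c(H, W, Co, N))
  for (n in 1:N) for (co in 1:Co) {
    acc <- matrix(b[co], H, W)
    for (c in 1:C) for (ki in 1:3) for (kj in 1:3) {
      sh <- ki - 2; sw <- kj - 2
      shifted <- matrix(0, H, W)
      hr <- max(1, 1 + sh):min(H, H + sh)
      wr <- max(1, 1 + sw):min(W, W + sw)
      shifted[hr - sh, wr - sw] <- x[hr, wr, c, n]
      acc <- acc + shifted * K[ki, kj, c, co]
    }
    out[, , co, n] <- acc
  }
  out
}

test_that("compiled convolution matches a direct R convolution", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  K <- array(rnorm(9 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  expect_equal(ki67gan:::conv_fwd(x, K, b), naive_conv(x, K, b),
               tolerance = 1e-12)
})

test_that("convolution, upsampling and pooling gradients are exact adjoints", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  K <- array(rnorm(9 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  g <- ki67gan:::conv_bwd(x, K, dy)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    fd <- (sum(ki67gan:::conv_fwd(xp, K, b) * dy) -
             sum(ki67gan:::conv_fwd(xm, K, b) * dy)) / (2 * eps)
    expect_equal(g$dx[i], fd, tolerance = 1e-6)
  }
  for (i in sample(length(K), 5)) {
    Kp <- K; Kp[i] <- K[i] + eps
    Km <- K; Km[i] <- K[i] - eps
    fd <- (sum(ki67gan:::conv_fwd(x, Kp, b) * dy) -
             sum(ki67gan:::conv_fwd(x, Km, b) * dy)) / (2 * eps)
    expect_equal(g$dK[i], fd, tolerance = 1e-6)
  }
  a <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  bb <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  expect_equal(sum(ki67gan:::up2(a) * bb), sum(a * ki67gan:::up2_bwd(bb)))
  expect_equal(sum(ki67gan:::pool2(bb) * a),
               sum(bb * ki67gan:::pool2_bwd(a)))
})

test_that("generator forward/backward agrees with finite differences", {
  spec <- generator_spec(z_dim = 8, w_dim = 8, img_size = 16,
                         channels = c(6, 5, 4))
  ckpt <- init_generator(spec, seed = 3)
  set.seed(4)
  z <- matrix(rnorm(2 * 8), 2)
  cvec <- c(0.1, 0.4)
  loss_of <- function(params) {
    w <- ki67gan:::map_latent_fwd(z, cvec, params, 8)$w
    y <- ki67gan:::synth_fwd(w, params, spec)$y
    sum(y^2)
  }
  mp <- ki67gan:::map_latent_fwd(z, cvec, ckpt$params, 8, cache = TRUE)
  sy <- ki67gan:::synth_fwd(mp$w, ckpt$params, spec, cache = TRUE)
  dy <- 2 * sy$y
  sb <- ki67gan:::synth_bwd(dy, sy, mp$w, ckpt$params, spec)
  grads <- ki67gan:::add_grads(
    sb$grads, ki67gan:::map_latent_bwd(sb$dw, mp$cache, ckpt$params, 8))
  eps <- 1e-5
  for (nm in c("map_Wemb", "map_W1", "map_W2", "syn_const", "A1", "K2",
               "Krgb", "cb1")) {
    i <- sample(length(ckpt$params[[nm]]), 1)
    pp <- ckpt$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- ckpt$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("discriminator gradients and input gradient are exact", {
  set.seed(5)
  p <- ki67gan:::disc_init(in_dim = 12, hidden = 6)
  v <- matrix(rnorm(3 * 12), 3)
  cvec <- c(0, 0.3, 0.8)
  fw <- ki67gan:::disc_fwd(v, cvec, p, cache = TRUE)
  dout <- rnorm(3)
  bw <- ki67gan:::disc_bwd(dout, fw$cache, p)
  eps <- 1e-6
  loss_p <- function(pp) sum(ki67gan:::disc_fwd(v, cvec, pp)$out * dout)
  for (nm in c("W1", "W2", "w3", "vproj", "b1", "b3")) {
    i <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
    expect_equal(bw$grads[[nm]][i], (loss_p(pp) - loss_p(pm)) / (2 * eps),
                 tolerance = 1e-5, label = paste("disc grad", nm))
  }
  # input gradient (the R1 operand) against finite differences
  ig <- ki67gan:::disc_input_grad(fw$cache, p)$G
  for (i in sample(length(v), 5)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    fd <- (ki67gan:::disc_fwd(vp, cvec, p)$out -
             ki67gan:::disc_fwd(vm, cvec, p)$out) / (2 * eps)
    expect_equal(ig[i], sum(fd), tolerance = 1e-5)
  }
})

test_that("R1 penalty is gamma/2 E||grad D||^2 and vanishes at gamma 0", {
  set.seed(6)
  p <- ki67gan:::disc_init(in_dim = 10, hidden = 5)
  v <- matrix(rnorm(4 * 10), 4)
  cvec <- runif(4)
  fw <- ki67gan:::disc_fwd(v, cvec, p, cache = TRUE)
  r1 <- ki67gan:::disc_r1(fw$cache, p, gamma = 2)
  # penalty value against finite-difference input gradients
  eps <- 1e-6
  gsq <- vapply(1:4, function(n) {
    g <- vapply(1:10, function(j) {
      vp <- v; vp[n, j] <- v[n, j] + eps
      vm <- v; vm[n, j] <- v[n, j] - eps
      (ki67gan:::disc_fwd(vp, cvec, p)$out[n] -
         ki67gan:::disc_fwd(vm, cvec, p)$out[n]) / (2 * eps)
    }, numeric(1))
    sum(g^2)
  }, numeric(1))
  expect_equal(r1$penalty, 2 / 2 * mean(gsq), tolerance = 1e-6)

  # parameter gradient of the penalty against finite differences
  pen_of <- function(pp) {
    fwp <- ki67gan:::disc_fwd(v, cvec, pp, cache = TRUE)
    ki67gan:::disc_r1(fwp$cache, pp, gamma = 2)$penalty
  }
  for (nm in c("W1", "W2", "w3", "vproj")) {
    i <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
    expect_equal(r1$grads[[nm]][i], (pen_of(pp) - pen_of(pm)) / (2 * eps),
                 tolerance = 1e-4, label = paste("r1 grad", nm))
  }

  off <- ki67gan:::disc_r1(fw$cache, p, gamma = 0)
  expect_identical(off$penalty, 0)
  expect_null(off$grads)
})
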