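# Small neural-network core shared by the conditional generator, the
# discriminator, and the image embedders/regressors.  Parameters live in flat
# named lists of numeric arrays; convolutions run through the compiled
# im2col/BLAS kernels in src/.

lrelu <- function(x, alpha = 0.2) {
  x * (alpha + (1 - alpha) * (x > 0))
}

lrelu_grad <- function(pre, alpha = 0.2) {
  alpha + (1 - alpha) * (pre > 0)
}

# He-style normal initialisation; fan_in from all but the last dim
he_weight <- function(...) {
  d <- c(...)
  fan_in <- prod(d[-length(d)])
  array(rnorm(prod(d), 0, sqrt(2 / fan_in)), d)
}

conv_fwd <- function(x, K, b) .nn_conv_fwd(x, K, b)
conv_bwd <- function(x, K, dy) .nn_conv_bwd(x, K, dy)
up2 <- function(x) .nn_up2(x)
up2_bwd <- function(dy) .nn_up2_bwd(dy)
pool2 <- function(x) .nn_pool2(x)
pool2_bwd <- function(dy) .nn_pool2_bwd(dy)

# repeatedly 2x2 average-pool an image tensor down to `target` pixels
pool_to <- function(x, target) {
  while (dim(x)[1] > target && dim(x)[1] %% 2L == 0L) {
    x <- pool2(x)
  }
  if (dim(x)[1] != target) {
    abort("image side must be a power-of-two multiple of the target size",
          class = "ki67gan_config_error")
  }
  x
}

# guarded second-moment (RMS) normalisation of row vectors, eps = 1e-8
moment_normalize <- function(x, eps = 1e-8) {
  m <- sqrt(rowMeans(x^2) + eps)
  x / m
}

moment_normalize_bwd <- function(x, g, eps = 1e-8) {
  m2 <- rowMeans(x^2) + eps
  m <- sqrt(m2)
  d <- ncol(x)
  g / m - x * (rowSums(x * g) / (d * m2 * m))
}

# ---- Adam over a flat named list of arrays -------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0, beta2 = 0.99,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- compact CNN (regressor / embedder backbone) -------------------------
#
# Fixed shape: input (size x size x 3) -> conv3x3 (3 -> c1) -> lrelu -> pool2
# -> conv3x3 (c1 -> c2) -> lrelu -> pool2 -> flatten -> FC -> lrelu
# (penultimate embedding) -> FC -> scalar output.

cnn_init <- function(input_size = 32, c1 = 12, c2 = 16, fc_dim = 32,
                     out_dim = 1) {
  flat <- (input_size / 4)^2 * c2
  params <- list(
    K1 = he_weight(3, 3, 3, c1), b1 = numeric(c1),
    K2 = he_weight(3, 3, c1, c2), b2 = numeric(c2),
    Wf = he_weight(flat, fc_dim), bf = numeric(fc_dim),
    Wo = he_weight(fc_dim, out_dim) * 0.1, bo = numeric(out_dim)
  )
  list(params = params, input_size = input_size, c1 = c1, c2 = c2,
       fc_dim = fc_dim, out_dim = out_dim, flat = flat)
}

cnn_fwd <- function(net, x, cache = FALSE) {
  p <- net$params
  x <- pool_to(x, net$input_size)
  a1 <- conv_fwd(x, p$K1, p$b1); h1 <- lrelu(a1)
  q1 <- pool2(h1)
  a2 <- conv_fwd(q1, p$K2, p$b2); h2 <- lrelu(a2)
  q2 <- pool2(h2)
  n <- dim(x)[4]
  flat <- matrix(q2, net$flat, n)   # column per sample
  af <- t(flat) %*% p$Wf + matrix(p$bf, n, net$fc_dim, byrow = TRUE)
  emb <- lrelu(af)
  out <- emb %*% p$Wo + matrix(p$bo, n, net$out_dim, byrow = TRUE)
  res <- list(out = out, emb = emb)
  if (cache) res$cache <- list(x = x, a1 = a1, q1 = q1, a2 = a2,
                               flat = flat, af = af, emb = emb)
  res
}

cnn_bwd <- function(net, cache, dout) {
  p <- net$params
  n <- nrow(dout)
  demb <- dout %*% t(p$Wo)
  dWo <- t(cache$emb) %*% dout
  dbo <- colSums(dout)
  daf <- demb * lrelu_grad(cache$af)
  dWf <- cache$flat %*% daf
  dbf <- colSums(daf)
  dflat <- p$Wf %*% t(daf)          # flat x n
  sz <- net$input_size / 4
  dq2 <- array(dflat, c(sz, sz, net$c2, n))
  dh2 <- pool2_bwd(dq2)
  da2 <- dh2 * lrelu_grad(cache$a2)
  g2 <- conv_bwd(cache$q1, p$K2, da2)
  dh1 <- pool2_bwd(g2$dx)
  da1 <- dh1 * lrelu_grad(cache$a1)
  g1 <- conv_bwd(cache$x, p$K1, da1)
  list(K1 = g1$dK, b1 = g1$db, K2 = g2$dK, b2 = g2$db,
       Wf = dWf, bf = dbf, Wo = dWo, bo = dbo)
}
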