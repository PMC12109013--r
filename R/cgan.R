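# Compact Ki67-conditioned style-mapping GAN.
#
# The conditioning contract follows the conditional mapping-network design:
# the scalar Ki67 index is embedded by a fully connected layer to the width
# of the intermediate latent space W, normalised like the input latent z
# (guarded second-moment normalisation), concatenated with normalised z and
# passed through two fully connected layers to give w.  The synthesis network
# is a 4-block style-modulated convolutional stack: w enters every block
# through a learned affine that produces per-channel feature scales.  The
# discriminator is a small leaky-ReLU MLP on 2x-downsampled patches with
# projection conditioning, trained with the non-saturating logistic loss and
# an R1 gradient penalty; the R1 term's parameter gradient is computed in
# closed form, which is exact almost everywhere for piecewise-linear
# activations.

#' Generator architecture specification
#'
#' @param z_dim input latent dimensionality.
#' @param w_dim intermediate latent dimensionality (the label embedding is
#'   also `w_dim` wide, so the concatenated mapping input is
#'   `z_dim + w_dim`).
#' @param img_size output resolution (power of two, >= 16; default 64).
#' @param channels feature channels from the learned 4 x 4 constant up to the
#'   final block; length `log2(img_size / 4) + 1`.
#' @return a list of class `ki67_generator_spec`.
#' @export
generator_spec <- function(z_dim = 64, w_dim = 64, img_size = 64,
                           channels = NULL) {
  n_blocks <- as.integer(round(log2(img_size / 4)))
  if (4 * 2^n_blocks != img_size || n_blocks < 1) {
    abort("`img_size` must be 4 * 2^k with k >= 1",
          class = "ki67gan_config_error")
  }
  channels <- channels %||% c(32, 24, 16, 12, 8)[seq_len(n_blocks + 1)]
  stopifnot(length(channels) == n_blocks + 1)
  structure(list(z_dim = z_dim, w_dim = w_dim, img_size = img_size,
                 n_blocks = n_blocks, channels = channels, label_dim = 1L,
                 mapping_layers = 2L),
            class = "ki67_generator_spec")
}

#' Initialise an untrained generator checkpoint
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for the weight draw.
#' @return an object of class `ki67_checkpoint` (mapping + synthesis weights,
#'   spec, kimgs trained, seed).
#' @export
init_generator <- function(spec = generator_spec(), seed = 1) {
  stopifnot(inherits(spec, "ki67_generator_spec"))
  with_seed(seed, {
    zd <- spec$z_dim; wd <- spec$w_dim
    ch <- spec$channels
    params <- list(
      map_Wemb = he_weight(1, wd),
      map_bemb = numeric(wd),
      map_W1 = he_weight(zd + wd, wd),
      map_b1 = numeric(wd),
      map_W2 = he_weight(wd, wd),
      map_b2 = numeric(wd),
      syn_const = array(rnorm(16 * ch[1], 0, 1), c(4, 4, ch[1]))
    )
    for (k in seq_len(spec$n_blocks)) {
      # small random style affine so w reaches the synthesis path from the
      # first step (scales stay near their neutral value 1)
      params[[paste0("A", k)]] <- matrix(rnorm(wd * ch[k], 0,
                                               0.2 / sqrt(wd)), wd, ch[k])
      params[[paste0("K", k)]] <- he_weight(3, 3, ch[k], ch[k + 1])
      params[[paste0("cb", k)]] <- numeric(ch[k + 1])
    }
    params$Krgb <- he_weight(1, 1, ch[spec$n_blocks + 1], 3) * 0.5
    params$brgb <- numeric(3)
    structure(list(spec = spec, params = params, kimgs = 0,
                   seed = seed, label_values = NULL),
              class = "ki67_checkpoint")
  })
}

#' @export
print.ki67_checkpoint <- function(x, ...) {
  cat(sprintf(
    "<ki67_checkpoint> %dx%d, z_dim = %d, w_dim = %d, trained %.1f kimgs\n",
    x$spec$img_size, x$spec$img_size, x$spec$z_dim, x$spec$w_dim, x$kimgs))
  invisible(x)
}

#' Save or load a generator checkpoint
#'
#' @param checkpoint a `ki67_checkpoint`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "ki67_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "ki67_checkpoint")) {
    abort("file does not contain a ki67_checkpoint",
          class = "ki67gan_io_error")
  }
  ckpt
}

# ---- mapping network -----------------------------------------------------

check_labels <- function(cvec) {
  if (any(!is.finite(cvec)) || any(cvec < 0) || any(cvec > 1)) {
    abort("Ki67 condition `c` must lie in [0, 1]",
          class = "ki67gan_domain_error")
  }
  cvec
}

map_latent_fwd <- function(z, cvec, params, zd, cache = FALSE) {
  e <- cbind(cvec) %*% params$map_Wemb +
    matrix(params$map_bemb, length(cvec), ncol(params$map_Wemb),
           byrow = TRUE)
  zn <- moment_normalize(z)
  en <- moment_normalize(e)
  u <- cbind(zn, en)
  a1 <- u %*% params$map_W1 +
    matrix(params$map_b1, nrow(u), ncol(params$map_W1), byrow = TRUE)
  h1 <- lrelu(a1)
  a2 <- h1 %*% params$map_W2 +
    matrix(params$map_b2, nrow(u), ncol(params$map_W2), byrow = TRUE)
  w <- lrelu(a2)
  if (cache) list(w = w, cache = list(cvec = cvec, e = e, u = u,
                                      a1 = a1, h1 = h1, a2 = a2))
  else list(w = w)
}

map_latent_bwd <- function(dw, cache, params, zd) {
  da2 <- dw * lrelu_grad(cache$a2)
  dW2 <- t(cache$h1) %*% da2
  db2 <- colSums(da2)
  dh1 <- da2 %*% t(params$map_W2)
  da1 <- dh1 * lrelu_grad(cache$a1)
  dW1 <- t(cache$u) %*% da1
  db1 <- colSums(da1)
  du <- da1 %*% t(params$map_W1)
  den <- du[, (zd + 1):ncol(du), drop = FALSE]
  de <- moment_normalize_bwd(cache$e, den)
  list(map_Wemb = rbind(colSums(cache$cvec * de)),
       map_bemb = colSums(de),
       map_W1 = dW1, map_b1 = db1, map_W2 = dW2, map_b2 = db2)
}

#' Map a latent vector and Ki67 condition to the intermediate latent w
#'
#' `w = FC2(FC1(concat(normalize(z), normalize(FC_embed(c)))))` with guarded
#' second-moment normalisation `x / sqrt(mean(x^2) + 1e-8)` and leaky-ReLU
#' fully connected layers.  Deterministic given weights.
#'
#' @param z latent vector of length `z_dim`, or an n x `z_dim` matrix.
#' @param c Ki67 index (or vector, one per row of `z`) in [0, 1].
#' @param checkpoint a `ki67_checkpoint`.
#' @return intermediate latent of length `w_dim` (matrix input: n x `w_dim`).
#' @export
map_latent <- function(z, c, checkpoint) {
  stopifnot(inherits(checkpoint, "ki67_checkpoint"))
  single <- !is.matrix(z)
  if (single) z <- matrix(z, 1)
  if (ncol(z) != checkpoint$spec$z_dim) {
    abort("`z` length does not match the checkpoint's z_dim",
          class = "ki67gan_domain_error")
  }
  cvec <- check_labels(rep_len(c, nrow(z)))
  w <- map_latent_fwd(z, cvec, checkpoint$params,
                      checkpoint$spec$z_dim)$w
  if (single) drop(w) else w
}

# ---- synthesis network ---------------------------------------------------

# broadcast per-sample, per-channel scales over an H x W x C x N tensor
scale_tensor <- function(x, s) .nn_scale(x, s)

synth_fwd <- function(wm, params, spec, cache = FALSE) {
  n <- nrow(wm)
  ch <- spec$channels
  x <- array(params$syn_const, c(4, 4, ch[1], n))
  caches <- if (cache) vector("list", spec$n_blocks)
  for (k in seq_len(spec$n_blocks)) {
    xu <- up2(x)
    s <- wm %*% params[[paste0("A", k)]] + 1
    xm <- scale_tensor(xu, s)
    a <- conv_fwd(xm, params[[paste0("K", k)]], params[[paste0("cb", k)]])
    x <- lrelu(a)
    if (cache) caches[[k]] <- list(xu = xu, s = s, xm = xm, a = a)
  }
  y <- conv_fwd(x, params$Krgb, params$brgb)
  if (cache) list(y = y, x_last = x, caches = caches) else list(y = y)
}

synth_bwd <- function(dy, fw, wm, params, spec) {
  n <- nrow(wm)
  grads <- list()
  g <- conv_bwd(fw$x_last, params$Krgb, dy)
  grads$Krgb <- g$dK; grads$brgb <- g$db
  dx <- g$dx
  dw <- matrix(0, n, ncol(wm))
  for (k in rev(seq_len(spec$n_blocks))) {
    cc <- fw$caches[[k]]
    da <- dx * lrelu_grad(cc$a)
    g <- conv_bwd(cc$xm, params[[paste0("K", k)]], da)
    grads[[paste0("K", k)]] <- g$dK
    grads[[paste0("cb", k)]] <- g$db
    dxm <- g$dx
    dxu <- scale_tensor(dxm, cc$s)
    ds <- .nn_plane_dot(dxm, cc$xu)
    grads[[paste0("A", k)]] <- t(wm) %*% ds
    dw <- dw + ds %*% t(params[[paste0("A", k)]])
    dx <- up2_bwd(dxu)
  }
  dconst <- array(rowSums(matrix(dx, prod(dim(dx)[1:3]), n)),
                  dim(dx)[1:3])
  grads$syn_const <- dconst
  list(grads = grads, dw = dw)
}

#' Synthesise an image from an intermediate latent vector
#'
#' Deterministic given `w` and the checkpoint weights.  The raw linear
#' network output is mapped to 8-bit intensities by
#' `clamp((y + 1) * 127.5, 0, 255)`.
#'
#' @param w intermediate latent of length `w_dim`, or an n x `w_dim` matrix.
#' @param checkpoint a `ki67_checkpoint`.
#' @return an H x W x 3 image array in [0, 255] (matrix input: a list).
#' @export
synthesize <- function(w, checkpoint) {
  stopifnot(inherits(checkpoint, "ki67_checkpoint"))
  single <- !is.matrix(w)
  if (single) w <- matrix(w, 1)
  if (ncol(w) != checkpoint$spec$w_dim) {
    abort("`w` length does not match the checkpoint's w_dim",
          class = "ki67gan_domain_error")
  }
  y <- synth_fwd(w, checkpoint$params, checkpoint$spec)$y
  imgs <- tensor_to_images(y)
  if (single) imgs[[1]] else imgs
}

# ---- discriminator -------------------------------------------------------

disc_init <- function(in_dim, hidden = 128) {
  list(
    W1 = he_weight(in_dim, hidden), b1 = numeric(hidden),
    W2 = he_weight(hidden, hidden), b2 = numeric(hidden),
    w3 = rnorm(hidden, 0, 1 / sqrt(hidden)), b3 = 0,
    vproj = rnorm(hidden, 0, 1 / sqrt(hidden))
  )
}

disc_fwd <- function(v, cvec, p, cache = FALSE) {
  n <- nrow(v)
  a1 <- v %*% p$W1 + matrix(p$b1, n, length(p$b1), byrow = TRUE)
  h1 <- lrelu(a1)
  a2 <- h1 %*% p$W2 + matrix(p$b2, n, length(p$b2), byrow = TRUE)
  h2 <- lrelu(a2)
  out <- as.vector(h2 %*% p$w3) + p$b3 + cvec * as.vector(h2 %*% p$vproj)
  if (cache) list(out = out, cache = list(v = v, cvec = cvec, a1 = a1,
                                          h1 = h1, a2 = a2, h2 = h2))
  else list(out = out)
}

# backward pass; returns parameter grads and the input gradient dv
disc_bwd <- function(dout, cache, p) {
  cvec <- cache$cvec
  dh2 <- outer(dout, p$w3) + outer(dout * cvec, p$vproj)
  dw3 <- as.vector(t(cache$h2) %*% dout)
  dvproj <- as.vector(t(cache$h2) %*% (dout * cvec))
  db3 <- sum(dout)
  da2 <- dh2 * lrelu_grad(cache$a2)
  dW2 <- t(cache$h1) %*% da2
  db2 <- colSums(da2)
  dh1 <- da2 %*% t(p$W2)
  da1 <- dh1 * lrelu_grad(cache$a1)
  dW1 <- t(cache$v) %*% da1
  db1 <- colSums(da1)
  dv <- da1 %*% t(p$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    w3 = dw3, b3 = db3, vproj = dvproj),
       dv = dv)
}

# input gradient of D (n x in_dim), exact a.e. for leaky-ReLU activations
disc_input_grad <- function(cache, p) {
  n <- nrow(cache$v)
  U <- matrix(p$w3, n, length(p$w3), byrow = TRUE) +
    cache$cvec * matrix(p$vproj, n, length(p$vproj), byrow = TRUE)
  T2 <- lrelu_grad(cache$a2) * U
  T1 <- (T2 %*% t(p$W2)) * lrelu_grad(cache$a1)
  list(G = T1 %*% t(p$W1), T1 = T1, T2 = T2)
}

# R1 penalty gamma/2 * E||grad_v D||^2 and its closed-form parameter
# gradients (activation derivative patterns held fixed, exact a.e.)
disc_r1 <- function(cache, p, gamma) {
  if (gamma == 0) {
    return(list(penalty = 0, grads = NULL))
  }
  n <- nrow(cache$v)
  ig <- disc_input_grad(cache, p)
  G <- ig$G
  penalty <- gamma / 2 * mean(rowSums(G^2))
  kappa <- gamma / (2 * n)
  dW1 <- 2 * (t(G) %*% ig$T1)
  GT1 <- 2 * (G %*% p$W1)
  e1 <- GT1 * lrelu_grad(cache$a1)
  dW2 <- t(e1) %*% ig$T2
  GT2 <- e1 %*% p$W2
  e2 <- GT2 * lrelu_grad(cache$a2)
  dw3 <- colSums(e2)
  dvproj <- colSums(cache$cvec * e2)
  list(penalty = penalty,
       grads = list(W1 = kappa * dW1, W2 = kappa * dW2,
                    w3 = kappa * dw3, vproj = kappa * dvproj))
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# random horizontal/vertical flips and transposition of an image batch;
# the fixed substitute for adaptive discriminator augmentation
augment_batch <- function(x) {
  n <- dim(x)[4]
  for (i in seq_len(n)) {
    xi <- x[, , , i, drop = FALSE]
    if (runif(1) < 0.5) xi <- xi[dim(xi)[1]:1, , , , drop = FALSE]
    if (runif(1) < 0.5) xi <- xi[, dim(xi)[2]:1, , , drop = FALSE]
    if (runif(1) < 0.5) xi <- aperm(xi, c(2, 1, 3, 4))
    x[, , , i] <- xi
  }
  x
}

#' Training configuration for the conditional GAN
#'
#' @param total_kimgs training length in thousands of (real) images shown to
#'   the discriminator.
#' @param batch_size minibatch size.
#' @param lr_g,lr_d Adam learning rates for generator and discriminator.
#' @param gamma R1 regularisation weight (> 0 normally; 0 removes the
#'   penalty exactly).
#' @param metric_interval_kimgs FID/PPL logging interval.
#' @param metric_n images per side for logged FID.
#' @param seed integer seed; two runs with the same data and config produce
#'   identical logs and weights.
#' @param z_dim,w_dim,img_size,channels generator architecture
#'   ([generator_spec()]).
#' @param disc_size discriminator input resolution (patches are
#'   average-pooled down to this side before the MLP).
#' @param disc_hidden discriminator hidden width.
#' @param augment apply fixed flip/transpose augmentation in the
#'   discriminator step.
#' @return a list of class `ki67_cgan_config`.
#' @export
cgan_config <- function(total_kimgs = 50, batch_size = 32, lr_g = 2e-3,
                        lr_d = 2e-3, gamma = 2, metric_interval_kimgs = 10,
                        metric_n = 256, seed = 1, z_dim = 64, w_dim = 64,
                        img_size = 64, channels = NULL, disc_size = 32,
                        disc_hidden = 128, augment = TRUE) {
  if (gamma < 0) abort("`gamma` must be >= 0", class = "ki67gan_config_error")
  if (total_kimgs < 0) {
    abort("`total_kimgs` must be >= 0", class = "ki67gan_config_error")
  }
  structure(as.list(environment()), class = "ki67_cgan_config")
}

manifest_training_data <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  if ("keep" %in% names(manifest)) manifest <- manifest[manifest$keep, ]
  if (nrow(manifest) == 0) {
    abort("manifest has no (kept) rows", class = "ki67gan_domain_error")
  }
  labels <- if ("ki67_index" %in% names(manifest)) manifest$ki67_index
            else manifest$true_index
  if (length(unique(labels)) < 2) {
    abort("manifest must contain at least 2 distinct Ki67 labels",
          class = "ki67gan_domain_error")
  }
  images <- purrr::map(seq_len(nrow(manifest)), function(i) {
    manifest_images(manifest[i, ])$he
  })
  list(x = images_to_tensor(images), labels = labels)
}

#' Train the Ki67-conditioned GAN
#'
#' Adversarial training with the non-saturating logistic loss and an R1
#' gradient penalty of weight `gamma` on real batches.  The discriminator
#' receives the (downsampled) patch together with its Ki67 label through a
#' projection term.  Progress is counted in kimgs (thousands of real images
#' shown), and FID and PPL are logged every `metric_interval_kimgs` to track
#' training the way generative-model training curves are usually read.
#'
#' @param manifest a labelled manifest ([label_dataset()] or
#'   [render_dataset()] output); excluded rows (`keep == FALSE`) are dropped.
#' @param config a [cgan_config()].
#' @return an object of class `ki67_cgan_fit`: `checkpoint`
#'   (`ki67_checkpoint`), `log` (tibble with kimgs, fid, ppl, loss_d,
#'   loss_g), `disc` (discriminator weights), `config`.
#' @export
train_cgan <- function(manifest, config = cgan_config()) {
  stopifnot(inherits(config, "ki67_cgan_config"))
  data <- manifest_training_data(manifest)
  n_real <- dim(data$x)[4]
  img_size <- dim(data$x)[1]
  if (img_size != config$img_size) {
    abort(sprintf("manifest images are %dx%d but config$img_size is %d",
                  img_size, img_size, config$img_size),
          class = "ki67gan_config_error")
  }
  spec <- generator_spec(config$z_dim, config$w_dim, config$img_size,
                         config$channels)
  ckpt <- init_generator(spec, seed = config$seed)
  ckpt$label_values <- data$labels
  in_dim <- config$disc_size^2 * 3
  vis <- visual_embedder(seed = config$seed + 1009L)
  perc <- perceptual_embedder(seed = config$seed + 2003L)

  log_rows <- list()
  with_seed(config$seed, {
    disc <- disc_init(in_dim, config$disc_hidden)
    optG <- adam_init(ckpt$params)
    optD <- adam_init(disc)
    bs <- config$batch_size
    n_steps <- ceiling(config$total_kimgs * 1000 / bs)
    next_log <- 0
    loss_d <- loss_g <- NA_real_

    flatten_v <- function(x) {
      x <- pool_to(x, config$disc_size)
      t(matrix(x, in_dim, dim(x)[4]))
    }
    log_metrics <- function(kimgs, ld, lg) {
      nm <- min(config$metric_n, n_real)
      ridx <- sample.int(n_real, nm)
      real_imgs <- tensor_to_images(data$x[, , , ridx, drop = FALSE])
      cf <- sample(data$labels, nm, replace = TRUE)
      z <- matrix(rnorm(nm * spec$z_dim), nm)
      fake_imgs <- synthesize(
        map_latent_fwd(z, cf, ckpt$params, spec$z_dim)$w, ckpt)
      fid_val <- fid(real_imgs, fake_imgs, vis)
      ppl_val <- ppl(ckpt,
                     ppl_config(n_pairs = 16, labels = data$labels),
                     perc, seed = sample.int(1e6, 1))
      log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
        kimgs = kimgs, fid = fid_val, ppl = ppl_val,
        loss_d = ld, loss_g = lg)
    }

    if (n_steps > 0) log_metrics(0, NA_real_, NA_real_)
    for (step in seq_len(n_steps)) {
      # ---- discriminator step
      ridx <- sample.int(n_real, bs, replace = n_real < bs)
      xr <- data$x[, , , ridx, drop = FALSE]
      if (config$augment) xr <- augment_batch(xr)
      vr <- flatten_v(xr)
      cr <- data$labels[ridx]
      zf <- matrix(rnorm(bs * spec$z_dim), bs)
      cf <- sample(data$labels, bs, replace = TRUE)
      wf <- map_latent_fwd(zf, cf, ckpt$params, spec$z_dim)$w
      yf <- synth_fwd(wf, ckpt$params, spec)$y
      if (config$augment) yf <- augment_batch(yf)
      vf <- flatten_v(yf)
      fr <- disc_fwd(vr, cr, disc, cache = TRUE)
      ff <- disc_fwd(vf, cf, disc, cache = TRUE)
      r1 <- disc_r1(fr$cache, disc, config$gamma)
      loss_d <- mean(softplus(-fr$out)) + mean(softplus(ff$out)) +
        r1$penalty
      br <- disc_bwd(-sigmoid(-fr$out) / bs, fr$cache, disc)
      bf <- disc_bwd(sigmoid(ff$out) / bs, ff$cache, disc)
      gd <- add_grads(add_grads(br$grads, bf$grads), r1$grads)
      st <- adam_step(disc, gd, optD, lr = config$lr_d)
      disc <- st$params; optD <- st$state

      # ---- generator step
      zg <- matrix(rnorm(bs * spec$z_dim), bs)
      cg <- sample(data$labels, bs, replace = TRUE)
      mp <- map_latent_fwd(zg, cg, ckpt$params, spec$z_dim, cache = TRUE)
      sy <- synth_fwd(mp$w, ckpt$params, spec, cache = TRUE)
      vg <- flatten_v(sy$y)
      fg <- disc_fwd(vg, cg, disc, cache = TRUE)
      loss_g <- mean(softplus(-fg$out))
      dv <- disc_bwd(-sigmoid(-fg$out) / bs, fg$cache, disc)$dv
      dy <- array(t(dv), c(config$disc_size, config$disc_size, 3, bs))
      while (dim(dy)[1] < img_size) dy <- pool2_bwd(dy)
      sb <- synth_bwd(dy, sy, mp$w, ckpt$params, spec)
      gg <- add_grads(sb$grads,
                      map_latent_bwd(sb$dw, mp$cache, ckpt$params,
                                     spec$z_dim))
      st <- adam_step(ckpt$params, gg, optG, lr = config$lr_g)
      ckpt$params <- st$params; optG <- st$state

      if (!is.finite(loss_d) || !is.finite(loss_g)) {
        abort(sprintf(
          "non-finite loss at %.1f kimgs (loss_d = %g, loss_g = %g)",
          step * bs / 1000, loss_d, loss_g),
          class = "ki67gan_training_error")
      }
      kimgs <- step * bs / 1000
      ckpt$kimgs <- kimgs
      if (kimgs >= next_log + config$metric_interval_kimgs ||
          step == n_steps) {
        next_log <- kimgs
        log_metrics(kimgs, loss_d, loss_g)
      }
    }
  })
  log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else {
    tibble::tibble(kimgs = double(), fid = double(), ppl = double(),
                   loss_d = double(), loss_g = double())
  }
  structure(list(checkpoint = ckpt, log = log, disc = disc,
                 config = config),
            class = "ki67_cgan_fit")
}

#' @export
print.ki67_cgan_fit <- function(x, ...) {
  cat(sprintf("<ki67_cgan_fit> trained %.1f kimgs", x$checkpoint$kimgs))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  (final FID %.2f, PPL %.1f)", last$fid, last$ppl))
  }
  cat("\n")
  invisible(x)
}

#' @rdname train_cgan
#' @param x a `ki67_cgan_fit`.
#' @param ... unused.
#' @export
tidy.ki67_cgan_fit <- function(x, ...) x$log

#' @rdname train_cgan
#' @export
glance.ki67_cgan_fit <- function(x, ...) {
  last <- if (nrow(x$log)) x$log[nrow(x$log), ] else {
    tibble::tibble(fid = NA_real_, ppl = NA_real_)
  }
  tibble::tibble(kimgs = x$checkpoint$kimgs, final_fid = last$fid,
                 final_ppl = last$ppl, gamma = x$config$gamma,
                 batch_size = x$config$batch_size)
}

#' @rdname train_cgan
#' @param object a `ki67_cgan_fit`.
#' @export
autoplot.ki67_cgan_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("fid", "ppl"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kimgs, y = .data$value)) +
    ggplot2::geom_line(colour = "#2171b5") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training progress [kimgs]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Generate images conditioned on a Ki67 index
#'
#' Draws `n` fresh latent vectors and synthesises images all conditioned on
#' `c` (or on per-image labels from `labels`).
#'
#' @param checkpoint a `ki67_checkpoint`.
#' @param c Ki67 condition in [0, 1] (ignored when `labels` is given).
#' @param n number of images.
#' @param labels optional per-image labels: a numeric vector of length `n`
#'   or a function `n -> labels`.
#' @param seed optional integer seed.
#' @return list with `images` (list of H x W x 3 arrays in [0, 255]) and
#'   `labels` (numeric vector).
#' @export
generate_conditional <- function(checkpoint, c = 0.1, n = 1, labels = NULL,
                                 seed = NULL) {
  stopifnot(inherits(checkpoint, "ki67_checkpoint"), n >= 1)
  with_seed(seed, {
    cvec <- if (is.null(labels)) rep(c, n)
            else if (is.function(labels)) labels(n)
            else rep_len(labels, n)
    check_labels(cvec)
    z <- matrix(rnorm(n * checkpoint$spec$z_dim), n)
    w <- map_latent(z, cvec, checkpoint)
    if (!is.matrix(w)) w <- matrix(w, 1)
    imgs <- synthesize(w, checkpoint)
    if (!is.list(imgs)) imgs <- list(imgs)
    list(images = imgs, labels = cvec)
  })
}
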