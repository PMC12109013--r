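# Generative-model evaluation metrics: FID, the FHD variant built on a
# Ki67-regression embedder, and perceptual path length, all against a
# pluggable embedder contract.

#' Embedder contract
#'
#' An embedder maps a list of RGB images to an n x d feature matrix.  FID
#' uses a generic visual embedder, FHD a histological embedder trained to
#' predict the Ki67 index from HE patches, and PPL a perceptual embedder.
#'
#' @param fn function taking a list of images (H x W x 3 arrays, [0, 255])
#'   and returning an n x d numeric matrix.
#' @param d feature dimensionality.
#' @param kind one of `"visual"`, `"histological"`, `"perceptual"`.
#' @param meta optional list of details (seed, architecture, training info).
#' @return an object of class `ki67_embedder`.
#' @export
new_embedder <- function(fn, d, kind = c("visual", "histological",
                                         "perceptual"), meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.function(fn), d >= 1)
  structure(list(fn = fn, d = d, kind = kind, meta = meta),
            class = "ki67_embedder")
}

#' @export
print.ki67_embedder <- function(x, ...) {
  cat(sprintf("<ki67_embedder> kind = %s, d = %d\n", x$kind, x$d))
  invisible(x)
}

#' Embed a set of images
#'
#' @param embedder a [new_embedder()] object.
#' @param images list of H x W x 3 arrays (or a single array / 4-d tensor).
#' @return n x d feature matrix.
#' @export
embed_images <- function(embedder, images) {
  stopifnot(inherits(embedder, "ki67_embedder"))
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  feats <- embedder$fn(images)
  if (!is.matrix(feats) || any(!is.finite(feats))) {
    abort(sprintf("embedder (%s) returned non-finite or non-matrix features",
                  embedder$kind), class = "ki67gan_embedder_error")
  }
  if (ncol(feats) != embedder$d) {
    abort("embedder output dimensionality does not match its declared d",
          class = "ki67gan_embedder_error")
  }
  feats
}

# random-feature CNN embedder: an untrained, fixed-seed convolutional
# backbone followed by a random projection; deterministic and cheap, the
# default stand-in for pretrained classifier features at desk scale
random_feature_embedder <- function(d, kind, seed, input_size = 32) {
  net <- with_seed(seed, cnn_init(input_size = input_size, c1 = 10, c2 = 12,
                                  fc_dim = d, out_dim = 1))
  fn <- function(images) {
    x <- images_to_tensor(images)
    n <- dim(x)[4]
    out <- matrix(0, n, d)
    step <- 256L
    for (from in seq(1L, n, by = step)) {
      to <- min(from + step - 1L, n)
      out[from:to, ] <- cnn_fwd(net, x[, , , from:to, drop = FALSE])$emb
    }
    out
  }
  new_embedder(fn, d = d, kind = kind,
               meta = list(seed = seed, input_size = input_size,
                           trained = FALSE))
}

#' Default visual and perceptual embedders
#'
#' Fixed-seed random-feature convolutional embedders: an untrained
#' convolutional backbone with a random projection head.  Random
#' convolutional features preserve colour and coarse texture statistics,
#' which is what the desk-scale Frechet comparisons need; the contract is
#' embedder-agnostic, so a pretrained backbone can be dropped in via
#' [new_embedder()].
#'
#' @param d feature dimensionality.
#' @param seed seed fixing the random backbone.
#' @return a `ki67_embedder`.
#' @export
visual_embedder <- function(d = 32, seed = 7) {
  random_feature_embedder(d, "visual", seed)
}

#' @rdname visual_embedder
#' @export
perceptual_embedder <- function(d = 64, seed = 11) {
  random_feature_embedder(d, "perceptual", seed)
}

#' Fit Gaussian statistics to an embedded image set
#'
#' Sample mean and unbiased (n - 1) sample covariance of the feature rows:
#' the operands of the Frechet distance.
#'
#' @param features n x d numeric matrix (n >= 2).
#' @return an object of class `gaussian_stats` with fields `mu`, `sigma`, `n`.
#' @export
fit_gaussian <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2) {
    abort("need at least 2 feature rows to fit Gaussian statistics",
          class = "ki67gan_domain_error")
  }
  structure(list(mu = colMeans(features),
                 sigma = stats::cov(features),
                 n = nrow(features)),
            class = "gaussian_stats")
}

#' @export
print.gaussian_stats <- function(x, ...) {
  cat(sprintf("<gaussian_stats> d = %d, n = %d\n", length(x$mu), x$n))
  invisible(x)
}

# trace of the matrix square root of sigma_a %*% sigma_b via the eigenvalues
# of the (generally non-symmetric) product; for PSD factors these are real
# and non-negative up to round-off
trace_sqrt_product <- function(sa, sb) {
  ev <- tryCatch(eigen(sa %*% sb, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(Re(ev)))) {
    jitter <- 1e-10 * diag(nrow(sa))
    ev <- eigen((sa + jitter) %*% (sb + jitter), only.values = TRUE)$values
  }
  sum(sqrt(pmax(Re(ev), 0)))
}

#' Squared Frechet distance between two Gaussians (FID convention)
#'
#' `||mu_a - mu_b||^2 + tr(sigma_a + sigma_b - 2 (sigma_a sigma_b)^{1/2})`,
#' with the matrix square root taken via an eigendecomposition of the
#' covariance product (small-jitter fallback) and the result clipped at 0.
#'
#' @param a,b `gaussian_stats` objects of matching dimensionality.
#' @return non-negative squared Frechet distance.
#' @export
#' @examples
#' s <- fit_gaussian(matrix(rnorm(200), 100, 2))
#' frechet(s, s)
frechet <- function(a, b) {
  stopifnot(inherits(a, "gaussian_stats"), inherits(b, "gaussian_stats"))
  if (length(a$mu) != length(b$mu)) {
    abort("Gaussian statistics have mismatched dimensionality",
          class = "ki67gan_domain_error")
  }
  d2 <- sum((a$mu - b$mu)^2) +
    sum(diag(a$sigma)) + sum(diag(b$sigma)) -
    2 * trace_sqrt_product(a$sigma, b$sigma)
  if (!is.finite(d2)) {
    abort("Frechet distance is non-finite", class = "ki67gan_domain_error")
  }
  max(d2, 0)
}

frechet_from_images <- function(real, generated, embedder) {
  fr <- embed_images(embedder, real)
  fg <- embed_images(embedder, generated)
  frechet(fit_gaussian(fr), fit_gaussian(fg))
}

#' Frechet Inception Distance between real and generated image sets
#'
#' Embeds both sets with a generic visual embedder, fits Gaussian statistics
#' to each and returns their squared Frechet distance.
#'
#' @param real,generated lists of H x W x 3 images (>= 2 each).
#' @param embedder a visual `ki67_embedder`.
#' @return FID value (non-negative).
#' @export
fid <- function(real, generated, embedder = visual_embedder()) {
  frechet_from_images(real, generated, embedder)
}

#' Frechet Histological Distance
#'
#' FID with the generic visual embedder replaced by a histological embedder:
#' a model trained to predict the Ki67 index from HE patches, embedding
#' images as its penultimate-layer activations
#' (see [train_histological_embedder()]).
#'
#' @inheritParams fid
#' @param embedder a histological `ki67_embedder`.
#' @return FHD value (non-negative).
#' @export
fhd <- function(real, generated, embedder) {
  stopifnot(inherits(embedder, "ki67_embedder"))
  if (embedder$kind != "histological") {
    warn("fhd called with a non-histological embedder")
  }
  frechet_from_images(real, generated, embedder)
}

#' Train the histological embedder (Ki67 regressor) on a labelled manifest
#'
#' Trains a small convolutional regressor to predict the Ki67 index from the
#' HE patch (mean-squared-error loss, Adam).  The embedding is the
#' penultimate fully connected layer's activations.
#'
#' @param labeled a [label_dataset()] manifest; only `keep` rows are used.
#'   The label column is `ki67_index` when present, else `true_index`.
#' @param d embedding dimensionality (penultimate layer width).
#' @param epochs,batch_size,lr training schedule.
#' @param seed integer seed; training is deterministic given the seed.
#' @param input_size internal resolution of the regressor.
#' @return a `ki67_embedder` of kind `"histological"` with `meta$net` (the
#'   trained network), `meta$predict` (images -> predicted indices) and
#'   `meta$history` (per-epoch training loss).
#' @export
train_histological_embedder <- function(labeled, d = 32, epochs = 4,
                                        batch_size = 32, lr = 2e-3,
                                        seed = 1, input_size = 32) {
  stopifnot(is.data.frame(labeled))
  if ("keep" %in% names(labeled)) labeled <- labeled[labeled$keep, ]
  if (nrow(labeled) < 50) {
    abort("need at least 50 kept rows to train the histological embedder",
          class = "ki67gan_domain_error")
  }
  y <- if ("ki67_index" %in% names(labeled)) labeled$ki67_index
       else labeled$true_index
  images <- purrr::map(seq_len(nrow(labeled)), function(i) {
    manifest_images(labeled[i, ])$he
  })
  x_all <- images_to_tensor(images)
  n <- length(y)
  with_seed(seed, {
    net <- cnn_init(input_size = input_size, c1 = 12, c2 = 16, fc_dim = d,
                    out_dim = 1)
    opt <- adam_init(net$params)
    history <- numeric(0)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (from in seq(1L, n, by = batch_size)) {
        idx <- ord[from:min(from + batch_size - 1L, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        fw <- cnn_fwd(net, xb, cache = TRUE)
        err <- fw$out - matrix(y[idx], ncol = 1)
        losses <- c(losses, mean(err^2))
        grads <- cnn_bwd(net, fw$cache, 2 * err / length(idx))
        st <- adam_step(net$params, grads, opt, lr = lr, beta1 = 0.5)
        net$params <- st$params
        opt <- st$state
      }
      history <- c(history, mean(losses))
    }
    predict_fn <- function(imgs) {
      as.vector(cnn_fwd(net, images_to_tensor(imgs))$out)
    }
    fn <- function(imgs) {
      x <- images_to_tensor(imgs)
      nn <- dim(x)[4]
      out <- matrix(0, nn, d)
      step <- 256L
      for (from in seq(1L, nn, by = step)) {
        to <- min(from + step - 1L, nn)
        out[from:to, ] <- cnn_fwd(net, x[, , , from:to, drop = FALSE])$emb
      }
      out
    }
    new_embedder(fn, d = d, kind = "histological",
                 meta = list(net = net, predict = predict_fn,
                             history = history, seed = seed,
                             n_train = n))
  })
}

#' Perceptual path length configuration
#'
#' @param epsilon interpolation step (> 0).
#' @param n_pairs number of interpolation pairs sampled.
#' @param space `"input-latent"` (spherical interpolation in z) or
#'   `"intermediate-latent"` (linear interpolation in w).
#' @param label_policy `"sampled"` draws one Ki67 label per pair from
#'   `labels` (held fixed along the path); `"fixed"` uses `label` for all.
#' @param label fixed conditioning value (policy `"fixed"`).
#' @param labels pool of labels resampled under policy `"sampled"`; defaults
#'   to the checkpoint's stored training labels, else Uniform(0, 1).
#' @return a list of class `ppl_config`.
#' @export
ppl_config <- function(epsilon = 1e-4, n_pairs = 64,
                       space = c("input-latent", "intermediate-latent"),
                       label_policy = c("sampled", "fixed"),
                       label = 0.1, labels = NULL) {
  if (epsilon <= 0) {
    abort("`epsilon` must be > 0", class = "ki67gan_config_error")
  }
  stopifnot(n_pairs >= 1)
  structure(list(epsilon = epsilon, n_pairs = n_pairs,
                 space = match.arg(space),
                 label_policy = match.arg(label_policy),
                 label = label, labels = labels),
            class = "ppl_config")
}

slerp <- function(z1, z2, t) {
  n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
  if (n1 < 1e-12 || n2 < 1e-12) return(z1 + t * (z2 - z1))
  cosang <- clamp(sum(z1 * z2) / (n1 * n2), -1, 1)
  omega <- acos(cosang)
  if (abs(sin(omega)) < 1e-8) return(z1 + t * (z2 - z1))
  (sin((1 - t) * omega) * z1 + sin(t * omega) * z2) / sin(omega)
}

#' Perceptual path length of a generator's latent space
#'
#' Mean of `d(G(interp(t)), G(interp(t + epsilon)))^2 / epsilon^2` over
#' random latent pairs and `t ~ U(0, 1)`, where `d` is the Euclidean distance
#' in the perceptual embedder's feature space.  Interpolation is spherical in
#' the input latent space or linear in the intermediate space.  Lower values
#' indicate a smoother, more disentangled latent space.
#'
#' @param generator a `ki67_checkpoint`, or a function `(z_matrix, labels) ->
#'   list of images` for custom generators (input-latent space only).
#' @param config a [ppl_config()].
#' @param embedder perceptual `ki67_embedder`.
#' @param seed integer seed.
#' @param z_dim latent dimensionality when `generator` is a function.
#' @return the PPL value.
#' @export
ppl <- function(generator, config = ppl_config(),
                embedder = perceptual_embedder(), seed = 1, z_dim = NULL) {
  stopifnot(inherits(config, "ppl_config"))
  is_ckpt <- inherits(generator, "ki67_checkpoint")
  if (!is_ckpt && config$space == "intermediate-latent") {
    abort("intermediate-latent PPL requires a checkpoint generator",
          class = "ki67gan_config_error")
  }
  zd <- if (is_ckpt) generator$spec$z_dim else z_dim
  if (is.null(zd)) {
    abort("`z_dim` is required for a function generator",
          class = "ki67gan_config_error")
  }
  gen_fn <- if (is_ckpt) {
    function(z, cvec) {
      synthesize(map_latent(z, cvec, generator), generator)
    }
  } else generator
  with_seed(seed, {
    np <- config$n_pairs
    eps <- config$epsilon
    labels <- switch(config$label_policy,
      fixed = rep(config$label, np),
      sampled = {
        pool <- config$labels %||%
          (if (is_ckpt) generator$label_values else NULL)
        if (is.null(pool) || !length(pool)) runif(np)
        else sample(pool, np, replace = TRUE)
      })
    z1 <- matrix(rnorm(np * zd), np, zd)
    z2 <- matrix(rnorm(np * zd), np, zd)
    tt <- runif(np)
    if (config$space == "input-latent") {
      za <- t(vapply(seq_len(np), function(i)
        slerp(z1[i, ], z2[i, ], tt[i]), numeric(zd)))
      zb <- t(vapply(seq_len(np), function(i)
        slerp(z1[i, ], z2[i, ], tt[i] + eps), numeric(zd)))
      ia <- gen_fn(za, labels)
      ib <- gen_fn(zb, labels)
    } else {
      wa1 <- map_latent(z1, labels, generator)
      wa2 <- map_latent(z2, labels, generator)
      wa <- wa1 + tt * (wa2 - wa1)
      wb <- wa1 + (tt + eps) * (wa2 - wa1)
      ia <- synthesize(wa, generator)
      ib <- synthesize(wb, generator)
    }
    ea <- embed_images(embedder, ia)
    eb <- embed_images(embedder, ib)
    mean(rowSums((ea - eb)^2) / eps^2)
  })
}
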