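# Synthetic HE/Ki67 patch-pair simulator.
#
# Adjacent-section patch pairs share one nuclei layout: the HE rendering shows
# all nuclei in hematoxylin purple on an eosin-pink background, while the Ki67
# rendering recolours a subset of the same nuclei DAB-brown (Ki67-positive)
# and the remainder hematoxylin blue on a pale IHC background.  The
# ground-truth index is the brown-pixel fraction over ALL pixels of the patch,
# matching the annotation pipeline's definition, so annotation-recovery tests
# close the loop exactly.
#
# Nuclei coverage grows linearly with the target index (coverage =
# index + coverage_base), which is also what makes the index visible in the
# HE rendering alone: a patch with more Ki67-positive tissue carries more
# nuclei.  `estimate_he_index()` in the annotation module inverts that
# calibration.

#' Ki67 label distribution specification
#'
#' Defines how ground-truth Ki67 indices are drawn when simulating a dataset.
#' The `"paper-imbalanced"` spec emulates the heavy class imbalance of real
#' seminoma patch collections: most patches below 0.1 and only about 2% above
#' 0.5.  It is a mixture of Beta(1, 12) (weight 0.976) and Uniform(0.4, 1)
#' (weight 0.024), which gives P(index > 0.5) = 0.020.
#'
#' @param name one of `"paper-imbalanced"`, `"uniform"`, `"point-mass"`.
#' @param ... distribution parameters; `"point-mass"` requires `value`,
#'   `"paper-imbalanced"` accepts `tail_weight`, `shape2` and `tail_min`.
#' @return an object of class `ki67_label_spec`.
#' @export
#' @examples
#' spec <- label_distribution("paper-imbalanced")
#' mean(sample_ki67_label(spec, 1000, seed = 1) > 0.5)
label_distribution <- function(name = c("paper-imbalanced", "uniform",
                                        "point-mass"), ...) {
  name <- tryCatch(match.arg(name), error = function(e) {
    abort(sprintf("unknown label distribution `%s`", name[1]),
          class = "ki67gan_config_error")
  })
  params <- list(...)
  if (name == "point-mass") {
    if (is.null(params$value)) {
      abort("point-mass spec requires `value`", class = "ki67gan_config_error")
    }
    stopifnot(params$value >= 0, params$value <= 1)
  }
  if (name == "paper-imbalanced") {
    params$tail_weight <- params$tail_weight %||% 0.024
    params$shape2 <- params$shape2 %||% 12
    params$tail_min <- params$tail_min %||% 0.4
  }
  structure(list(name = name, params = params), class = "ki67_label_spec")
}

#' @export
print.ki67_label_spec <- function(x, ...) {
  cat("<ki67_label_spec>", x$name, "\n")
  if (length(x$params)) {
    cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Draw Ki67 index labels from a distribution spec
#'
#' @param spec a [label_distribution()] object.
#' @param n number of draws.
#' @param seed optional integer; when given, draws are reproducible and the
#'   session RNG is left untouched.
#' @return numeric vector of fractions in [0, 1].
#' @export
sample_ki67_label <- function(spec, n = 1, seed = NULL) {
  if (!inherits(spec, "ki67_label_spec")) {
    abort("`spec` must be created by label_distribution()",
          class = "ki67gan_config_error")
  }
  with_seed(seed, {
    switch(spec$name,
      "point-mass" = rep(spec$params$value, n),
      "uniform" = runif(n),
      "paper-imbalanced" = {
        p <- spec$params
        tail <- runif(n) < p$tail_weight
        x <- rbeta(n, 1, p$shape2)
        x[tail] <- runif(sum(tail), p$tail_min, 1)
        pmin(x, 1)
      }
    )
  })
}

# rendering palette; jitter is applied per patch / per nucleus / per pixel
.palette <- list(
  he_bg       = c(233, 182, 205),
  he_nucleus  = c(118, 70, 158),
  ki_bg       = c(238, 234, 228),
  ki_negative = c(95, 110, 175),
  ki_positive = c(145, 95, 45)
)

# rasterise one ellipse; returns linear pixel indices within the size x size
# patch (row-major h + size*(w-1) in column-major matrix terms)
ellipse_pixels <- function(cx, cy, a, b, theta, size) {
  r <- ceiling(max(a, b))
  xs <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(integer(0))
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (gx * ct + gy * st) / a
  v <- (-gx * st + gy * ct) / b
  inside <- u * u + v * v <= 1
  row <- rep(ys, times = length(xs))[inside]
  col <- rep(xs, each = length(ys))[inside]
  row + size * (col - 1L)
}

# place elliptical nuclei until `target_coverage` of the patch is covered.
# Overlap is discouraged (mostly distinct blobs at low coverage) but allowed
# once rejection dominates, so high coverage remains reachable.
place_nuclei <- function(target_coverage, size, radius_scale = size / 64) {
  label_map <- matrix(0L, size, size)
  covered <- 0L
  target_px <- round(target_coverage * size * size)
  id <- 0L
  consecutive_rej <- 0L
  attempts <- 0L
  max_attempts <- 40000L
  while (covered < target_px && attempts < max_attempts) {
    attempts <- attempts + 1L
    a <- runif(1, 2.6, 4.2) * radius_scale
    b <- a * runif(1, 0.65, 0.95)
    px <- ellipse_pixels(runif(1, 1, size), runif(1, 1, size),
                         a, b, runif(1, 0, pi), size)
    if (length(px) < 4L) next
    overlap <- mean(label_map[px] > 0L)
    limit <- if (consecutive_rej < 150L) 0.25
             else if (consecutive_rej < 400L) 0.6 else 1
    if (overlap > limit) {
      consecutive_rej <- consecutive_rej + 1L
      next
    }
    consecutive_rej <- 0L
    id <- id + 1L
    covered <- covered + sum(label_map[px] == 0L)
    label_map[px] <- id
    if (id > 100000L) break
  }
  label_map
}

# paint pixels of one colour class with per-pixel jitter onto channel matrices
paint <- function(channels, idx, base, jitter_sd = 2.5, shift = c(0, 0, 0)) {
  for (ch in 1:3) {
    channels[[ch]][idx] <- base[ch] + shift[ch] +
      rnorm(length(idx), 0, jitter_sd)
  }
  channels
}

#' Render one synthetic HE/Ki67 patch pair
#'
#' @param p target Ki67 index in [0, 1]; fraction of all patch pixels to be
#'   rendered Ki67-positive (brown) in the Ki67 image.  Values that exceed
#'   the achievable nuclei coverage are clamped with a warning.
#' @param size patch side in pixels (>= 32; default 64).
#' @param seed optional integer seed.
#' @param coverage_base nuclei area fraction of a `p = 0` patch; coverage is
#'   `p + coverage_base`, capped at `max_coverage`.
#' @param max_coverage maximum nuclei area fraction attempted.
#' @param patch_id identifier stored with the pair.
#' @return an object of class `patch_pair` with fields `he_image`,
#'   `ki67_image` (H x W x 3, 8-bit), `true_index` (realised brown fraction),
#'   `requested_index`, `nuclei_mask`, `positive_mask`, `patch_id`.
#' @export
#' @examples
#' pair <- render_patch_pair(0.2, size = 64, seed = 1)
#' pair$true_index
render_patch_pair <- function(p, size = 64, seed = NULL,
                              coverage_base = 0.12, max_coverage = 0.88,
                              patch_id = "patch") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single value in [0, 1]",
          class = "ki67gan_domain_error")
  }
  stopifnot(size >= 32)
  with_seed(seed, {
    coverage <- min(p + coverage_base, max_coverage)
    label_map <- place_nuclei(coverage, size)
    n_nuclei <- max(label_map)
    counts <- tabulate(label_map[label_map > 0L], nbins = n_nuclei)
    total_px <- size * size
    target_px <- round(p * total_px)
    achievable <- sum(counts)
    if (target_px > achievable) {
      warn(sprintf(
        "requested index %.3f exceeds achievable nuclei coverage %.3f; clamped",
        p, achievable / total_px))
      target_px <- achievable
    }
    # greedy nucleus-level selection of the Ki67-positive subset
    ord <- sample.int(n_nuclei)
    cum <- cumsum(counts[ord])
    n_take <- sum(cum <= target_px)
    taken <- if (n_take > 0L) cum[n_take] else 0L
    if (n_take < n_nuclei &&
        abs(cum[n_take + 1L] - target_px) < abs(taken - target_px)) {
      n_take <- n_take + 1L
    }
    positive_ids <- if (n_take > 0L) ord[seq_len(n_take)] else integer(0)

    nuclei_mask <- label_map > 0L
    positive_mask <- matrix(label_map %in% positive_ids & nuclei_mask,
                            size, size)
    true_index <- sum(positive_mask) / total_px

    he <- lapply(1:3, function(ch) {
      matrix(.palette$he_bg[ch] + rnorm(1, 0, 6) +
               rnorm(total_px, 0, 2.5), size, size)
    })
    ki <- lapply(1:3, function(ch) {
      matrix(.palette$ki_bg[ch] + rnorm(1, 0, 3) +
               rnorm(total_px, 0, 2.5), size, size)
    })
    for (i in seq_len(n_nuclei)) {
      idx <- which(label_map == i)
      shift <- rnorm(3, 0, 10)
      he <- paint(he, idx, .palette$he_nucleus, shift = shift)
      ki_base <- if (i %in% positive_ids) .palette$ki_positive
                 else .palette$ki_negative
      ki <- paint(ki, idx, ki_base, shift = rnorm(3, 0, 8))
    }
    to_img <- function(chs) {
      out <- array(0, c(size, size, 3))
      for (ch in 1:3) out[, , ch] <- clamp(round(chs[[ch]]), 0, 255)
      out
    }
    structure(list(
      he_image = to_img(he),
      ki67_image = to_img(ki),
      true_index = true_index,
      requested_index = p,
      nuclei_mask = nuclei_mask,
      positive_mask = positive_mask,
      patch_id = patch_id,
      degraded = NA_character_
    ), class = "patch_pair")
  })
}

#' @export
print.patch_pair <- function(x, ...) {
  d <- dim(x$he_image)
  cat(sprintf("<patch_pair> %s  %dx%d  true_index = %.4f%s\n",
              x$patch_id, d[1], d[2], x$true_index,
              if (!is.na(x$degraded)) paste0("  degraded: ", x$degraded)
              else ""))
  invisible(x)
}

#' Degrade a patch pair to emulate low-quality tissue patches
#'
#' The four modes emulate the patch types a quality filter must exclude:
#' out-of-focus scans (`blur`), empty glass (`blank`), tearing artifacts with
#' large white regions (`tear`) and patches with too little cellular content
#' (`sparse`).
#'
#' @param pair a [render_patch_pair()] object.
#' @param mode one of `"blur"`, `"blank"`, `"tear"`, `"sparse"`.
#' @param sigma Gaussian blur standard deviation in pixels (mode `blur`).
#' @param fraction fraction of the patch covered by the white tear region
#'   (mode `tear`).
#' @param keep_nuclei number of nuclei retained in mode `sparse`.
#' @param seed optional integer seed.
#' @return a degraded `patch_pair`; the `degraded` field records the mode.
#' @export
degrade <- function(pair, mode = c("blur", "blank", "tear", "sparse"),
                    sigma = 5, fraction = 0.75, keep_nuclei = 4,
                    seed = NULL) {
  stopifnot(inherits(pair, "patch_pair"))
  mode <- tryCatch(match.arg(mode), error = function(e) {
    abort(sprintf("unknown degradation mode `%s`", mode[1]),
          class = "ki67gan_config_error")
  })
  size <- dim(pair$he_image)[1]
  with_seed(seed, {
    out <- pair
    if (mode == "blur") {
      out$he_image <- clamp(EBImage::gblur(pair$he_image, sigma = sigma),
                            0, 255)
      out$ki67_image <- clamp(EBImage::gblur(pair$ki67_image, sigma = sigma),
                              0, 255)
    } else if (mode == "blank") {
      blank <- function() {
        x <- array(250 + rnorm(size * size * 3, 0, 0.8), c(size, size, 3))
        clamp(x, 0, 255)
      }
      out$he_image <- blank()
      out$ki67_image <- blank()
      out$nuclei_mask[] <- FALSE
      out$positive_mask[] <- FALSE
    } else if (mode == "tear") {
      stopifnot(fraction > 0, fraction <= 1)
      n_rows <- ceiling(fraction * size)
      from_top <- runif(1) < 0.5
      rows <- if (from_top) seq_len(n_rows) else (size - n_rows + 1L):size
      white <- function(img) {
        img[rows, , ] <- clamp(252 + rnorm(length(rows) * size * 3, 0, 1),
                               0, 255)
        img
      }
      out$he_image <- white(out$he_image)
      out$ki67_image <- white(out$ki67_image)
      out$nuclei_mask[rows, ] <- FALSE
      out$positive_mask[rows, ] <- FALSE
    } else { # sparse: repaint all but `keep_nuclei` nuclei with background
      lm <- matrix(0L, size, size)
      lm[pair$nuclei_mask] <- 1L
      comp <- EBImage::bwlabel(lm)
      keep <- sample(seq_len(max(comp)), min(keep_nuclei, max(comp)))
      drop_idx <- which(comp > 0 & !(comp %in% keep))
      he <- lapply(1:3, function(ch) out$he_image[, , ch])
      ki <- lapply(1:3, function(ch) out$ki67_image[, , ch])
      he <- paint(he, drop_idx, .palette$he_bg)
      ki <- paint(ki, drop_idx, .palette$ki_bg)
      for (ch in 1:3) {
        out$he_image[, , ch] <- clamp(round(he[[ch]]), 0, 255)
        out$ki67_image[, , ch] <- clamp(round(ki[[ch]]), 0, 255)
      }
      out$nuclei_mask[drop_idx] <- FALSE
      out$positive_mask[drop_idx] <- FALSE
    }
    out$true_index <- sum(out$positive_mask) / (size * size)
    out$degraded <- mode
    out
  })
}

#' Simulate a dataset of patch pairs
#'
#' Convenience wrapper drawing labels from a distribution spec and rendering
#' one pair per label.  Returns an in-memory manifest that downstream
#' functions ([label_dataset()], [train_cgan()]) accept directly.
#'
#' @param n number of pairs.
#' @param size patch side in pixels.
#' @param spec a [label_distribution()]; defaults to the imbalanced spec that
#'   emulates real seminoma label distributions.
#' @param seed integer seed (required for reproducibility).
#' @param degrade_fraction fraction of pairs degraded (split evenly over the
#'   four modes) for filter testing.
#' @return a tibble with columns `patch_id`, `pair` (list of `patch_pair`),
#'   `true_index`, `degraded`.
#' @export
render_dataset <- function(n, size = 64,
                           spec = label_distribution("paper-imbalanced"),
                           seed = 1, degrade_fraction = 0) {
  labels <- sample_ki67_label(spec, n, seed = seed)
  modes <- c("blur", "blank", "tear", "sparse")
  n_degrade <- round(degrade_fraction * n)
  degrade_plan <- rep(NA_character_, n)
  if (n_degrade > 0) {
    degrade_plan[seq_len(n_degrade)] <-
      rep(modes, length.out = n_degrade)
    degrade_plan <- with_seed(seed + 1L, sample(degrade_plan))
  }
  pairs <- purrr::map(seq_len(n), function(i) {
    pr <- render_patch_pair(labels[i], size = size, seed = seed + 13L + i,
                            patch_id = sprintf("p%05d", i))
    if (!is.na(degrade_plan[i])) {
      pr <- degrade(pr, degrade_plan[i], seed = seed + 31L + i)
    }
    pr
  })
  tibble::tibble(
    patch_id = purrr::map_chr(pairs, "patch_id"),
    pair = pairs,
    true_index = purrr::map_dbl(pairs, "true_index"),
    degraded = degrade_plan
  )
}

#' Write a dataset of patch pairs to disk
#'
#' Writes one PNG per image and a CSV manifest (`manifest.csv`) with columns
#' `patch_id`, `he_path`, `ki67_path`, `true_index`.  Indices round-trip
#' bit-identically through the manifest.
#'
#' @param pairs a list of `patch_pair` objects or a [render_dataset()] tibble.
#' @param directory output directory (created if needed).
#' @return the manifest path, invisibly a tibble attribute-free path string.
#' @export
write_dataset <- function(pairs, directory) {
  if (tibble::is_tibble(pairs)) pairs <- pairs$pair
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      abort(sprintf("cannot create directory: %s", directory),
            class = "ki67gan_io_error")
    }
  }
  rows <- purrr::map(pairs, function(p) {
    stopifnot(inherits(p, "patch_pair"))
    he_path <- file.path(directory, paste0(p$patch_id, "_he.png"))
    ki_path <- file.path(directory, paste0(p$patch_id, "_ki67.png"))
    write_image(p$he_image, he_path)
    write_image(p$ki67_image, ki_path)
    tibble::tibble(patch_id = p$patch_id, he_path = he_path,
                   ki67_path = ki_path, true_index = p$true_index)
  })
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(patch_id = character(), he_path = character(),
                   ki67_path = character(), true_index = double())
  }
  manifest_path <- file.path(directory, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  manifest_path
}

#' Read a dataset manifest written by [write_dataset()]
#'
#' @param manifest_path path to `manifest.csv`.
#' @return tibble with columns `patch_id`, `he_path`, `ki67_path`,
#'   `true_index`.
#' @export
read_manifest <- function(manifest_path) {
  readr::read_csv(manifest_path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patch_id = readr::col_character(),
                    he_path = readr::col_character(),
                    ki67_path = readr::col_character(),
                    true_index = readr::col_double()
                  ))
}

#' Histogram of a label distribution across the Ki67 intervals
#'
#' @param labels numeric vector of Ki67 indices.
#' @return a ggplot object showing interval shares.
#' @export
plot_label_distribution <- function(labels) {
  iv <- ki67_intervals(include_full = FALSE)
  shares <- purrr::map_dbl(seq_len(nrow(iv)), function(i) {
    mean(in_interval(labels, iv[i, ]))
  })
  df <- tibble::tibble(interval = factor(iv$label, levels = iv$label),
                       share = shares)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$share)) +
    ggplot2::geom_col(fill = "#8c6bb1") +
    ggplot2::labs(x = "Ki67 interval", y = "share of patches") +
    ggplot2::theme_minimal()
}
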