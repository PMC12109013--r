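# Ki67-sweep sequences: one fixed latent vector, the Ki67 condition swept
# over an ordered grid, and a rank-correlation trend statistic that asks
# whether the sweep is expressed in the generated images.

#' Specification of one Ki67 sweep sequence
#'
#' The default protocol: six images from one latent vector, Ki67 starting at
#' 0 and increasing to 0.5 in steps of 0.1.  Grids reaching above 0.5 are
#' allowed but warn, since conditional generators trained on imbalanced data
#' are least reliable there.
#'
#' @param z latent vector (length `z_dim`); drawn fresh when `NULL`.
#' @param grid strictly increasing Ki67 values in [0, 1].
#' @param id sequence identifier.
#' @param z_dim latent dimensionality used when drawing `z`.
#' @param seed optional seed for the `z` draw.
#' @return a list of class `sequence_spec`.
#' @export
sequence_spec <- function(z = NULL, grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                          id = "seq", z_dim = 64, seed = NULL) {
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 1)) {
    abort("sequence grid values must lie in [0, 1]",
          class = "ki67gan_domain_error")
  }
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    abort("sequence grid must be strictly increasing",
          class = "ki67gan_domain_error")
  }
  if (any(grid > 0.5)) {
    warn("grid reaches above Ki67 = 0.5, where conditioning is least reliable")
  }
  if (is.null(z)) z <- with_seed(seed, rnorm(z_dim))
  structure(list(z = z, grid = grid, id = id), class = "sequence_spec")
}

#' Generate one Ki67 sweep sequence
#'
#' One image per grid value, all synthesised from the spec's single latent
#' vector; deterministic given checkpoint and spec.  Each image is scored
#' with the annotation module's HE index proxy ([estimate_he_index()]) and
#' the sequence's trend statistic is attached.
#'
#' @param checkpoint a `ki67_checkpoint`.
#' @param spec a [sequence_spec()].
#' @return an object of class `ki67_sequence`: `spec`, `images` (list),
#'   `recovered` (per-image estimated index), `trend`.
#' @export
generate_sequence <- function(checkpoint, spec) {
  stopifnot(inherits(checkpoint, "ki67_checkpoint"),
            inherits(spec, "sequence_spec"))
  z <- matrix(spec$z, length(spec$grid), length(spec$z), byrow = TRUE)
  w <- map_latent(z, spec$grid, checkpoint)
  images <- synthesize(w, checkpoint)
  recovered <- purrr::map_dbl(images, estimate_he_index)
  res <- structure(list(spec = spec, images = images,
                        recovered = recovered, trend = NA_real_),
                   class = "ki67_sequence")
  res$trend <- sequence_trend(res)
  res
}

#' @export
print.ki67_sequence <- function(x, ...) {
  cat(sprintf("<ki67_sequence> %s: %d images, grid [%s], trend = %.2f\n",
              x$spec$id, length(x$images),
              paste(x$spec$grid, collapse = ", "), x$trend))
  invisible(x)
}

#' Trend statistic of a sequence
#'
#' Spearman rank correlation between the Ki67 grid and the recovered indices
#' of the generated images: a quantitative stand-in for the qualitative
#' "consistent increase of tumour cells" reading of a sweep.  Constant
#' recovered indices give 0 with a tie warning.
#'
#' @param result a `ki67_sequence`, or a numeric vector of recovered indices
#'   (then `grid` must be supplied).
#' @param grid grid values matching `result` when it is a plain vector.
#' @return rank correlation in [-1, 1].
#' @export
sequence_trend <- function(result, grid = NULL) {
  if (inherits(result, "ki67_sequence")) {
    grid <- result$spec$grid
    recovered <- result$recovered
  } else {
    recovered <- result
  }
  stopifnot(length(recovered) == length(grid), length(grid) >= 3)
  if (sd(recovered) == 0) {
    warn("recovered indices are constant (all tied); trend set to 0")
    return(0)
  }
  suppressWarnings(cor(grid, recovered, method = "spearman"))
}

#' Generate a group of sweep sequences
#'
#' `n` sequences with independent latent draws sharing the default grid.
#'
#' @param checkpoint a `ki67_checkpoint`.
#' @param n number of sequences (a published evaluation group used 20).
#' @param grid shared Ki67 grid.
#' @param seed integer seed.
#' @return list of `ki67_sequence` objects, class `ki67_sequence_group`.
#' @export
generate_sequence_group <- function(checkpoint, n = 20,
                                    grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                                    seed = 1) {
  stopifnot(n >= 1)
  zd <- checkpoint$spec$z_dim
  specs <- with_seed(seed, purrr::map(seq_len(n), function(i) {
    sequence_spec(z = rnorm(zd), grid = grid, id = sprintf("seq%02d", i))
  }))
  structure(purrr::map(specs, ~generate_sequence(checkpoint, .x)),
            class = "ki67_sequence_group")
}

#' @export
print.ki67_sequence_group <- function(x, ...) {
  cat(sprintf("<ki67_sequence_group> %d sequences, median trend = %.2f\n",
              length(x), stats::median(purrr::map_dbl(x, "trend"))))
  invisible(x)
}

#' @rdname generate_sequence_group
#' @param x a `ki67_sequence_group`.
#' @param ... unused.
#' @export
tidy.ki67_sequence_group <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(i) {
    s <- x[[i]]
    tibble::tibble(sequence = i, position = seq_along(s$spec$grid),
                   ki67 = s$spec$grid, recovered = s$recovered,
                   trend = s$trend)
  })
}

#' Write a sequence-group montage PNG
#'
#' Rows are sequences, columns the Ki67 grid, matching the usual published
#' layout of sweep figures.
#'
#' @param group a `ki67_sequence_group`.
#' @param path output PNG path.
#' @param gap gap between tiles in pixels.
#' @return the path, invisibly.
#' @export
write_sequence_montage <- function(group, path, gap = 2) {
  stopifnot(length(group) >= 1)
  d <- dim(group[[1]]$images[[1]])
  n_col <- length(group[[1]]$images)
  n_row <- length(group)
  H <- n_row * d[1] + (n_row - 1) * gap
  W <- n_col * d[2] + (n_col - 1) * gap
  canvas <- array(255, c(H, W, 3))
  for (i in seq_len(n_row)) {
    for (j in seq_len(n_col)) {
      r0 <- (i - 1) * (d[1] + gap)
      c0 <- (j - 1) * (d[2] + gap)
      canvas[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <-
        group[[i]]$images[[j]]
    }
  }
  write_image(canvas, path)
  invisible(path)
}
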