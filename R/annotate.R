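# Semi-automated Ki67 annotation: colour clustering of the IHC patch,
# brown-pixel quantification, HE quality filtering, and manifest labelling.

#' Colour-based clustering of a Ki67-stained patch
#'
#' k-means in CIE Lab space.  The Ki67-positive cluster is the cluster whose
#' centroid satisfies the DAB-brown rule: HSV hue in [15, 50] degrees,
#' saturation > 0.2, value in [0.15, 0.85].  Ties between brown centroids are
#' broken towards the larger cluster.
#'
#' @param ki67_image numeric H x W x 3 array, intensities in [0, 255].
#' @param k number of colour clusters (>= 2; default 3: positive brown,
#'   negative blue, background).
#' @param seed integer seed making the clustering deterministic.
#' @return an object of class `cluster_map` with fields `labels` (H x W
#'   integers in 1..k), `centroids` (k x 3 RGB), `positive_cluster` (integer
#'   or `NA` when no centroid is brown), `sizes`.
#' @export
cluster_stain <- function(ki67_image, k = 3, seed = 1) {
  assert_rgb_image(ki67_image, "ki67_image")
  stopifnot(k >= 2)
  d <- dim(ki67_image)
  px <- matrix(ki67_image, d[1] * d[2], 3)
  n_distinct <- nrow(unique(px))
  lab <- rgb_to_lab_rows(px)
  if (n_distinct < k) {
    warn(sprintf(
      "k = %d exceeds the %d distinct colours; using distinct colours", k,
      n_distinct))
    centres_rgb <- unique(px)
    centres <- rgb_to_lab_rows(centres_rgb)
    dmat <- outer(rowSums(lab^2), rep(1, nrow(centres))) -
      2 * lab %*% t(centres) +
      outer(rep(1, nrow(lab)), rowSums(centres^2))
    labels <- max.col(-dmat)
    centroids <- centres_rgb
  } else {
    km <- with_seed(seed, tryCatch(
      kmeans(lab, centers = k, nstart = 3, iter.max = 30),
      error = function(e) {
        # duplicate sampled centres (few distinct colours): seed k-means
        # with k distinct colours spread along the lightness axis
        uq <- unique(lab)
        uq <- uq[order(uq[, 1]), , drop = FALSE]
        centres <- uq[round(seq(1, nrow(uq), length.out = k)), ,
                      drop = FALSE]
        kmeans(lab, centers = centres, iter.max = 30)
      }))
    labels <- km$cluster
    # centroid colour in RGB: mean of member pixels
    centroids <- do.call(rbind, lapply(seq_len(max(labels)), function(i) {
      colMeans(px[labels == i, , drop = FALSE])
    }))
  }
  sizes <- tabulate(labels, nbins = nrow(centroids))
  hsv <- rgb_to_hsv_rows(centroids)
  brown <- hsv$h >= 15 & hsv$h <= 50 & hsv$s > 0.2 &
    hsv$v >= 0.15 & hsv$v <= 0.85
  positive <- if (any(brown)) {
    cand <- which(brown)
    cand[which.max(sizes[cand])]
  } else NA_integer_
  structure(list(
    labels = matrix(labels, d[1], d[2]),
    centroids = centroids,
    positive_cluster = positive,
    sizes = sizes,
    k = nrow(centroids)
  ), class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> k = %d, positive cluster: %s\n", x$k,
              if (is.na(x$positive_cluster)) "absent"
              else as.character(x$positive_cluster)))
  invisible(x)
}

#' Quantify the Ki67 index of an IHC patch
#'
#' The index is the proportion of pixels assigned to the DAB-brown cluster.
#' With `denominator = "all"` (the default, and the definition the simulator's
#' ground truth uses) the proportion is over every pixel of the patch; with
#' `"tissue"` near-white background cluster pixels are excluded from the
#' denominator.
#'
#' @inheritParams cluster_stain
#' @param denominator `"all"` or `"tissue"`.
#' @return fraction in [0, 1]; exactly 0 when no cluster is brown.
#' @export
#' @examples
#' pair <- render_patch_pair(0.3, seed = 2)
#' compute_ki67_index(pair$ki67_image)
compute_ki67_index <- function(ki67_image, k = 3, seed = 1,
                               denominator = c("all", "tissue")) {
  denominator <- match.arg(denominator)
  cm <- cluster_stain(ki67_image, k = k, seed = seed)
  if (is.na(cm$positive_cluster)) return(0)
  positive <- cm$sizes[cm$positive_cluster]
  total <- if (denominator == "all") sum(cm$sizes) else {
    hsv <- rgb_to_hsv_rows(cm$centroids)
    background <- hsv$v > 0.85 & hsv$s < 0.15
    sum(cm$sizes[!background])
  }
  if (total == 0) return(0)
  positive / total
}

#' Estimate a Ki67 index from an HE patch alone
#'
#' The simulator couples nuclei coverage to the Ki67 index (coverage =
#' index + `coverage_base`), mirroring the biological expectation that more
#' proliferative tissue carries more tumour cells.  This proxy measures the
#' hematoxylin-dark pixel fraction (luminance below `threshold`) and inverts
#' the calibration.  It is the annotation-side oracle used to score generated
#' HE images, where no adjacent IHC section exists; only its monotonicity in
#' the true index matters for the rank statistics built on it.
#'
#' @param he_image numeric H x W x 3 array in [0, 255].
#' @param coverage_base calibration intercept; must match the simulator's.
#' @param threshold luminance cut separating nuclei from eosin background.
#' @return estimated fraction in [0, 1].
#' @export
estimate_he_index <- function(he_image, coverage_base = 0.12,
                              threshold = 0.62) {
  assert_rgb_image(he_image, "he_image")
  dark <- mean(luminance(he_image) < threshold)
  clamp(dark - coverage_base, 0, 1)
}

#' Default thresholds for the HE patch quality filter
#'
#' Values are on the 8-bit scale where relevant.  A patch is kept when its
#' Laplacian variance, edge density, dark-blob count and tissue fraction all
#' meet their thresholds and the patch is not blank.
#'
#' @return named list of thresholds.
#' @export
default_filter_thresholds <- function() {
  list(
    laplacian_variance = 50,   # below: blurred
    edge_density = 0.02,       # below: too few gradient edges
    blob_count = 10,           # below: insufficient cellular content
    tissue_fraction = 0.3,     # below: mostly white / no tissue
    blank_sd = 10              # 8-bit intensity sd below: blank patch
  )
}

filter_metrics <- function(he_image) {
  gray <- luminance(he_image)           # [0, 1]
  gray8 <- gray * 255
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap_var <- var(as.vector(EBImage::filter2(gray8, lap)))
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(gray, sx)
  gy <- EBImage::filter2(gray, t(sx))
  edge_density <- mean(sqrt(gx^2 + gy^2) > 0.3)
  thr <- mean(gray) - sd(gray)
  dark <- EBImage::bwlabel(gray < thr)
  blob_sizes <- tabulate(dark[dark > 0])
  blob_count <- sum(blob_sizes >= 5)
  tissue_fraction <- mean(gray < 0.9)
  intensity_sd <- sd(as.vector(he_image))
  c(laplacian_variance = lap_var, edge_density = edge_density,
    blob_count = blob_count, tissue_fraction = tissue_fraction,
    intensity_sd = intensity_sd)
}

#' Quality-filter an HE patch
#'
#' Computes Laplacian variance (blur detection), Sobel edge density, dark
#' connected-component count (blob detection) and tissue fraction, compares
#' each to its threshold and reports the failure reasons.  A patch is kept
#' iff no reason fires, so filtering a kept patch again keeps it with
#' identical metrics.
#'
#' @param he_image numeric H x W x 3 array in [0, 255].
#' @param thresholds named list as produced by [default_filter_thresholds()];
#'   all keys are required.
#' @return an object of class `filter_decision`: `keep` (logical), `reasons`
#'   (character subset of blur, blank, low-edge, low-blob-count, low-tissue)
#'   and `metrics` (named numeric).
#' @export
quality_filter <- function(he_image, thresholds = default_filter_thresholds()) {
  assert_rgb_image(he_image, "he_image")
  required <- names(default_filter_thresholds())
  missing <- setdiff(required, names(thresholds))
  if (length(missing)) {
    abort(paste0("missing filter threshold(s): ",
                 paste(missing, collapse = ", ")),
          class = "ki67gan_config_error")
  }
  m <- filter_metrics(he_image)
  reasons <- character(0)
  if (m[["laplacian_variance"]] < thresholds$laplacian_variance)
    reasons <- c(reasons, "blur")
  if (m[["intensity_sd"]] < thresholds$blank_sd)
    reasons <- c(reasons, "blank")
  if (m[["edge_density"]] < thresholds$edge_density)
    reasons <- c(reasons, "low-edge")
  if (m[["blob_count"]] < thresholds$blob_count)
    reasons <- c(reasons, "low-blob-count")
  if (m[["tissue_fraction"]] < thresholds$tissue_fraction)
    reasons <- c(reasons, "low-tissue")
  structure(list(keep = length(reasons) == 0L, reasons = reasons,
                 metrics = m), class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(sprintf("<filter_decision> keep = %s%s\n", x$keep,
              if (length(x$reasons)) paste0("  [",
                paste(x$reasons, collapse = ", "), "]") else ""))
  invisible(x)
}

# fetch the two images of a manifest row, whichever storage form is used
manifest_images <- function(row) {
  if ("pair" %in% names(row)) {
    p <- row$pair[[1]]
    list(he = p$he_image, ki67 = p$ki67_image)
  } else {
    list(he = read_image(row$he_path), ki67 = read_image(row$ki67_path))
  }
}

#' Label a dataset manifest with computed Ki67 indices and filter decisions
#'
#' For every row the Ki67 index is quantified from the IHC patch via
#' [compute_ki67_index()] and the HE patch is passed through
#' [quality_filter()].  Row order is preserved; unreadable rows are marked
#' `failed` and processing continues.
#'
#' @param manifest a tibble from [render_dataset()] (list-column `pair`) or
#'   [read_manifest()] (path columns).
#' @param k colour cluster count for the quantifier.
#' @param thresholds quality-filter thresholds.
#' @param seed clustering seed.
#' @param denominator passed to [compute_ki67_index()].
#' @param verbose print kept/excluded counts per reason.
#' @return the manifest with added columns `ki67_index`, `keep`, `reasons`
#'   (comma-separated), `failed`.
#' @export
label_dataset <- function(manifest, k = 3,
                          thresholds = default_filter_thresholds(),
                          seed = 1, denominator = "all", verbose = TRUE) {
  stopifnot(is.data.frame(manifest))
  manifest <- tibble::as_tibble(manifest)
  n <- nrow(manifest)
  out <- purrr::map(seq_len(n), function(i) {
    row <- manifest[i, ]
    res <- tryCatch({
      imgs <- manifest_images(row)
      idx <- compute_ki67_index(imgs$ki67, k = k, seed = seed,
                                denominator = denominator)
      dec <- quality_filter(imgs$he, thresholds)
      tibble::tibble(ki67_index = idx, keep = dec$keep,
                     reasons = paste(dec$reasons, collapse = ","),
                     failed = FALSE)
    }, error = function(e) {
      tibble::tibble(ki67_index = NA_real_, keep = FALSE,
                     reasons = "failed", failed = TRUE)
    })
    res
  })
  labeled <- dplyr::bind_cols(manifest, dplyr::bind_rows(out))
  if (verbose && n > 0) {
    kept <- sum(labeled$keep)
    reasons <- unlist(strsplit(labeled$reasons[!labeled$keep], ","))
    reasons <- reasons[nzchar(reasons)]
    message(sprintf("label_dataset: kept %d / %d patches", kept, n))
    if (length(reasons)) {
      tab <- sort(table(reasons), decreasing = TRUE)
      message("  excluded by reason: ",
              paste(names(tab), tab, sep = "=", collapse = ", "))
    }
  }
  labeled
}
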