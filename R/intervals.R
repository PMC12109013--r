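# Ki67-interval evaluation protocol: the interval hierarchy, assignment of
# labelled images to intervals, FID/FHD cross matrices and the
# subset/complement expectation checks used to read them.

#' The Ki67 interval hierarchy
#'
#' The six evaluation intervals, ordered as they appear in the matrix
#' reports: `[0.5,1]` (upper-inclusive), `[0,0.5)`, `[0.2,0.5)`, `[0,0.2)`,
#' `[0.1,0.2)`, `[0,0.1)`; optionally preceded by the full range `[0,1]`.
#' All bounds are lower-inclusive and upper-exclusive except the top
#' interval, so every index lands in exactly one interval per hierarchy
#' level.
#'
#' @param include_full prepend the full range `[0,1]`.
#' @return tibble with columns `label`, `lower`, `upper`, `upper_inclusive`.
#' @export
ki67_intervals <- function(include_full = FALSE) {
  iv <- tibble::tibble(
    label = c("[0.5,1]", "[0,0.5)", "[0.2,0.5)", "[0,0.2)", "[0.1,0.2)",
              "[0,0.1)"),
    lower = c(0.5, 0, 0.2, 0, 0.1, 0),
    upper = c(1, 0.5, 0.5, 0.2, 0.2, 0.1),
    upper_inclusive = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  if (include_full) {
    iv <- dplyr::bind_rows(
      tibble::tibble(label = "[0,1]", lower = 0, upper = 1,
                     upper_inclusive = TRUE), iv)
  }
  iv
}

#' Relation between two Ki67 intervals
#'
#' Computed from the bounds, never asserted by hand: `identical`, `subset`
#' (one contains the other, either direction), `complementary` (disjoint
#' ranges) or `overlapping`.
#'
#' @param a,b single-row interval tibbles (rows of [ki67_intervals()]).
#' @return character scalar.
#' @export
interval_relation <- function(a, b) {
  if (a$lower == b$lower && a$upper == b$upper &&
      a$upper_inclusive == b$upper_inclusive) return("identical")
  contains <- function(x, y) { # y inside x
    x$lower <= y$lower && (y$upper < x$upper ||
      (y$upper == x$upper && (x$upper_inclusive || !y$upper_inclusive)))
  }
  if (contains(a, b) || contains(b, a)) return("subset")
  disjoint <- a$upper <= b$lower || b$upper <= a$lower
  if (disjoint) return("complementary")
  "overlapping"
}

#' All pairwise relations of the interval hierarchy
#'
#' @param intervals an interval tibble ([ki67_intervals()]).
#' @return tibble with columns `label_a`, `label_b`, `relation`.
#' @export
interval_relations <- function(intervals = ki67_intervals()) {
  grid <- tidyr::expand_grid(i = seq_len(nrow(intervals)),
                             j = seq_len(nrow(intervals)))
  grid <- grid[grid$i != grid$j, ]
  tibble::tibble(
    label_a = intervals$label[grid$i],
    label_b = intervals$label[grid$j],
    relation = purrr::map2_chr(grid$i, grid$j, function(i, j) {
      interval_relation(intervals[i, ], intervals[j, ])
    })
  )
}

#' Interval membership
#'
#' Half-open membership `lower <= x < upper`, upper-inclusive for intervals
#' flagged so (the `[0.5,1]` top interval).
#'
#' @param x numeric vector of Ki67 indices in [0, 1].
#' @param interval a single-row interval tibble.
#' @return logical vector.
#' @export
in_interval <- function(x, interval) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("Ki67 labels must lie in [0, 1]", class = "ki67gan_domain_error")
  }
  if (interval$upper_inclusive) {
    x >= interval$lower & x <= interval$upper
  } else {
    x >= interval$lower & x < interval$upper
  }
}

#' Assign labelled items to every interval of the hierarchy
#'
#' @param x numeric vector of Ki67 indices.
#' @param intervals interval tibble.
#' @return named list of integer index vectors, one per interval label.
#' @export
assign_intervals <- function(x, intervals = ki67_intervals()) {
  out <- purrr::map(seq_len(nrow(intervals)), function(i) {
    which(in_interval(x, intervals[i, ]))
  })
  names(out) <- intervals$label
  out
}

# expectation flag for a cell from the row/column interval relation
cell_flag <- function(relation) {
  switch(relation,
    identical = "diagonal",
    subset = "expect-low",
    complementary = "expect-high",
    "none")
}

#' Frechet-distance matrix between interval image sets
#'
#' Computes the full cross matrix of FID or FHD values between row sets and
#' column sets (named lists of image lists, names = interval labels), embeds
#' each set once, and attaches per-cell expectation flags derived from the
#' interval relations: `diagonal` where row and column intervals are
#' identical, `expect-low` for subset pairs, `expect-high` for complementary
#' pairs.  Cells whose sets have fewer than 2 images are reported missing
#' (`NA`), never zero.
#'
#' @param row_sets,col_sets named lists of image lists; names must be
#'   interval labels from [ki67_intervals()].
#' @param metric `"fid"` or `"fhd"` (recorded in the report).
#' @param embedder the `ki67_embedder` used for all sets.
#' @param intervals interval tibble defining labels and relations.
#' @return an object of class `ki67_metric_matrix`: `values` (matrix),
#'   `flags` (matrix), `metric`, `symmetric` (TRUE when row and column sets
#'   are the same object), `n_row`, `n_col`.
#' @export
metric_matrix <- function(row_sets, col_sets, metric = c("fhd", "fid"),
                          embedder, intervals = ki67_intervals()) {
  metric <- match.arg(metric)
  stopifnot(!is.null(names(row_sets)), !is.null(names(col_sets)))
  symmetric <- identical(row_sets, col_sets)
  stats_of <- function(sets) {
    purrr::map(sets, function(imgs) {
      if (length(imgs) < 2) return(NULL)
      fit_gaussian(embed_images(embedder, imgs))
    })
  }
  row_stats <- stats_of(row_sets)
  col_stats <- if (symmetric) row_stats else stats_of(col_sets)
  nr <- length(row_stats); nc <- length(col_stats)
  values <- matrix(NA_real_, nr, nc,
                   dimnames = list(names(row_sets), names(col_sets)))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (symmetric && j < i) {
        values[i, j] <- values[j, i]
      } else if (!is.null(row_stats[[i]]) && !is.null(col_stats[[j]])) {
        values[i, j] <- frechet(row_stats[[i]], col_stats[[j]])
      }
    }
  }
  new_metric_matrix(values, metric, symmetric, intervals,
                    n_row = purrr::map_int(row_sets, length),
                    n_col = purrr::map_int(col_sets, length))
}

new_metric_matrix <- function(values, metric, symmetric,
                              intervals = ki67_intervals(),
                              n_row = NULL, n_col = NULL) {
  rl <- rownames(values); cl <- colnames(values)
  lookup <- function(lbl) {
    row <- intervals[intervals$label == lbl, ]
    if (nrow(row) != 1) {
      abort(sprintf("unknown interval label `%s`", lbl),
            class = "ki67gan_config_error")
    }
    row
  }
  flags <- matrix("none", nrow(values), ncol(values),
                  dimnames = dimnames(values))
  for (i in seq_along(rl)) {
    for (j in seq_along(cl)) {
      flags[i, j] <- cell_flag(
        interval_relation(lookup(rl[i]), lookup(cl[j])))
    }
  }
  structure(list(values = values, flags = flags, metric = metric,
                 symmetric = symmetric, n_row = n_row, n_col = n_col),
            class = "ki67_metric_matrix")
}

#' @export
print.ki67_metric_matrix <- function(x, ...) {
  cat(sprintf("<ki67_metric_matrix> %s%s\n", toupper(x$metric),
              if (x$symmetric) " (symmetric)" else ""))
  print(round(x$values, 2))
  invisible(x)
}

#' @rdname metric_matrix
#' @param x a `ki67_metric_matrix`.
#' @param ... unused.
#' @export
tidy.ki67_metric_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(x$values), stringsAsFactors = FALSE)
  names(df) <- c("row_label", "col_label", "value")
  df$flag <- as.vector(x$flags)
  tibble::as_tibble(df)
}

#' @rdname metric_matrix
#' @param object a `ki67_metric_matrix`.
#' @export
autoplot.ki67_metric_matrix <- function(object, ...) {
  df <- tidy(object)
  df$row_label <- factor(df$row_label, levels = rev(rownames(object$values)))
  df$col_label <- factor(df$col_label, levels = colnames(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_label, y = .data$row_label,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#de2d26",
                                 na.value = "grey85") +
    ggplot2::labs(x = "column interval", y = "row interval",
                  fill = toupper(object$metric)) +
    ggplot2::theme_minimal()
}

#' Check a metric matrix against the interval expectations
#'
#' The diagonal (identical intervals) is expected to hold the smallest
#' distances and complementary intervals the largest, so a violation is
#' recorded whenever a complementary (`expect-high`) cell falls below its
#' row's or its column's diagonal value.  This mirrors the emphasised
#' "unexpected" entries of the matrix reports; subset (`expect-low`) cells
#' sitting marginally below a diagonal are a known consequence of label
#' imbalance and are not flagged.
#'
#' @param report a `ki67_metric_matrix`.
#' @return tibble of violations with columns `row_label`, `col_label`,
#'   `type`, `value`, `reference`, `reference_value`; zero rows when all
#'   expectations hold.
#' @export
check_relations <- function(report) {
  stopifnot(inherits(report, "ki67_metric_matrix"))
  v <- report$values
  f <- report$flags
  rl <- rownames(v); cl <- colnames(v)
  out <- list()
  push <- function(i, j, type, ref, ref_value) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      row_label = rl[i], col_label = cl[j], type = type,
      value = v[i, j], reference = ref, reference_value = ref_value)
  }
  for (i in seq_along(rl)) {
    for (j in seq_along(cl)) {
      if (is.na(v[i, j]) || f[i, j] != "expect-high") next
      # against the row diagonal
      dj <- which(f[i, ] == "diagonal")
      if (length(dj) && !is.na(v[i, dj]) && v[i, j] < v[i, dj]) {
        push(i, j, "below-row-diagonal", paste0("(", rl[i], ", ", cl[dj], ")"),
             v[i, dj])
      }
      # against the column diagonal
      di <- which(f[, j] == "diagonal")
      if (length(di) && !is.na(v[di, j]) && v[i, j] < v[di, j]) {
        push(i, j, "below-column-diagonal",
             paste0("(", rl[di], ", ", cl[j], ")"), v[di, j])
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(row_label = character(), col_label = character(),
                   type = character(), value = double(),
                   reference = character(), reference_value = double())
  }
}

#' Label sampler for one Ki67 interval
#'
#' Returns a function drawing conditioning labels for generation "inside"
#' an interval: the empirical distribution of the supplied (kept, real)
#' labels restricted to the interval, falling back to the uniform
#' distribution on the interval when no real label lands in it.
#'
#' @param labels numeric vector of real Ki67 labels.
#' @param interval a single-row interval tibble.
#' @return function `n -> n labels` inside the interval.
#' @export
interval_label_sampler <- function(labels, interval) {
  pool <- labels[in_interval(labels, interval)]
  lo <- interval$lower
  hi <- interval$upper
  function(n) {
    if (length(pool)) {
      sample(pool, n, replace = TRUE)
    } else {
      lo + runif(n) * (hi - lo)
    }
  }
}

#' Evaluate a conditional generator over the Ki67 interval hierarchy
#'
#' Assigns the labelled real patches to intervals, generates
#' `n_per_interval` images for each interval (conditioning labels resampled
#' from the interval's empirical real-label distribution), computes the
#' full FID/FHD cross matrix with expectation flags and runs the violation
#' detector.
#'
#' @param labeled a [label_dataset()] manifest (kept rows are used).
#' @param checkpoint a trained `ki67_checkpoint`.
#' @param metric `"fhd"` or `"fid"`.
#' @param embedder the embedder for the chosen metric.
#' @param n_per_interval generated images per interval.
#' @param seed integer seed for generation.
#' @param intervals interval tibble.
#' @return list with `report` (a `ki67_metric_matrix`, rows = dataset
#'   intervals, columns = generator intervals) and `violations` (tibble).
#' @export
evaluate_intervals <- function(labeled, checkpoint, metric = c("fhd", "fid"),
                               embedder, n_per_interval = 200, seed = 1,
                               intervals = ki67_intervals()) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(labeled), inherits(checkpoint, "ki67_checkpoint"))
  if ("keep" %in% names(labeled)) labeled <- labeled[labeled$keep, ]
  labels <- if ("ki67_index" %in% names(labeled)) labeled$ki67_index
            else labeled$true_index
  he_imgs <- purrr::map(seq_len(nrow(labeled)), function(i) {
    manifest_images(labeled[i, ])$he
  })
  members <- assign_intervals(labels, intervals)
  real_sets <- purrr::map(members, ~he_imgs[.x])
  gen_sets <- purrr::map(seq_len(nrow(intervals)), function(i) {
    sampler <- interval_label_sampler(labels, intervals[i, ])
    generate_conditional(checkpoint, n = n_per_interval, labels = sampler,
                         seed = seed + i)$images
  })
  names(gen_sets) <- intervals$label
  report <- metric_matrix(real_sets, gen_sets, metric = metric,
                          embedder = embedder, intervals = intervals)
  list(report = report, violations = check_relations(report))
}

#' Transcribed interval-evaluation reference tables
#'
#' Loads the published FID/FHD interval matrices shipped as CSV fixtures:
#' `"fid_dataset_generator"`, `"fhd_dataset_generator"`,
#' `"fhd_generator_generator"`, `"fhd_dataset_dataset"` and the per-interval
#' `"ppl"` row.  The matrices are returned as `ki67_metric_matrix` objects
#' (rows are dataset or generator intervals as published).
#'
#' @param name which table to load.
#' @return a `ki67_metric_matrix`, or a tibble for `"ppl"`.
#' @export
reference_table <- function(name = c("fid_dataset_generator",
                                     "fhd_dataset_generator",
                                     "fhd_generator_generator",
                                     "fhd_dataset_dataset", "ppl")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "ki67gan",
                      mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (name == "ppl") return(df)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  colnames(m) <- names(df)[-1]
  metric <- if (grepl("^fid", name)) "fid" else "fhd"
  new_metric_matrix(m, metric, symmetric = isTRUE(all.equal(m, t(m))),
                    intervals = ki67_intervals())
}
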