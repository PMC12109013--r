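# Ordinal analysis of the pathologists' sequence verdicts: the 5-level
# scale, inter-rater distances, consistency fractions and category
# summaries.

#' The 5-level realism verdict scale
#'
#' Ordered from unreal to real; the ordinal encoding is the position on this
#' scale, 0 to 4.
#'
#' @return character vector of the five verdicts in scale order.
#' @export
verdict_levels <- function() {
  c("certainly unreal", "rather unreal", "partially real and unreal",
    "rather real", "certainly real")
}

#' Encode a verdict string as its ordinal level
#'
#' @param verdict character vector of verdicts.
#' @return integer vector, 0 (certainly unreal) to 4 (certainly real).
#' @export
#' @examples
#' encode_verdict("partially real and unreal")
encode_verdict <- function(verdict) {
  idx <- match(verdict, verdict_levels())
  if (any(is.na(idx))) {
    bad <- unique(verdict[is.na(idx)])
    abort(paste0("unknown verdict(s): ", paste(bad, collapse = ", "),
                 "; valid verdicts are: ",
                 paste(verdict_levels(), collapse = ", ")),
          class = "ki67gan_config_error")
  }
  idx - 1L
}

#' Load pathologist rating records
#'
#' Reads the rating fixture CSV (columns `group`, `sequence`, `rater`,
#' `verdict`).  The default is the transcription of the two published
#' evaluation groups (20 sequences x 2 raters each) shipped with the
#' package.
#'
#' @param path CSV path; default the shipped transcription.
#' @return tibble of rating records with an added `level` column (0-4).
#' @export
read_ratings <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pathologist_ratings.csv",
                                package = "ki67gan", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          group = readr::col_integer(),
                          sequence = readr::col_integer(),
                          rater = readr::col_integer(),
                          verdict = readr::col_character()))
  df$level <- encode_verdict(df$verdict)
  df
}

complete_group <- function(records, group = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(group)) records <- records[records$group == group, ]
  if (!"level" %in% names(records)) {
    records$level <- encode_verdict(records$verdict)
  }
  wide <- tidyr::pivot_wider(
    records[, c("sequence", "rater", "level")],
    names_from = "rater", values_from = "level", names_prefix = "r")
  if (!all(c("r1", "r2") %in% names(wide)) ||
      any(is.na(wide$r1)) || any(is.na(wide$r2))) {
    missing <- if (all(c("r1", "r2") %in% names(wide))) {
      wide$sequence[is.na(wide$r1) | is.na(wide$r2)]
    } else unique(records$sequence)
    abort(paste0("missing rater verdict(s) for sequence(s): ",
                 paste(missing, collapse = ", ")),
          class = "ki67gan_domain_error")
  }
  dplyr::arrange(wide, .data$sequence)
}

#' Inter-rater consistency of one rating group
#'
#' Computes the per-sequence ordinal distance `|r1 - r2|`, its histogram
#' over 0..4, the consistent fraction (distance at most `threshold`) and the
#' maximum observed distance.
#'
#' @param records rating records ([read_ratings()] format).
#' @param group group id to analyse (1 or 2); `NULL` if `records` already
#'   holds a single group.
#' @param threshold largest distance still considered consistent.
#' @return an object of class `ki67_consistency`: `per_sequence` (tibble),
#'   `histogram` (tibble distance/count), `consistent_fraction`,
#'   `max_distance`, `threshold`.
#' @export
#' @examples
#' rating_consistency(read_ratings(), group = 1)$consistent_fraction
rating_consistency <- function(records, group = NULL, threshold = 1) {
  wide <- complete_group(records, group)
  wide$distance <- abs(wide$r1 - wide$r2)
  hist <- tibble::tibble(
    distance = 0:4,
    count = purrr::map_int(0:4, ~sum(wide$distance == .x)))
  structure(list(
    per_sequence = wide,
    histogram = hist,
    consistent_fraction = mean(wide$distance <= threshold),
    max_distance = max(wide$distance),
    threshold = threshold,
    n_sequences = nrow(wide)
  ), class = "ki67_consistency")
}

#' @export
print.ki67_consistency <- function(x, ...) {
  cat(sprintf(
    "<ki67_consistency> %d sequences: %.0f%% consistent (distance <= %d), max distance %d\n",
    x$n_sequences, 100 * x$consistent_fraction, x$threshold,
    x$max_distance))
  invisible(x)
}

#' @rdname rating_consistency
#' @param x a `ki67_consistency`.
#' @param ... unused.
#' @export
tidy.ki67_consistency <- function(x, ...) x$per_sequence

#' @rdname rating_consistency
#' @export
glance.ki67_consistency <- function(x, ...) {
  tibble::tibble(n_sequences = x$n_sequences,
                 consistent_fraction = x$consistent_fraction,
                 inconsistent_fraction = 1 - x$consistent_fraction,
                 max_distance = x$max_distance,
                 threshold = x$threshold)
}

#' Summarise verdict counts for one rating group
#'
#' Per-rater and combined counts and fractions for each of the five
#' verdicts; fractions are over the sequences per rater and over all
#' verdicts for the combined row.
#'
#' @inheritParams rating_consistency
#' @return tibble with columns `rater` (`"1"`, `"2"`, `"combined"`),
#'   `verdict`, `level`, `count`, `fraction`.
#' @export
summarize_ratings <- function(records, group = NULL) {
  wide <- complete_group(records, group)
  lv <- verdict_levels()
  count_of <- function(values) {
    purrr::map_int(0:4, ~sum(values == .x))
  }
  per <- dplyr::bind_rows(
    tibble::tibble(rater = "1", verdict = lv, level = 0:4,
                   count = count_of(wide$r1)),
    tibble::tibble(rater = "2", verdict = lv, level = 0:4,
                   count = count_of(wide$r2)))
  combined <- per |>
    dplyr::group_by(.data$verdict, .data$level) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(rater = "combined") |>
    dplyr::arrange(.data$level)
  out <- dplyr::bind_rows(per, combined)
  n_seq <- nrow(wide)
  out$fraction <- out$count / ifelse(out$rater == "combined", 2 * n_seq,
                                     n_seq)
  out[, c("rater", "verdict", "level", "count", "fraction")]
}

#' Collapse verdict counts into unreal / partially / real categories
#'
#' `real` is rather + certainly real, `unreal` rather + certainly unreal,
#' matching the usual reading of 5-level realism scales.
#'
#' @inheritParams rating_consistency
#' @return tibble with columns `rater`, `category`, `count`, `fraction`.
#' @export
rating_categories <- function(records, group = NULL) {
  s <- summarize_ratings(records, group)
  s$category <- dplyr::case_when(
    s$level <= 1 ~ "unreal",
    s$level == 2 ~ "partially",
    TRUE ~ "real")
  s |>
    dplyr::group_by(.data$rater, .data$category) |>
    dplyr::summarise(count = sum(.data$count),
                     fraction = sum(.data$fraction), .groups = "drop") |>
    dplyr::mutate(category = factor(.data$category,
                                    c("unreal", "partially", "real"))) |>
    dplyr::arrange(.data$rater, .data$category)
}
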