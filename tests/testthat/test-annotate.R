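flat_patch <- function(colours, regions, size = 30) {
  # paint `regions` (list of row index sets) with colours on a white patch
  img <- array(255, c(size, size, 3))
  for (i in seq_along(regions)) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[regions[[i]], ] <- colours[[i]][ch]
      img[, , ch] <- plane
    }
  }
  img
}

test_that("clustering separates flat colour regions exactly", {
  img <- flat_patch(list(c(140, 90, 50), c(80, 100, 180)),
                    list(1:10, 11:20), size = 30)
  cm <- cluster_stain(img, k = 3, seed = 1)
  expect_s3_class(cm, "cluster_map")
  # each region maps to a single cluster
  expect_equal(length(unique(as.vector(cm$labels[1:10, ]))), 1)
  expect_equal(length(unique(as.vector(cm$labels[11:20, ]))), 1)
  expect_equal(length(unique(as.vector(cm$labels[21:30, ]))), 1)
  # the brown region is the positive cluster
  expect_equal(unique(as.vector(cm$labels[1:10, ])), cm$positive_cluster)
})

test_that("positive cluster is absent on brown-free patches", {
  white <- array(255, c(20, 20, 3))
  cm <- suppressWarnings(cluster_stain(white, k = 3))
  expect_true(is.na(cm$positive_cluster))
  expect_identical(compute_ki67_index(white), 0)
})

test_that("painted brown fractions are quantified to within a pixel count", {
  img <- flat_patch(list(c(140, 90, 50), c(80, 100, 180)),
                    list(1:3, 4:30), size = 30)   # exactly 10% brown
  expect_lt(abs(compute_ki67_index(img) - 0.10), 0.01)
  expect_error(compute_ki67_index(matrix(0, 5, 5)),
               class = "ki67gan_format_error")
})

test_that("index recovery closes the loop against the simulator", {
  pair <- render_patch_pair(0.2, seed = 31)
  cm <- cluster_stain(pair$ki67_image, seed = 1)
  pred <- cm$labels == cm$positive_cluster
  jaccard <- sum(pred & pair$positive_mask) / sum(pred | pair$positive_mask)
  expect_gt(jaccard, 0.9)

  pair3 <- render_patch_pair(0.3, seed = 32)
  expect_lt(abs(compute_ki67_index(pair3$ki67_image) - 0.3), 0.05)
})

test_that("the index is monotone in the painted brown area", {
  sizes <- c(2, 6, 12, 20)
  idx <- vapply(sizes, function(s) {
    compute_ki67_index(flat_patch(list(c(140, 90, 50), c(80, 100, 180)),
                                  list(seq_len(s), 21:30), size = 30))
  }, numeric(1))
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= 0 & idx <= 1))
})

test_that("quality filter rejects each degradation and keeps clean patches", {
  pair <- render_patch_pair(0.1, seed = 41)
  clean <- quality_filter(pair$he_image)
  expect_true(clean$keep)
  expect_length(clean$reasons, 0)

  blank <- quality_filter(degrade(pair, "blank", seed = 1)$he_image)
  expect_false(blank$keep)
  expect_true(all(c("blank", "low-tissue") %in% blank$reasons))

  blur <- quality_filter(degrade(pair, "blur", sigma = 5, seed = 1)$he_image)
  expect_false(blur$keep)
  expect_true("blur" %in% blur$reasons)

  # idempotence: a kept patch filters to identical metrics again
  again <- quality_filter(pair$he_image)
  expect_identical(again$metrics, clean$metrics)
  expect_true(again$keep)

  expect_error(quality_filter(pair$he_image, thresholds = list(blob_count = 1)),
               class = "ki67gan_config_error")
})

test_that("label_dataset labels, filters and survives bad rows", {
  ds <- render_dataset(30, seed = 51, degrade_fraction = 0.2)
  # degrade_fraction 0.2 over 30 rows: blur, blank, tear, sparse, blur, blank
  lab <- label_dataset(ds, verbose = FALSE)
  expect_equal(nrow(lab), 30)
  expect_identical(lab$patch_id, ds$patch_id)
  blank_rows <- which(ds$degraded == "blank")
  expect_true(all(!lab$keep[blank_rows]))
  expect_true(all(grepl("blank", lab$reasons[blank_rows])))
  kept <- lab[lab$keep, ]
  expect_lt(mean(abs(kept$ki67_index - kept$true_index)), 0.05)

  empty <- label_dataset(ds[0, ], verbose = FALSE)
  expect_equal(nrow(empty), 0)

  broken <- tibble::tibble(patch_id = "x", he_path = "missing.png",
                           ki67_path = "missing.png", true_index = 0.1)
  labb <- label_dataset(broken, verbose = FALSE)
  expect_true(labb$failed[1])
  expect_false(labb$keep[1])
})
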