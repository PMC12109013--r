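test_that("the interval hierarchy and its relations derive from bounds", {
  iv <- ki67_intervals()
  expect_equal(nrow(iv), 6)
  expect_setequal(iv$label, c("[0.5,1]", "[0,0.5)", "[0.2,0.5)", "[0,0.2)",
                              "[0.1,0.2)", "[0,0.1)"))
  full <- ki67_intervals(include_full = TRUE)
  expect_equal(full$label[1], "[0,1]")

  at <- function(lbl) iv[iv$label == lbl, ]
  expect_equal(interval_relation(at("[0,0.1)"), at("[0,0.2)")), "subset")
  expect_equal(interval_relation(at("[0.1,0.2)"), at("[0,0.1)")),
               "complementary")
  expect_equal(interval_relation(at("[0,0.5)"), at("[0.5,1]")),
               "complementary")
  # complementary halves cover the full range
  expect_equal(at("[0,0.5)")$lower, 0)
  expect_equal(at("[0.5,1]")$upper, 1)
  expect_equal(at("[0,0.5)")$upper, at("[0.5,1]")$lower)

  rel <- interval_relations(iv)
  expect_equal(nrow(rel), 30)
  # every top-interval pair is complementary
  expect_true(all(rel$relation[rel$label_a == "[0.5,1]"] == "complementary"))
})

test_that("assignment uses half-open bounds and conserves counts", {
  iv <- ki67_intervals()
  at <- function(lbl) iv[iv$label == lbl, ]
  expect_true(in_interval(0.1, at("[0.1,0.2)")))
  expect_false(in_interval(0.1, at("[0,0.1)")))
  expect_true(in_interval(1, at("[0.5,1]")))
  expect_error(in_interval(1.5, at("[0.5,1]")),
               class = "ki67gan_domain_error")

  x <- sample_ki67_label(label_distribution("paper-imbalanced"), 5000,
                         seed = 12)
  m <- assign_intervals(x, iv)
  expect_equal(length(m[["[0,0.1)"]]) + length(m[["[0.1,0.2)"]]),
               length(m[["[0,0.2)"]]))
  expect_equal(length(m[["[0,0.2)"]]) + length(m[["[0.2,0.5)"]]),
               length(m[["[0,0.5)"]]))
  expect_equal(length(m[["[0,0.5)"]]) + length(m[["[0.5,1]"]]), length(x))
})

test_that("metric matrices carry expectation flags and report missing cells", {
  set.seed(13)
  emb <- visual_embedder(d = 8, seed = 3)
  mk <- function(shift, n) lapply(seq_len(n), function(i) {
    ki67gan:::clamp(array(120 + shift + rnorm(64 * 64 * 3, 0, 12),
                          c(64, 64, 3)), 0, 255)
  })
  sets <- list("[0,0.1)" = mk(0, 8), "[0.1,0.2)" = mk(25, 8),
               "[0.5,1]" = mk(80, 1))   # too small: must be NA
  mm <- metric_matrix(sets, sets, metric = "fid", embedder = emb)
  expect_true(mm$symmetric)
  expect_true(all(is.na(mm$values["[0.5,1]", ])))
  sub <- mm$values[1:2, 1:2]
  expect_equal(sub, t(sub), tolerance = 1e-9)
  expect_equal(unname(diag(mm$flags[1:2, 1:2])), rep("diagonal", 2))
  expect_equal(mm$flags["[0,0.1)", "[0.1,0.2)"], "expect-high")

  td <- tidy(mm)
  expect_equal(nrow(td), 9)
})

test_that("a dominant diagonal with ordered flags yields no violations", {
  iv <- ki67_intervals()
  v <- matrix(50, 6, 6, dimnames = list(iv$label, iv$label))
  diag(v) <- 1
  # subset cells mildly low, complementary cells high
  mm <- ki67gan:::new_metric_matrix(v, "fhd", symmetric = TRUE)
  mm$values[mm$flags == "expect-low"] <- 10
  expect_equal(nrow(check_relations(mm)), 0)
})

test_that("the violation detector reproduces the published anomalies", {
  t1 <- reference_table("fid_dataset_generator")
  v1 <- check_relations(t1)
  # row <0.2,0.5): shorter distance to the complementary intervals
  row_viol <- v1[v1$type == "below-row-diagonal", ]
  expect_setequal(paste(row_viol$row_label, row_viol$col_label),
                  c("[0.2,0.5) [0,0.2)", "[0.2,0.5) [0.1,0.2)",
                    "[0.2,0.5) [0,0.1)"))
  # generated <0.2,0.5) closer to dataset <0.1,0.2) than its diagonal
  col_viol <- v1[v1$type == "below-column-diagonal", ]
  expect_equal(paste(col_viol$row_label, col_viol$col_label),
               "[0.1,0.2) [0.2,0.5)")

  t2 <- reference_table("fhd_dataset_generator")
  v2 <- check_relations(t2)
  # no diagonal violation in the dataset row <0.2,0.5)
  expect_false(any(v2$type == "below-row-diagonal" &
                     v2$row_label == "[0.2,0.5)"))
  expect_equal(paste(v2$row_label[v2$type == "below-column-diagonal"],
                     v2$col_label[v2$type == "below-column-diagonal"]),
               "[0.1,0.2) [0.2,0.5)")
})

test_that("interval label samplers stay inside their interval", {
  iv <- ki67_intervals()
  labels <- sample_ki67_label(label_distribution("paper-imbalanced"), 400,
                              seed = 14)
  for (i in seq_len(nrow(iv))) {
    s <- interval_label_sampler(labels, iv[i, ])
    draws <- ki67gan:::with_seed(15, s(50))
    expect_true(all(in_interval(draws, iv[i, ])))
  }
  # empty pool falls back to uniform on the interval
  s_empty <- interval_label_sampler(numeric(0), iv[iv$label == "[0.5,1]", ])
  draws <- ki67gan:::with_seed(16, s_empty(50))
  expect_true(all(draws >= 0.5 & draws <= 1))
})

test_that("evaluate_intervals ties assignment, generation and checking together", {
  ds <- render_dataset(60, size = 32, seed = 17)
  ck <- init_generator(generator_spec(z_dim = 16, w_dim = 16,
                                      img_size = 32,
                                      channels = c(12, 10, 8, 6)), seed = 1)
  res <- evaluate_intervals(ds, ck, metric = "fid",
                            embedder = visual_embedder(d = 8, seed = 4),
                            n_per_interval = 4, seed = 2)
  expect_s3_class(res$report, "ki67_metric_matrix")
  expect_identical(dim(res$report$values), c(6L, 6L))
  expect_true(all(res$report$n_col == 4))
  expect_s3_class(res$violations, "tbl_df")
})

test_that("reference tables load with published diagonals", {
  t4 <- reference_table("fhd_dataset_dataset")
  expect_true(t4$symmetric)
  expect_equal(unname(diag(t4$values)), rep(0, 6))
  t3 <- reference_table("fhd_generator_generator")
  expect_true(all(diag(t3$values) < 0.5))
  p5 <- reference_table("ppl")
  expect_equal(p5$ppl[p5$interval == "[0,1]"], 1526.11)
})
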