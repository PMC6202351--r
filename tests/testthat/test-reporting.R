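test_that("the cell table carries labels, features, metrics and NaN", {
  ft <- data.frame(label = 1:2, area = c(30, 45),
                   centroid_x = c(4, 9), centroid_y = c(5, 6))
  class(ft) <- c("feature_table", "data.frame")
  tab <- build_cell_table(ft, list(pcc = c(0.3, 0.9)),
                          image_names = "imgA")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$label, c("imgA:1", "imgA:2"))
  expect_equal(tab$pcc, c(0.3, 0.9))
  # failed metric -> NaN in the table
  tab2 <- build_cell_table(ft, list(icq = c(0.1, NaN)), image_names = "x")
  expect_true(is.nan(tab2$icq[2L]))
  # empty cell set -> header-only table
  ft0 <- ft[0, ]
  class(ft0) <- c("feature_table", "data.frame")
  tab0 <- build_cell_table(ft0, list(), image_names = "x")
  expect_equal(nrow(tab0), 0L)
  # retained subset restricts rows
  tab3 <- build_cell_table(ft, list(pcc = c(0.3, 0.9)), image_names = "a",
                           retained = 2L)
  expect_equal(tab3$label, "a:2")
  expect_equal(tab3$pcc, 0.9)
})

test_that("summaries use finite values with sample stddev", {
  s <- summarize_metric(c(0.2, 0.4, 0.6))
  expect_equal(s$count, 3L)
  expect_equal(s$mean, 0.4)
  expect_equal(s$median, 0.4)
  expect_equal(s$stddev, sd(c(0.2, 0.4, 0.6)))
  s1 <- summarize_metric(0.5)
  expect_true(is.nan(s1$stddev))
  s2 <- summarize_metric(c(0.1, NaN, 0.3))
  expect_equal(s2$count, 2L)
  expect_error(summarize_metric(c(NaN, NaN)), "no finite")
  tab <- data.frame(v = c(0.1, 0.2))
  expect_equal(summarize_metric(tab, "v")$count, 2L)
  expect_error(summarize_metric(tab, "w"), "not found")
})

test_that("histograms bin right-closed, conserve counts, report the mode", {
  hb <- metric_histogram(c(0, 0.5, 1), 2L)
  expect_equal(hb$counts, c(2L, 1L))
  expect_equal(hb$bin_width, 0.5)
  expect_equal(hb$mode, 0.25)
  withr::with_seed(15, v <- runif(100))
  h100 <- metric_histogram(v, 10L)
  expect_equal(sum(h100$counts), 100L)
  expect_equal(h100$count, 100L)
  expect_equal(h100$bin_width, (max(v) - min(v)) / 10)
  # constant input: single occupied zero-width bin
  hc <- metric_histogram(rep(0.7, 5), 4L)
  expect_equal(hc$counts[1L], 5L)
  expect_equal(hc$bin_width, 0)
  expect_equal(hc$mode, 0.7)
  expect_error(metric_histogram(c(NaN, NA), 5L), "no finite")
})

test_that("masks and ROI sets round-trip to identical pixel sets", {
  ds <- make_synth_dataset(withr::local_tempdir(), n_cells = 4L, seed = 21L)
  out <- withr::local_tempdir()
  files <- export_masks_and_rois(ds$lm, out, basenames = "f1")
  mask <- read_tiff(file.path(out, "f1_mask.tif"))$images[[1L]]
  expect_setequal(unique(as.numeric(mask)), c(0, 255))
  expect_equal(mask > 0, ds$lm$labels > 0)
  rs <- load_roi_set(file.path(out, "f1_RoiSet.zip"), dim(ds$lm$labels))
  expect_length(rs$outlines, ds$lm$n)
  lm2 <- rois_to_labelmap(rs, dim(ds$lm$labels))
  expect_identical(lm2$labels, ds$lm$labels)
  # empty label map -> zero mask + empty zip with warning
  empty <- label_map(matrix(0L, 8, 8))
  expect_warning(
    expect_warning(export_masks_and_rois(empty, out, basenames = "e"),
                   "empty"),
    "empty")
  expect_true(all(read_tiff(file.path(out, "e_mask.tif"))$images[[1L]] == 0))
})

test_that("analyze runs end-to-end and is byte-deterministic", {
  ds <- make_synth_dataset(withr::local_tempdir(), n_cells = 5L, seed = 33L)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  conf <- list(cell_images = file.path(ds$dir, "cellid.tif"),
               reporter1_images = file.path(ds$dir, "reporter1.tif"),
               reporter2_images = file.path(ds$dir, "reporter2.tif"),
               threshold_method = "Otsu", watershed = TRUE,
               filters = "Area=50,5000",
               matrix_metric = "TOS", matrix_stat = "median",
               step_ft = 0.5, heatmap_scope = "cell", out_dir = out1)
  res <- run_analysis(conf)
  expect_equal(nrow(res$cell_table), ds$lm$n)
  expect_true(all(c("cells.csv", "summary.txt", "matrix.csv",
                    "analysis.log") %in% basename(res$files)))
  conf$out_dir <- out2
  run_analysis(conf)
  expect_identical(readLines(file.path(out1, "cells.csv")),
                   readLines(file.path(out2, "cells.csv")))
  expect_identical(readLines(file.path(out1, "matrix.csv")),
                   readLines(file.path(out2, "matrix.csv")))
  # NaN serialization is literal "NaN" in the CSV
  tosv <- res$cell_table$tos
  expect_true(all(is.finite(tosv)))
  # the log records each decision stage
  expect_true(any(grepl("threshold", res$log)))
})

test_that("re-analysis from exported ROIs reproduces the cell table", {
  ds <- make_synth_dataset(withr::local_tempdir(), n_cells = 5L, seed = 44L)
  out <- withr::local_tempdir()
  conf <- list(cell_images = file.path(ds$dir, "cellid.tif"),
               reporter1_images = file.path(ds$dir, "reporter1.tif"),
               reporter2_images = file.path(ds$dir, "reporter2.tif"),
               threshold_method = "Otsu", out_dir = out)
  res <- run_analysis(conf)
  conf2 <- conf
  conf2$out_dir <- NULL
  conf2$roi_set <- file.path(out, "image1_RoiSet.zip")
  res2 <- run_analysis(conf2)
  expect_equal(nrow(res2$cell_table), nrow(res$cell_table))
  for (col in c("area", "pcc", "srcc", "icq", "tos", "m1", "m2")) {
    expect_equal(res2$cell_table[[col]], res$cell_table[[col]])
  }
})

test_that("three reporters restrict metrics and build 3-axis matrices", {
  ds <- make_synth_dataset(withr::local_tempdir(), n_cells = 4L,
                           seed = 55L, channels = 3L)
  conf <- list(cell_stack = ds$painted$cell_id,
               reporter_stacks = ds$painted$stacks,
               threshold_method = "Otsu",
               metrics = c("pcc", "icq", "tos", "manders"),
               matrix_metric = "TOS", step_ft = 0.5)
  res <- run_analysis(conf)
  expect_false("pcc" %in% names(res$cell_table))
  expect_true(all(c("icq", "tos", "m1", "m2", "m3") %in%
                    names(res$cell_table)))
  expect_length(dim(res$matrix$values), 3L)
  expect_true(any(grepl("unavailable", res$log)))
})

test_that("NaN is written literally and config files parse", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(data.frame(label = c("a:1", "a:2"), icq = c(1, NaN)), p)
  expect_true(any(grepl("NaN", readLines(p), fixed = TRUE)))
  cf <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("threshold_method = Otsu", "# comment",
               "filters = Area=10,500", "watershed = true"), cf)
  cfg <- read_config(cf)
  expect_equal(cfg$threshold_method, "Otsu")
  expect_equal(cfg$watershed, "true")
  expect_equal(cfg$filters, c("Area=10", "500"))
})

test_that("custom metric hooks flow into the per-cell table", {
  ds <- make_synth_dataset(withr::local_tempdir(), n_cells = 3L, seed = 66L)
  conf <- list(cell_stack = ds$painted$cell_id,
               reporter_stacks = ds$painted$stacks,
               threshold_method = "Otsu",
               custom_metric = function(cell, fts) max(cell[[1L]]))
  res <- run_analysis(conf)
  expect_true("custom" %in% names(res$cell_table))
  expect_true(all(res$cell_table$custom > 0))
})
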