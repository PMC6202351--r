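test_that("the F_T grid follows the step rule with a remainder last step", {
  expect_equal(ft_grid(0.3), c(0.3, 0.6, 0.9, 1))
  expect_equal(ft_grid(0.5), c(0.5, 1))
  expect_equal(ft_grid(1), 1)
  expect_equal(ft_grid(0.1), seq(0.1, 1, by = 0.1))
  for (step in c(0.07, 0.15, 0.2, 0.33, 0.49)) {
    g <- ft_grid(step)
    expect_length(g, ceiling(1 / step))
    expect_equal(g[length(g)], 1)
    expect_true(all(diff(g) > 0))
  }
  expect_error(ft_grid(0), "fraction")
  expect_error(ft_grid(1.5), "fraction")
})

test_that("TOS matrices black out the fT=1 row and column", {
  withr::with_seed(23, cl <- cell_pixels(runif(64), runif(64)))
  mm <- metric_matrix(cl, "TOS", 0.5)
  expect_equal(dim(mm$values), c(2L, 2L))
  expect_equal(sum(is.finite(mm$values)), 1L)
  expect_true(all(is.nan(mm$values[2L, ])))
  expect_true(all(is.nan(mm$values[, 2L])))
  # identical channels: every finite entry is +1
  ident <- cell_pixels(cl[[1L]], cl[[1L]])
  mi <- metric_matrix(ident, "TOS", 0.25)
  fin <- mi$values[is.finite(mi$values)]
  expect_true(all(fin == 1))
  expect_equal(length(fin), 9L)        # 3x3 sub-grid below fT=1
})

test_that("matrix values sit at their metric's evaluation on the grid", {
  withr::with_seed(29, cl <- cell_pixels(runif(50), runif(50)))
  g <- ft_grid(0.5)
  for (metric in c("PCC", "SRCC", "ICQ", "M1", "M2")) {
    mm <- metric_matrix(cl, metric, 0.5)
    fn <- switch(metric,
                 PCC = function(s) pcc(cl, s),
                 SRCC = function(s) srcc(cl, s),
                 ICQ = function(s) icq(cl, s),
                 M1 = function(s) manders(cl, s)[["M1"]],
                 M2 = function(s) manders(cl, s)[["M2"]])
    for (i in seq_along(g)) for (j in seq_along(g)) {
      want <- fn(c(g[i], g[j]))
      if (is.nan(want)) expect_true(is.nan(mm$values[i, j]))
      else expect_equal(mm$values[i, j], want)
    }
  }
  expect_error(metric_matrix(cl, "XYZ", 0.5), "unknown metric")
  expect_error(metric_matrix(cl, "M3", 0.5), "three channels")
})

test_that("matrix symmetry under data exchange, and 3-channel shape", {
  withr::with_seed(37, {
    a <- runif(40); b <- runif(40); c3 <- runif(40)
  })
  m_ab <- metric_matrix(cell_pixels(a, b), "TOS", 0.25)
  m_ba <- metric_matrix(cell_pixels(b, a), "TOS", 0.25)
  expect_equal(m_ab$values, t(m_ba$values))
  m3 <- metric_matrix(cell_pixels(a, b, c3), "TOS", 0.5)
  expect_equal(dim(m3$values), c(2L, 2L, 2L))
  expect_equal(sum(is.finite(m3$values)), 1L)
})

test_that("custom metric callbacks participate like built-ins", {
  withr::with_seed(43, cl <- cell_pixels(runif(30), runif(30)))
  overlap_count <- function(cell, fts) {
    sels <- lapply(seq_along(cell), function(i)
      select_top_fraction(cell[[i]], fts[i]))
    length(Reduce(intersect, sels))
  }
  mm <- metric_matrix(cl, overlap_count, 0.5)
  expect_equal(mm$metric, "custom")
  expect_equal(mm$values[2L, 2L], 30)    # fT=1 everywhere overlaps fully
})

test_that("aggregation excludes NaN per element; mode bins at 0.01", {
  base <- metric_matrix(cell_pixels(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                        "TOS", 0.5)
  mk <- function(v) { m <- base; m$values[1L, 1L] <- v; m }
  med <- aggregate_matrices(list(mk(0.2), mk(0.4), mk(0.6)), "median")
  expect_equal(med$values[1L, 1L], 0.4)
  avg <- aggregate_matrices(list(mk(0.5), mk(NaN), mk(0.7)), "mean")
  expect_equal(avg$values[1L, 1L], 0.6)
  allnan <- aggregate_matrices(list(mk(NaN), mk(NaN)), "mean")
  expect_true(is.nan(allnan$values[1L, 1L]))
  # mode: most populated 0.01 bin wins, ties to the lower bin
  mode1 <- aggregate_matrices(lapply(c(0.201, 0.203, 0.7), mk), "mode")
  expect_equal(mode1$values[1L, 1L], 0.205)
  tie <- aggregate_matrices(lapply(c(0.101, 0.301), mk), "mode")
  expect_equal(tie$values[1L, 1L], 0.105)
  other <- metric_matrix(cell_pixels(1:4, 4:1), "TOS", 0.25)
  expect_error(aggregate_matrices(list(base, other), "mean"), "share")
})

test_that("heat maps honor the 0-255 contract in all scopes", {
  lab <- matrix(0L, 6, 10)
  lab[2:3, 2:3] <- 1L
  lab[5, 6:9] <- 2L
  img <- matrix(0, 6, 10)
  img[lab == 1L] <- c(0, 5, 5, 10)
  img[lab == 2L] <- c(0, 250, 500, 1000)
  st <- channel_stack(img, "reporter1")
  lm <- label_map(lab)
  hm_cell <- heatmap_rescale(st, lm, "cell")[[1L]]
  for (k in 1:2) {
    expect_equal(min(hm_cell[lab == k]), 0L)
    expect_equal(max(hm_cell[lab == k]), 255L)
  }
  expect_true(all(hm_cell[lab == 0L] == 0L))
  # image scope compresses the dim cell
  hm_img <- heatmap_rescale(st, lm, "image")[[1L]]
  expect_equal(max(hm_img[lab == 1L]), as.integer(round(10 * 255 / 1000)))
  expect_equal(max(hm_img), 255L)
  # idempotence: rescaling an already cell-scaled raster is the identity
  st2 <- channel_stack(hm_cell * 1, "reporter1")
  expect_identical(heatmap_rescale(st2, lm, "cell")[[1L]], hm_cell)
  # constant cell -> all zero
  lab3 <- matrix(0L, 4, 4); lab3[2:3, 2:3] <- 1L
  img3 <- matrix(9, 4, 4)
  hm3 <- heatmap_rescale(channel_stack(img3, "reporter1"),
                         label_map(lab3), "cell")[[1L]]
  expect_true(all(hm3 == 0L))
  # stack scope: one range across images
  st4 <- channel_stack(list(img, img / 10), "reporter1")
  hm4 <- heatmap_rescale(st4, list(lm, lm), "stack")
  expect_equal(max(hm4[[1L]]), 255L)
  expect_lt(max(hm4[[2L]]), 30L)
})

test_that("scatterplot data has one row per pixel and channel columns", {
  cl <- cell_pixels(1:9, 9:1, names = c("cy3", "dapi"))
  sd2 <- scatterplot_data(cl)
  expect_equal(nrow(sd2), 9L)
  expect_equal(ncol(sd2), 3L)            # pixel + 2 channels
  expect_equal(sd2$cy3, 1:9)
  cl3 <- cell_pixels(1:5, 1:5, 5:1)
  expect_equal(ncol(scatterplot_data(cl3)), 4L)
  ident <- scatterplot_data(cell_pixels(1:6, 1:6))
  expect_true(all(ident[[2L]] == ident[[3L]]))
})
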