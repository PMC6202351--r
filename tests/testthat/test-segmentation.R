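test_that("Otsu and Default thresholds separate a bimodal image", {
  img <- bimodal_image(100, 100, 10, 200)
  for (method in c("Otsu", "Default")) {
    cutoff <- auto_threshold(img, method, "dark_background")
    expect_gt(as.numeric(cutoff), 10)
    expect_lt(as.numeric(cutoff), 200)
    expect_equal(sum(threshold_mask(img, cutoff, "dark_background")), 100L)
  }
  # Otsu oracle: exhaustive between-class variance search on the 256-bin
  # histogram of min-max scaled values
  v <- as.numeric(img)
  bins <- pmin(255, floor((v - min(v)) / (max(v) - min(v)) * 256))
  h <- tabulate(bins + 1L, nbins = 256L)
  bcv <- vapply(0:254, function(t) {
    w1 <- sum(h[1:(t + 1)]); w2 <- sum(h) - w1
    if (w1 == 0 || w2 == 0) return(-1)
    m1 <- sum((0:t) * h[1:(t + 1)]) / w1
    m2 <- sum(((t + 1):255) * h[(t + 2):256]) / w2
    w1 * w2 * (m1 - m2)^2
  }, numeric(1))
  t_star <- which.max(bcv) - 1L
  expect_equal(attr(auto_threshold(img, "Otsu", "dark_background"), "bin"),
               t_star)
  # Default oracle: iterative intermeans fixed point
  t <- 128L
  repeat {
    in1 <- 0:255 <= t
    m1 <- sum((0:255)[in1] * h[in1]) / sum(h[in1])
    m2 <- sum((0:255)[!in1] * h[!in1]) / sum(h[!in1])
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t) break
    t <- t_new
  }
  expect_equal(attr(auto_threshold(img, "Default", "dark_background"),
                    "bin"), t)
})

test_that("all registry methods run; unknown methods and constant images error", {
  withr::with_seed(3, {
    img <- matrix(c(rnorm(150, 30, 5), rnorm(50, 180, 10)), 10, 20)
  })
  for (m in threshold_methods()) {
    cutoff <- auto_threshold(img, m, "dark_background")
    expect_true(is.finite(cutoff))
    fg <- sum(threshold_mask(img, cutoff, "dark_background"))
    expect_gt(fg, 0)
    expect_lt(fg, length(img))
  }
  # light-background mirror keeps separating the classes
  cutoff <- auto_threshold(img, "Otsu", "light_background")
  expect_equal(sum(threshold_mask(img, cutoff, "light_background")), 150L)
  expect_error(auto_threshold(img, "Nope", "dark_background"), "Otsu")
  expect_error(auto_threshold(matrix(5, 4, 4), "Otsu"), "constant")
})

test_that("watershed splits touching discs; off keeps them merged", {
  img <- touching_discs() * 100 + 10
  lm_on <- segment_cells(img, 50, use_watershed = TRUE)
  lm_off <- segment_cells(img, 50, use_watershed = FALSE)
  expect_equal(lm_on$n, 2L)
  expect_equal(lm_off$n, 1L)
  # the two split objects sit left and right
  expect_true(lm_on$labels[20, 20] != lm_on$labels[20, 35])
  expect_gt(lm_on$labels[20, 20], 0L)
  # watershed never merges: as many or more objects than without
  expect_gte(lm_on$n, lm_off$n)
})

test_that("pre-watershed area filter removes large blobs before splitting", {
  img <- matrix(0, 120, 120)
  img[disc_mask(120, 120, 30, 30, 10)] <- 100     # area ~317 cell
  img[40:110, 60:115] <- 100                       # ~3976 px blob
  lm <- segment_cells(img, 50, use_watershed = TRUE,
                      prewatershed_max_area = 1000)
  expect_equal(lm$n, 1L)
  expect_gt(lm$labels[30, 30], 0L)
  expect_equal(lm$labels[70, 80], 0L)
  # without the filter the blob survives
  lm2 <- segment_cells(img, 50, use_watershed = FALSE)
  expect_gte(lm2$n, 2L)
})

test_that("border-touching objects are removed and labels renumbered", {
  m <- matrix(FALSE, 20, 20)
  m[1:3, 8:10] <- TRUE          # touches row 1
  m[8:10, 8:10] <- TRUE
  m[14:16, 3:5] <- TRUE
  lm <- label_map(label_components(m))
  expect_equal(lm$n, 3L)
  lm2 <- remove_border_objects(lm)
  expect_equal(lm2$n, 2L)
  expect_equal(sort(unique(as.integer(lm2$labels[lm2$labels > 0]))),
               c(1L, 2L))
  # all-interior objects: unchanged up to renumbering
  lm3 <- remove_border_objects(lm2)
  expect_identical(lm3$labels, lm2$labels)
  # single frame-spanning object -> empty map with warning
  full <- label_map(matrix(1L, 5, 5))
  expect_warning(lm4 <- remove_border_objects(full), "border")
  expect_equal(lm4$n, 0L)
})

test_that("labeling is deterministic and raster-scan ordered", {
  withr::with_seed(7, m <- matrix(runif(400) < 0.3, 20, 20))
  l1 <- label_components(m)
  l2 <- label_components(m)
  expect_identical(l1, l2)
  # label 1 contains the first foreground pixel in raster order
  pos <- which(t(m), arr.ind = TRUE)   # row-major scan
  first <- pos[1, ]
  expect_equal(l1[first[2], first[1]], 1L)
})

test_that("features match brute-force accumulation on a known square", {
  lab <- matrix(0L, 16, 16)
  lab[6:8, 6:8] <- 1L                 # 3x3 square, rows/cols 5..7 (0-based)
  rep_img <- matrix(10, 16, 16)
  rep_img[6:8, 6:8] <- 50
  lm <- label_map(lab)
  ft <- compute_features(lm, channel_stack(rep_img, "reporter1"))
  expect_equal(ft$area, 9)
  expect_equal(ft$centroid_x, 6)
  expect_equal(ft$centroid_y, 6)
  expect_equal(ft$perimeter, 12)              # crack outline of a 3x3 square
  expect_equal(ft$circularity, min(1, 4 * pi * 9 / 144))
  expect_equal(ft$solidity, 1)
  expect_equal(ft$feret, sqrt(18))            # corner-to-corner diagonal
  expect_equal(ft$mean_intensity.reporter1, 50)
  expect_equal(ft$mean_bgnd_ratio.reporter1, 5)
  expect_equal(ft$median_bgnd_ratio.reporter1, 5)
})

test_that("feature computation matches per-pixel oracles on random maps", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      m <- matrix(runif(144) < 0.25, 12, 12)
      lab <- label_components(m)
      if (max(lab) == 0) next
      img <- matrix(runif(144, 1, 100), 12, 12)
      ft <- compute_features(label_map(lab),
                             channel_stack(img, "reporter1"))
      for (k in seq_len(max(lab))) {
        px <- which(lab == k)
        expect_equal(ft$area[k], length(px))
        expect_equal(ft$centroid_y[k], mean((px - 1) %% 12))
        expect_equal(ft$centroid_x[k], mean((px - 1) %/% 12))
        expect_equal(ft$mean_intensity.reporter1[k], mean(img[px]))
        expect_equal(ft$median_intensity.reporter1[k], median(img[px]))
        expect_equal(ft$mean_bgnd_ratio.reporter1[k],
                     mean(img[px]) / mean(img[lab == 0]))
      }
    }
  })
})

test_that("zero background yields NaN ratios per the NaN convention", {
  lab <- matrix(0L, 8, 8); lab[3:4, 3:4] <- 1L
  img <- matrix(0, 8, 8); img[3:4, 3:4] <- 42
  ft <- compute_features(label_map(lab), channel_stack(img, "reporter1"))
  expect_true(is.nan(ft$mean_bgnd_ratio.reporter1))
  expect_true(is.nan(ft$median_bgnd_ratio.reporter1))
})

test_that("cell filters retain objects inside inclusive bounds, per channel", {
  ft <- data.frame(label = 1:3, area = c(5, 40, 900),
                   mean_bgnd_ratio.reporter1 = c(1.1, 3.0, 2.5))
  class(ft) <- c("feature_table", "data.frame")
  expect_equal(apply_filters(ft, filter_spec("Area", 10, 500)), 2L)
  expect_equal(apply_filters(ft, list()), 1:3)
  expect_equal(
    apply_filters(ft, filter_spec("MeanBgndRatio", min = 2.0,
                                  channel = "reporter1")),
    2:3)
  # conjunction, order independent
  s1 <- filter_spec("Area", 10, 1000)
  s2 <- filter_spec("MeanBgndRatio", min = 2.6, channel = "reporter1")
  expect_equal(apply_filters(ft, list(s1, s2)),
               apply_filters(ft, list(s2, s1)))
  expect_equal(apply_filters(ft, list(s1, s2)), 2L)
  # inclusive at both ends
  expect_equal(apply_filters(ft, filter_spec("Area", 5, 900)), 1:3)
  # spec validation
  expect_error(filter_spec("Area", channel = "reporter1"), "must not")
  expect_error(filter_spec("MeanIntensity"), "requires")
  expect_error(filter_spec("Banana"), "unknown")
  expect_error(
    apply_filters(ft, filter_spec("MeanIntensity", channel = "reporter2")),
    "absent")
})
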