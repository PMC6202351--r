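test_that("top-fraction selection counts, ties and bounds are exact", {
  expect_equal(select_top_fraction(c(10, 30, 20, 40), 0.5), c(2L, 4L))
  expect_equal(select_top_fraction(c(5, 5, 5, 5), 0.5), c(1L, 2L))
  expect_equal(select_top_fraction(runif(7), 1), 1:7)
  expect_equal(length(select_top_fraction(runif(100), 0.004)), 1L)
  expect_error(select_top_fraction(1:4, 0), "fraction")
  expect_error(select_top_fraction(1:4, 1.2), "fraction")
})

test_that("TOS hits its extremes and the worked example", {
  withr::with_seed(5, a <- runif(100))
  ident <- cell_pixels(a, a)
  expect_equal(tos(ident, 0.1), 1)
  expect_equal(tos(ident, 0.1, scaling = "log"), 1)
  # disjoint top halves -> -1
  dis <- cell_pixels(c(rep(10, 50), rep(1, 50)),
                     c(rep(1, 50), rep(10, 50)))
  expect_equal(tos(dis, 0.5), -1)
  # fT=(0.2,0.3), overlap 10 of 100
  x <- numeric(100); y <- numeric(100)
  x[1:20] <- 100 + 1:20
  y[c(1:10, 21:40)] <- 100 + 1:30
  expect_equal(tos(cell_pixels(x, y), c(0.2, 0.3)),
               (0.10 - 0.06) / (0.20 - 0.06))
  # any fT = 1 is undefined (forced overlap)
  expect_true(is.nan(tos(ident, 1)))
  expect_true(is.nan(tos(ident, c(0.5, 1))))
  expect_true(is.nan(tos(ident, c(0.5, 1), scaling = "log")))
})

test_that("TOS formula equals the brute-force set-count oracle", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      a <- runif(100)
      b <- runif(100)
      cl <- cell_pixels(a, b)
      for (f1 in c(0.1, 0.3, 0.5, 0.9, 1)) for (f2 in c(0.2, 0.5, 1)) {
        got <- tos(cl, c(f1, f2))
        want <- tos_oracle(a, b, f1, f2)
        if (is.nan(want)) expect_true(is.nan(got))
        else expect_equal(got, want)
      }
    }
  })
})

test_that("three-channel TOS: extremes, bounds and permutation symmetry", {
  withr::with_seed(8, a <- runif(200))
  expect_equal(tos(cell_pixels(a, a, a), 0.1), 1)
  withr::with_seed(9, {
    for (rep in 1:10) {
      x <- runif(60); y <- runif(60); z <- runif(60)
      v <- tos(cell_pixels(x, y, z), c(0.2, 0.3, 0.4))
      expect_gte(v, -1); expect_lte(v, 1)
      # invariant under channel permutation (thresholds permute along)
      expect_equal(tos(cell_pixels(y, z, x), c(0.3, 0.4, 0.2)), v)
    }
  })
  # disjoint thirds at fT=1/3 anticolocalize
  x <- c(rep(9, 4), rep(0, 8)); y <- c(rep(0, 4), rep(9, 4), rep(0, 4))
  z <- c(rep(0, 8), rep(9, 4))
  expect_lt(tos(cell_pixels(x, y, z), 1 / 3), 0)
})

test_that("PCC and SRCC match hand computations and degenerate to NaN", {
  expect_equal(pcc(cell_pixels(c(1, 2, 3), c(2, 4, 6))), 1)
  expect_equal(pcc(cell_pixels(c(1, 2, 3, 4), c(1, 3, 2, 4))), 0.8)
  expect_true(is.nan(pcc(cell_pixels(c(2, 2, 2), c(1, 2, 3)))))
  expect_equal(srcc(cell_pixels(1:4, c(1, 3, 2, 4))), 0.8)
  expect_equal(srcc(cell_pixels(1:4, c(4, 3, 2, 1))), -1)
  # any strictly monotone transform gives rho = 1
  withr::with_seed(2, v <- runif(30))
  expect_equal(srcc(cell_pixels(v, exp(3 * v))), 1)
  # thresholded variants restrict to the intersection of selections
  a <- c(100, 90, 80, 1, 2, 3)
  b <- c(90, 100, 85, 3, 2, 1)
  r_top <- pcc(cell_pixels(a, b), spec = 0.5)
  expect_equal(r_top, cor(a[1:3], b[1:3]))
  expect_true(is.nan(pcc(cell_pixels(a, b), spec = 1 / 6)))  # single pixel
})

test_that("ICQ matches sign-counting for 2 and 3 channels", {
  expect_equal(icq(cell_pixels(1:4, 1:4)), 0.5)
  expect_equal(icq(cell_pixels(1:4, 10 - (1:4))), -0.5)
  expect_equal(icq(cell_pixels(c(1, 2, 3, 4), c(4, 1, 2, 3))), 0)
  # zero sign-products are excluded from numerator and denominator
  expect_equal(icq(cell_pixels(c(1, 2, 3, 2), c(1, 2, 3, 2))), 0.5)
  # 3-channel: identical channels hit the upper bound 0.75
  expect_equal(icq(cell_pixels(1:4, 1:4, 1:4)), 0.75)
  # one inverted channel: no pixel has all three signs equal
  expect_equal(icq(cell_pixels(1:4, 1:4, 10 - (1:4))), -0.25)
  # empty restriction -> NaN
  cl <- cell_pixels(c(10, 0, 0, 0), c(0, 10, 0, 0), c(0, 0, 10, 0))
  expect_true(is.nan(icq(cl, spec = 0.25)))
})

test_that("Manders coefficients: sums, extremes, NaN and monotonicity", {
  m <- manders(cell_pixels(c(5, 1, 0, 4), c(10, 0, 0, 10)), c(1, 0.5))
  expect_equal(unname(m["M1"]), 0.9)        # (5+4)/10 over ch2 top half
  expect_equal(unname(manders(cell_pixels(1:4, 4:1), c(1, 1))), c(1, 1))
  expect_true(is.nan(manders(cell_pixels(rep(0, 4), 1:4),
                             c(0.5, 0.5))[["M1"]]))
  # 3-channel M1 uses the intersection of channels 2 and 3 selections
  a <- c(8, 4, 2, 1); b <- c(9, 9, 0, 0); c3 <- c(9, 0, 9, 0)
  m3 <- manders(cell_pixels(a, b, c3), c(1, 0.5, 0.5))
  expect_equal(unname(m3["M1"]), 8 / 15)    # only pixel 1 in both selections
  # M1 non-decreasing in channel-2 fT
  withr::with_seed(31, cl <- cell_pixels(runif(50), runif(50)))
  prev <- 0
  for (f2 in seq(0.1, 1, by = 0.1)) {
    cur <- manders(cl, c(1, f2))[["M1"]]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("metrics are invariant under positive affine/scalar rescaling", {
  withr::with_seed(13, {
    a <- runif(80); b <- runif(80)
  })
  cl <- cell_pixels(a, b)
  cl2 <- cell_pixels(3 * a + 7, 0.5 * b + 1)
  expect_equal(pcc(cl2), pcc(cl))
  expect_equal(srcc(cl2), srcc(cl))
  expect_equal(icq(cl2), icq(cl))
  expect_equal(tos(cl2, c(0.2, 0.4)), tos(cl, c(0.2, 0.4)))
  # Manders under positive scalar multiplication only
  cl3 <- cell_pixels(3 * a, 5 * b)
  expect_equal(manders(cl3, c(0.3, 0.3)), manders(cl, c(0.3, 0.3)))
})

test_that("symmetric metrics commute with channel exchange", {
  withr::with_seed(17, {
    a <- runif(60); b <- runif(60)
  })
  cl <- cell_pixels(a, b); rl <- cell_pixels(b, a)
  expect_equal(pcc(cl), pcc(rl))
  expect_equal(srcc(cl), srcc(rl))
  expect_equal(icq(cl), icq(rl))
  expect_equal(tos(cl, c(0.2, 0.5)), tos(rl, c(0.5, 0.2)))
  m <- manders(cl, c(0.2, 0.5)); mr <- manders(rl, c(0.5, 0.2))
  expect_equal(unname(m["M1"]), unname(mr["M2"]))
  expect_equal(unname(m["M2"]), unname(mr["M1"]))
})

test_that("Costes thresholds: independent noise stops high, B=A descends", {
  withr::with_seed(41, {
    a <- runif(500, 0, 1000)
    b <- runif(500, 0, 1000)
  })
  ct <- costes_thresholds(cell_pixels(a, b))
  expect_true(ct$converged)
  expect_gte(ct$t1, quantile(a, 0.9))        # top decile of A
  expect_equal(ct$t2, ct$intercept + ct$slope * ct$t1)
  # perfectly correlated: never <= 0, descend to the minimum with warning
  expect_warning(cd <- costes_thresholds(cell_pixels(a, 2 * a + 5)),
                 "minimum")
  expect_false(cd$converged)
  expect_equal(cd$t1, min(a))
  # preconditions
  expect_error(costes_thresholds(cell_pixels(1:5, 5:1)), "8 pixels")
  expect_error(costes_thresholds(cell_pixels(rep(1, 10), 1:10)),
               "degenerate")
})
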