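test_that("first-order features match direct summation on arbitrary patches", {
  set.seed(42)
  patch <- matrix(runif(25, 0, 255), 5, 5)
  f <- first_order_features(patch)
  # brute-force population statistics, element by element
  n <- length(patch); s <- 0
  for (v in patch) s <- s + v
  mu <- s / n
  ss <- 0
  for (v in patch) ss <- ss + (v - mu)^2
  expect_equal(unname(f["mean"]), mu, tolerance = 1e-12)
  expect_equal(unname(f["std"]), sqrt(ss / n), tolerance = 1e-12)
  expect_equal(unname(f["range"]), max(patch) - min(patch))
})

test_that("first-order features on degenerate patches", {
  f <- first_order_features(matrix(100, 7, 7))
  expect_equal(unname(f[c("mean", "std", "range", "sobel")]),
               c(100, 0, 0, 0))
  checker <- matrix(c(0, 255), 6, 6)
  expect_equal(unname(first_order_features(checker)["range"]), 255)
  # translation invariance of dispersion statistics
  set.seed(1); p <- matrix(rnorm(64), 8, 8)
  expect_equal(first_order_features(p + 50)[c("std", "range", "sobel")],
               first_order_features(p)[c("std", "range", "sobel")],
               tolerance = 1e-10)
  expect_error(first_order_features(1:10), "2-D")
})

test_that("co-occurrence matrix matches hand pair enumeration", {
  # patch [[0,0],[1,1]] (rows), levels 2, distance 1.
  # 0 deg: pairs (0,0),(1,1) -> symmetric counts diag(2,2) -> diag(.5,.5)
  # 90 deg: vertical pairs (1,0)x2 -> off-diagonal .5/.5
  # 45/135 deg: single (1,0) pair each -> off-diagonal .5/.5
  # average of the four: [[.125,.375],[.375,.125]]
  patch <- rbind(c(0, 0), c(1, 1))
  P <- cooccurrence_matrix(patch, levels = 2, distance = 1)
  expect_equal(P, rbind(c(0.125, 0.375), c(0.375, 0.125)), tolerance = 1e-12)
})

test_that("co-occurrence matrices are normalized and symmetric", {
  set.seed(7)
  for (i in 1:5) {
    patch <- matrix(runif(900), 30, 30)
    P <- cooccurrence_matrix(patch, levels = 64, distance = 1)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
  }
  expect_error(cooccurrence_matrix(matrix(1, 2, 2), levels = 1), "levels")
  expect_error(cooccurrence_matrix(matrix(1, 2, 2), distance = 2), "larger")
})

test_that("Haralick features behave on degenerate and random inputs", {
  h <- haralick_features(matrix(5, 10, 10))
  expect_equal(unname(h["har_energy"]), 1)
  expect_equal(unname(h["har_entropy"]), 0)
  expect_equal(unname(h["har_contrast"]), 0)
  expect_length(h, 13)
  set.seed(3)
  for (patch in list(matrix(rnorm(100), 10, 10),
                     matrix(c(7, 8), 9, 8),       # single-pixel range
                     matrix(0, 5, 5))) {
    expect_true(all(is.finite(haralick_features(patch, levels = 8))))
  }
})

test_that("Haralick energy and entropy match direct formulas from the GLCM", {
  set.seed(11)
  patch <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  P <- cooccurrence_matrix(patch, levels = 4, distance = 1)
  h <- haralick_features(patch, levels = 4, distance = 1)
  expect_equal(unname(h["har_energy"]), sum(P^2), tolerance = 1e-12)
  nz <- P[P > 0]
  expect_equal(unname(h["har_entropy"]), -sum(nz * log(nz)),
               tolerance = 1e-12)
  ii <- row(P); jj <- col(P)
  expect_equal(unname(h["har_contrast"]), sum((ii - jj)^2 * P),
               tolerance = 1e-12)
})

test_that("Gabor bank has 40 filters, zero DC response, and matched tuning", {
  bank <- gabor_bank()
  expect_equal(nrow(bank), 40)
  expect_error(gabor_bank(frequencies = 0.7), "frequencies")
  g <- gabor_features(matrix(0.7, 20, 20))
  expect_length(g, 40)
  expect_true(all(g < 1e-6))
  # response is maximal at the bank filter matching the grating
  for (f0 in c(0.1, 0.2)) for (oi in c(1, 5)) {
    th <- (oi - 1) * pi / 8
    grating <- outer(0:29, 0:29,
                     function(r, c) sin(2 * pi * f0 * (c * cos(th) +
                                                         r * sin(th))))
    gg <- gabor_features(grating)
    expect_equal(names(which.max(gg)), sprintf("gabor_f%.3f_o%d", f0, oi))
  }
})

test_that("rotating a grating to another bank orientation moves the peak accordingly", {
  resp_at <- function(th) {
    grating <- outer(0:29, 0:29,
                     function(r, c) sin(2 * pi * 0.2 * (c * cos(th) +
                                                          r * sin(th))))
    gabor_features(grating)[sprintf("gabor_f0.200_o%d", 1:8)]
  }
  r1 <- resp_at(0)
  r2 <- resp_at(pi / 2)         # quarter turn: orientation index 1 -> 5
  expect_equal(unname(which.max(r1)), 1)
  expect_equal(unname(which.max(r2)), 5)
  expect_equal(unname(r1[1]), unname(r2[5]), tolerance = 0.05)
})

test_that("patch feature vectors honor the selection and the registry", {
  expect_length(default_feature_selection(), 14)
  expect_true(all(default_feature_selection() %in% feature_registry()))
  expect_length(feature_registry(), 7 + 13 + 40)

  set.seed(5)
  img <- matrix(runif(60 * 60), 60, 60)
  v <- patch_feature_vector(img, c(10, 10, 30))
  expect_length(v, 14)
  expect_named(v, default_feature_selection())
  expect_true(all(is.finite(v)))
  # identical regions give identical vectors (determinism)
  expect_identical(v, patch_feature_vector(img, c(10, 10, 30)))
  expect_error(patch_feature_vector(img, c(50, 50, 30)), "bounds")
  expect_error(patch_feature_vector(img, c(0, 0, 30), selection = "nope"),
               "unknown feature")
  full <- patch_feature_vector(img, c(0, 0, 30),
                               selection = feature_registry())
  expect_length(full, 60)
})
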