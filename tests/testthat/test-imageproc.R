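# Raster primitives against their definitions and brute-force oracles.

test_that("gaussian_blur preserves constants, mass, and matches dense convolution", {
  const <- matrix(7.5, 9, 13)
  expect_equal(gaussian_blur(const, 2), const)

  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  expect_equal(sum(gaussian_blur(imp, 1)), 1, tolerance = 1e-12)

  # brute-force oracle: explicitly sampled, truncated-and-renormalized
  # kernel applied by dense convolution with replicate padding
  set.seed(101)
  img <- matrix(runif(25), 5, 5)
  r <- 3
  k1 <- dnorm(-r:r, sd = 1); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), 5); jj <- min(max(j + dj, 1), 5)
      acc <- acc + kern[di + r + 1, dj + r + 1] * img[ii, jj]
    }
    ref[i, j] <- acc
  }
  expect_lt(max(abs(gaussian_blur(img, 1) - ref)), 1e-9)

  expect_identical(gaussian_blur(img, 0), img)
  expect_error(gaussian_blur(img, -1), "non-negative")
})

test_that("otsu_threshold separates a two-level image and flags constants", {
  img <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  th <- otsu_threshold(img)
  expect_false(th$degenerate)
  expect_identical(th$mask, img == 200)

  flat <- matrix(3, 8, 8)
  thf <- otsu_threshold(flat)
  expect_true(thf$degenerate)
  expect_identical(sum(thf$mask), 0L)
})

test_that("otsu_threshold equals the exhaustive between-class-variance scan", {
  # spec-style histogram: 10 px at 10, 5 px at 100, 5 px at 200
  img <- matrix(c(rep(10, 10), rep(100, 5), rep(200, 5)), 4, 5)
  expect_equal(otsu_threshold(img)$threshold, oracle_otsu(img))

  set.seed(42)
  for (i in 1:10) {
    img <- matrix(sample(c(rnorm(40, 20, 5), rnorm(24, 80, 10))), 8, 8)
    expect_equal(otsu_threshold(img)$threshold, oracle_otsu(img))
  }
})

test_that("despeckle removes isolated pixels and matches the per-pixel median oracle", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_false(any(despeckle(m)))

  solid <- matrix(FALSE, 12, 12); solid[3:10, 3:10] <- TRUE
  expect_identical(despeckle(solid)[4:9, 4:9], solid[4:9, 4:9])

  set.seed(7)
  for (i in 1:5) {
    m <- random_mask(32, 32)
    expect_identical(despeckle(m), oracle_median3x3(m * 1) > 0.5)
    img <- matrix(runif(32 * 32), 32, 32)
    expect_equal(despeckle(img), oracle_median3x3(img))
  }
})

test_that("dilate/erode follow the set definition and its iterates", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  d1 <- binary_dilate(m, 1)
  expect_identical(which(d1), which(mk_disc(7, 7, 4, 4, 1.5)))
  expect_identical(sum(d1), 9L)

  # opening of a convex solid away from borders restores it
  sq <- matrix(FALSE, 30, 30); sq[10:20, 12:22] <- TRUE
  expect_identical(binary_erode(binary_dilate(sq, 3), 3), sq)

  set.seed(11)
  for (i in 1:5) {
    m <- random_mask(32, 32, 0.3)
    expect_identical(binary_dilate(m, 2), oracle_dilate(m, 2))
    expect_identical(binary_erode(m, 1), oracle_erode(m, 1))
  }
  expect_identical(binary_dilate(sq, 0), sq)
  expect_error(binary_erode(sq, -2), "non-negative")
})

test_that("erosion is the exact dual of dilation on a padded domain", {
  set.seed(13)
  for (i in 1:10) {
    m <- random_mask(24, 24)
    p <- matrix(FALSE, 26, 26); p[2:25, 2:25] <- m
    expect_identical(binary_erode(p, 1), !binary_dilate(!p, 1))
  }
})

test_that("dilation is extensive, erosion anti-extensive, both monotone", {
  set.seed(17)
  for (i in 1:8) {
    m <- random_mask(20, 20, 0.35)
    sub <- m & random_mask(20, 20, 0.7)   # sub is a subset of m
    expect_true(all(m <= binary_dilate(m, 1)))
    expect_true(all(binary_erode(m, 1) <= m))
    expect_true(all(binary_dilate(sub, 1) <= binary_dilate(m, 1)))
    expect_true(all(binary_erode(sub, 1) <= binary_erode(m, 1)))
  }
})

test_that("binary_close bridges sub-element gaps, fixes discs, is idempotent", {
  m <- matrix(FALSE, 10, 15)
  m[4:7, 3:6] <- TRUE; m[4:7, 8:11] <- TRUE   # 1-px gap at column 7
  closed <- binary_close(m)
  expect_true(all(closed[4:7, 7]))

  disc <- mk_disc(25, 25, 13, 13, 8)
  expect_identical(binary_close(disc), disc)

  set.seed(19)
  for (i in 1:5) {
    m <- random_mask(32, 32)
    ref <- oracle_erode(oracle_dilate(m, 1), 1)
    got <- binary_close(m)
    expect_identical(got, ref)
    expect_identical(binary_close(got), got)
  }
})

test_that("fill_holes fills enclosed background only and is idempotent", {
  ring <- mk_disc(21, 21, 11, 11, 8) & !mk_disc(21, 21, 11, 11, 7)
  filled <- fill_holes(ring)
  expect_identical(filled, mk_disc(21, 21, 11, 11, 8))

  open_shape <- matrix(FALSE, 10, 10); open_shape[3:6, 3:6] <- TRUE
  expect_identical(fill_holes(open_shape), open_shape)

  set.seed(23)
  for (i in 1:5) {
    m <- random_mask(32, 32)
    got <- fill_holes(m)
    expect_identical(got, oracle_fill_holes(m))
    expect_true(all(m <= got))            # foreground never removed
    expect_identical(fill_holes(got), got)
  }
})

test_that("watershed_split separates touching discs and respects seeds", {
  # two radius-10 discs, centers 15 px apart (overlapping)
  m <- mk_disc(60, 60, 30, 22, 10) | mk_disc(60, 60, 30, 37, 10)
  lab <- watershed_split(m, 8)
  expect_identical(n_labels(lab), 2L)
  # the split pieces are disconnected: a 1-px background line separates them
  expect_identical(n_labels(label_particles(lab > 0, 8)), 2L)

  one <- mk_disc(40, 40, 20, 20, 12)
  lab1 <- watershed_split(one, 8)
  expect_identical(n_labels(lab1), 1L)
  expect_identical(lab1 > 0, one)         # nothing lost for a single object

  empty <- matrix(FALSE, 16, 16)
  expect_identical(n_labels(watershed_split(empty, 8)), 0L)
})

test_that("watershed_split finds k labels on k well-separated discs", {
  for (k in c(2, 5, 10)) {
    m <- matrix(FALSE, 64, 64 * 2)
    centers <- cbind(row = 12 + 40 * ((seq_len(k) - 1) %/% 5),
                     col = 12 + 24 * ((seq_len(k) - 1) %% 5))
    for (i in seq_len(k)) m <- m | mk_disc(64, 128, centers[i, 1], centers[i, 2], 8)
    expect_identical(n_labels(watershed_split(m, 6)), as.integer(k))
  }
})

test_that("label_particles counts, filters and conserves foreground", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE; m[10:14, 10:14] <- TRUE
  lab <- label_particles(m, 8)
  expect_identical(n_labels(lab), 2L)
  expect_identical(as.integer(table(lab[lab > 0])), c(25L, 25L))

  diag2 <- matrix(FALSE, 5, 5); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_identical(n_labels(label_particles(diag2, 8)), 1L)
  expect_identical(n_labels(label_particles(diag2, 4)), 2L)

  set.seed(29)
  for (i in 1:5) {
    m <- random_mask(64, 64, 0.35)
    ref <- oracle_label(m, 8L)
    areas <- table(ref[ref > 0])
    keep <- as.integer(names(areas)[areas >= 5])
    lab <- label_particles(m, 8, min_area_px = 5)
    expect_identical(n_labels(lab), length(keep))
    # conservation: surviving labels plus removed components tile the mask
    expect_identical((lab > 0) | (ref > 0 & !(ref %in% keep)), m)
    # identical partition of surviving pixels
    expect_true(all((lab > 0) == (ref %in% keep & ref > 0)))
  }
  expect_error(label_particles(m, 6), "connectivity")
  expect_error(label_particles(m, 8, min_area_px = 10, max_area_px = 5), "exceed")
})

test_that("label maps are contiguous with raster-ordered labels", {
  set.seed(31)
  m <- random_mask(40, 40, 0.3)
  lab <- label_particles(m, 4)
  k <- n_labels(lab)
  expect_identical(sort(unique(as.integer(lab[lab > 0]))), seq_len(k))
  # first pixel (row-major) of label i precedes that of label i+1
  h <- nrow(lab)
  firsts <- vapply(seq_len(k), function(i) {
    idx <- which(lab == i)
    min((((idx - 1) %% h)) * ncol(lab) + ((idx - 1) %/% h))
  }, numeric(1))
  expect_true(all(diff(firsts) > 0))
})
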