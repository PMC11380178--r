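# Synthetic micrograph generator: determinism, ground-truth consistency,
# membership bookkeeping and index oracle arithmetic.

small_cfg <- function(..., seed = 5L) {
  simulation_config(height_px = 256L, width_px = 256L, n_nuclei = 30L,
                    n_myotubes = 2L, myotube_length_px = 220,
                    myotube_width_px = 40, seed = seed, ...)
}

test_that("an empty scene is background plus noise with empty truth", {
  cfg <- simulation_config(height_px = 64L, width_px = 64L, n_nuclei = 0L,
                           n_myotubes = 0L, noise_sd = 0, psf_sigma_px = 0,
                           seed = 1L)
  sim <- generate_image(cfg)
  expect_identical(nrow(sim$truth$nuclei), 0L)
  expect_identical(length(sim$truth$myotubes), 0L)
  expect_true(all(get_channel(sim$image, "nuclei") == cfg$background_level))
  expect_true(all(get_channel(sim$image, "myotubes") == cfg$background_level))

  noisy <- generate_image(simulation_config(height_px = 64L, width_px = 64L,
                                            n_nuclei = 0L, n_myotubes = 0L,
                                            noise_sd = 50, seed = 2L))
  ch <- get_channel(noisy$image, "nuclei")
  expect_lt(abs(mean(ch) - 1000), 10)      # ~background_level
  expect_lt(abs(sd(ch) - 50), 5)
})

test_that("the realized inside fraction hits target_mdi exactly when feasible", {
  cfg <- simulation_config(n_nuclei = 100L, target_mdi = 0.5, seed = 7L)
  sim <- generate_image(cfg)
  expect_identical(sum(sim$truth$nuclei$inside_myotube_id > 0L), 50L)
  expect_equal(sim$truth$realized_mdi, 0.5)

  for (tm in c(0.2, 0.6)) {
    sim <- generate_image(small_cfg(target_mdi = tm))
    expect_equal(sim$truth$realized_mdi, round(tm * 30) / 30)
  }
})

test_that("equal configurations reproduce bit-identical output", {
  cfg <- small_cfg()
  a <- generate_image(cfg)
  b <- generate_image(cfg)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(lapply(a$truth$myotubes, `[[`, "footprint"),
                   lapply(b$truth$myotubes, `[[`, "footprint"))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_image(small_cfg()))
  expect_identical(runif(1), before)
})

test_that("membership flags agree with footprint geometry", {
  for (s in c(3L, 9L, 27L)) {
    sim <- generate_image(small_cfg(seed = s))
    nuc <- sim$truth$nuclei
    fps <- lapply(sim$truth$myotubes, `[[`, "footprint")
    for (i in seq_len(nrow(nuc))) {
      r <- round(nuc$center_row[i]); c <- round(nuc$center_col[i])
      k <- nuc$inside_myotube_id[i]
      if (k > 0) {
        expect_true(fps[[k]][r, c])
      } else {
        expect_false(any(vapply(fps, function(f) f[r, c], logical(1))))
      }
    }
    counts <- vapply(sim$truth$myotubes, `[[`, integer(1),
                     "intended_nucleus_count")
    expect_identical(sum(counts),
                     sum(nuc$inside_myotube_id > 0L))
  }
})

test_that("noise-free render support equals the ground-truth footprints", {
  cfg <- small_cfg(noise_sd = 0, psf_sigma_px = 0)
  sim <- generate_image(cfg)
  tube_support <- get_channel(sim$image, "myotubes") > cfg$background_level
  fp_union <- Reduce(`|`, lapply(sim$truth$myotubes, `[[`, "footprint"))
  expect_identical(tube_support, fp_union)

  nuc_support <- get_channel(sim$image, "nuclei") > cfg$background_level
  nuc <- sim$truth$nuclei
  ellipse_union <- matrix(FALSE, cfg$height_px, cfg$width_px)
  for (i in seq_len(nrow(nuc))) {
    ellipse_union <- ellipse_union |
      mk_ellipse_mask(cfg$height_px, cfg$width_px, nuc$center_row[i],
                      nuc$center_col[i], nuc$semi_major[i],
                      nuc$semi_minor[i], nuc$angle[i])
  }
  expect_identical(nuc_support, ellipse_union)
})

test_that("touching pairs are generated at the requested fraction with <= 1 px gaps", {
  cfg <- simulation_config(height_px = 400L, width_px = 400L, n_nuclei = 50L,
                           touching_pair_fraction = 0.2, n_myotubes = 2L,
                           myotube_length_px = 250, target_mdi = 0.3,
                           seed = 13L)
  sim <- generate_image(cfg)
  nuc <- sim$truth$nuclei
  # boundary gap to the nearest neighbour, approximated along the
  # center-to-center line by the semi-major axes (pairs are co-oriented
  # along their major axes, so this is exact for pair partners)
  n <- nrow(nuc)
  gaps <- vapply(seq_len(n), function(i) {
    d <- sqrt((nuc$center_row - nuc$center_row[i])^2 +
              (nuc$center_col - nuc$center_col[i])^2)
    d[i] <- Inf
    j <- which.min(d)
    d[j] - nuc$semi_major[i] - nuc$semi_major[j]
  }, numeric(1))
  expect_identical(sum(gaps <= 1), 10L)   # 2 * round(0.2 * 50 / 2)
})

test_that("a multinucleation profile fixes per-myotube intended counts", {
  cfg <- small_cfg(multinucleation_profile = c(7L, 3L),
                   touching_pair_fraction = 0)
  sim <- generate_image(cfg)
  counts <- vapply(sim$truth$myotubes, `[[`, integer(1),
                   "intended_nucleus_count")
  expect_identical(counts, c(7L, 3L))
  gt <- ground_truth_indices(sim$truth)
  expect_equal(gt$mdi, 10 / 30)
  expect_equal(gt$mfi, 10 / 30)
})

test_that("infeasible placement fails with an explicit constraint error", {
  expect_error(
    generate_image(simulation_config(height_px = 64L, width_px = 64L,
                                     n_nuclei = 0L, n_myotubes = 20L,
                                     myotube_width_px = 30,
                                     myotube_length_px = 60, seed = 1L)),
    "myotube placement infeasible")
  expect_error(
    generate_image(simulation_config(height_px = 80L, width_px = 80L,
                                     n_nuclei = 60L, n_myotubes = 0L,
                                     target_mdi = 0, seed = 1L)),
    "nucleus placement infeasible")
})

test_that("ground_truth_indices computes the stated arithmetic", {
  mk_truth <- function(inside_ids, n_tubes) {
    structure(list(
      nuclei = data.frame(id = seq_along(inside_ids),
                          center_row = 1, center_col = 1,
                          semi_major = 1, semi_minor = 1, angle = 0,
                          inside_myotube_id = inside_ids),
      myotubes = lapply(seq_len(n_tubes), function(i)
        list(id = i, footprint = matrix(TRUE, 1, 1),
             intended_nucleus_count = sum(inside_ids == i))),
      realized_mdi = mean(inside_ids > 0)
    ), class = "ground_truth")
  }
  expect_equal(ground_truth_indices(mk_truth(rep(0L, 10), 1))$mdi, 0)
  expect_equal(ground_truth_indices(mk_truth(rep(1L, 10), 1))$mdi, 1)
  expect_equal(ground_truth_indices(mk_truth(rep(1L, 10), 1))$mfi, 1)

  # myotube counts {5, 3, 1} plus 11 outside: MDI = 9/20, MFI (>=2) = 8/20
  ids <- c(rep(1L, 5), rep(2L, 3), rep(3L, 1), rep(0L, 11))
  gt <- ground_truth_indices(mk_truth(ids, 3), mfi_min_nuclei = 2)
  expect_identical(gt$n_total, 20L)
  expect_equal(gt$mdi, 0.45)
  expect_equal(gt$mfi, 0.40)
  expect_identical(gt$histogram, c("1" = 1L, "2-4" = 1L, ">=5" = 1L))
})
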