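# Seeded synthetic two-channel micrographs with exact object-level ground
# truth. The generator emulates the quantified stainings: a dark background
# with additive Gaussian noise, bright elliptical DAPI nuclei (a controlled
# fraction placed as touching pairs), elongated capsule-shaped MF20 myotube
# footprints containing a controlled fraction of the nuclei, and a Gaussian
# point-spread-function blur. Images are emitted as 16-bit integers.

#' Configuration for the synthetic micrograph generator
#'
#' Defaults describe the simulated study conditions: 512 x 512 rasters with
#' 150 nuclei of ~8 px radius, six myotubes of 40 x 400 px, half of the
#' nuclei inside myotubes, 10% of nuclei in touching pairs, a 1 px PSF and
#' moderate additive noise on a dim background.
#'
#' @param height_px,width_px canvas size, pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_mean_px,nucleus_radius_sd_px equivalent-circle
#'   nucleus radius distribution, pixels.
#' @param nucleus_eccentricity_max maximum ellipse eccentricity in \\[0, 1).
#' @param touching_pair_fraction fraction of nuclei generated as
#'   co-oriented pairs with a boundary-to-boundary gap of at most 1 px.
#' @param n_myotubes number of myotube footprints.
#' @param myotube_width_px,myotube_length_px capsule width and total
#'   length, pixels.
#' @param target_mdi intended fraction of nuclei inside myotubes.
#' @param multinucleation_profile optional integer vector of intended
#'   nucleus counts per myotube (length `n_myotubes`); overrides
#'   `target_mdi`, and touching pairs are then placed outside myotubes.
#' @param psf_sigma_px Gaussian point-spread-function sigma, pixels.
#' @param background_level,noise_sd background intensity and additive
#'   Gaussian noise SD, intensity units.
#' @param nucleus_intensity,myotube_intensity object intensities.
#' @param seed integer RNG seed; equal configs reproduce identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(height_px = 512L, width_px = 512L,
                              n_nuclei = 150L,
                              nucleus_radius_mean_px = 8,
                              nucleus_radius_sd_px = 1,
                              nucleus_eccentricity_max = 0.6,
                              touching_pair_fraction = 0.1,
                              n_myotubes = 6L,
                              myotube_width_px = 40,
                              myotube_length_px = 400,
                              target_mdi = 0.5,
                              multinucleation_profile = NULL,
                              psf_sigma_px = 1,
                              background_level = 1000,
                              noise_sd = 100,
                              nucleus_intensity = 20000,
                              myotube_intensity = 15000,
                              seed = 1L) {
  cfg <- list(height_px = as.integer(height_px), width_px = as.integer(width_px),
              n_nuclei = as.integer(n_nuclei),
              nucleus_radius_mean_px = nucleus_radius_mean_px,
              nucleus_radius_sd_px = nucleus_radius_sd_px,
              nucleus_eccentricity_max = nucleus_eccentricity_max,
              touching_pair_fraction = touching_pair_fraction,
              n_myotubes = as.integer(n_myotubes),
              myotube_width_px = myotube_width_px,
              myotube_length_px = myotube_length_px,
              target_mdi = target_mdi,
              multinucleation_profile = if (is.null(multinucleation_profile))
                NULL else as.integer(multinucleation_profile),
              psf_sigma_px = psf_sigma_px,
              background_level = background_level,
              noise_sd = noise_sd,
              nucleus_intensity = nucleus_intensity,
              myotube_intensity = myotube_intensity,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$height_px >= 1L, cfg$width_px >= 1L,
            cfg$n_nuclei >= 0L, cfg$n_myotubes >= 0L,
            cfg$nucleus_radius_mean_px > 0, cfg$nucleus_radius_sd_px >= 0,
            cfg$nucleus_eccentricity_max >= 0, cfg$nucleus_eccentricity_max < 1,
            cfg$touching_pair_fraction >= 0, cfg$touching_pair_fraction <= 1,
            cfg$myotube_width_px > 0, cfg$myotube_length_px > 0,
            cfg$target_mdi >= 0, cfg$target_mdi <= 1,
            cfg$psf_sigma_px >= 0, cfg$background_level >= 0,
            cfg$noise_sd >= 0, cfg$nucleus_intensity >= 0,
            cfg$myotube_intensity >= 0)
  if (!is.null(cfg$multinucleation_profile)) {
    stopifnot(length(cfg$multinucleation_profile) == cfg$n_myotubes,
              all(cfg$multinucleation_profile >= 0L),
              sum(cfg$multinucleation_profile) <= cfg$n_nuclei)
  }
  invisible(cfg)
}

# ---- geometry helpers -------------------------------------------------------

point_seg_dist <- function(pr, pc, a, b) {
  # distance from point (pr, pc) to segment a->b, each c(row, col)
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  l2 <- vr^2 + vc^2
  t <- if (l2 == 0) 0 else max(0, min(1, ((pr - a[1]) * vr + (pc - a[2]) * vc) / l2))
  sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
}

seg_seg_dist <- function(p1, q1, p2, q2) {
  # minimum distance between two 2-D segments: segments either intersect or
  # the minimum is attained at an endpoint
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(p2, q2, p1); d2 <- orient(p2, q2, q1)
  d3 <- orient(p1, q1, p2); d4 <- orient(p1, q1, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(point_seg_dist(p1[1], p1[2], p2, q2),
      point_seg_dist(q1[1], q1[2], p2, q2),
      point_seg_dist(p2[1], p2[2], p1, q1),
      point_seg_dist(q2[1], q2[2], p1, q1))
}

capsule_mask <- function(h, w, a, b, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  l2 <- vr^2 + vc^2
  t <- if (l2 == 0) matrix(0, h, w)
       else pmin(pmax(((rr - a[1]) * vr + (cc - a[2]) * vc) / l2, 0), 1)
  dr <- rr - (a[1] + t * vr); dc <- cc - (a[2] + t * vc)
  dr * dr + dc * dc <= radius^2
}

draw_ellipse <- function(img, r0, c0, a, b, theta, value) {
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(r0 - rad)):min(h, ceiling(r0 + rad))
  cols <- max(1L, floor(c0 - rad)):min(w, ceiling(c0 + rad))
  if (!length(rows) || !length(cols)) return(img)
  dr <- matrix(rows - r0, length(rows), length(cols))
  dc <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  patch <- img[rows, cols, drop = FALSE]
  patch[inside] <- pmax(patch[inside], value)
  img[rows, cols] <- patch
  img
}

# ---- generator --------------------------------------------------------------

MAX_PLACEMENT_TRIES <- 1000L

place_myotubes <- function(cfg) {
  h <- cfg$height_px; w <- cfg$width_px
  half_w <- cfg$myotube_width_px / 2
  half_len <- max(0, (cfg$myotube_length_px - cfg$myotube_width_px) / 2)
  gap <- 12  # keeps footprints separable after the net-dilation chain
  # crowded fields get semi-aligned tubes (as dense differentiating
  # cultures do); sparse fields use fully random orientations
  aligned <- cfg$n_myotubes * (2 * half_w + gap) > 0.7 * min(h, w)
  for (restart in 1:10) {
    base_theta <- runif(1, 0, pi)
    axes <- vector("list", cfg$n_myotubes)
    all_placed <- TRUE
    for (i in seq_len(cfg$n_myotubes)) {
      placed <- FALSE
      for (try in seq_len(MAX_PLACEMENT_TRIES)) {
        theta <- if (aligned) (base_theta + rnorm(1, 0, pi / 18)) %% pi
                 else runif(1, 0, pi)
        ctr <- c(runif(1, half_w + 2, h - half_w - 2),
                 runif(1, half_w + 2, w - half_w - 2))
        p <- ctr - half_len * c(cos(theta), sin(theta))
        q <- ctr + half_len * c(cos(theta), sin(theta))
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (seg_seg_dist(p, q, axes[[j]]$p, axes[[j]]$q) <
              2 * half_w + gap) { ok <- FALSE; break }
        }
        if (ok) { axes[[i]] <- list(p = p, q = q); placed <- TRUE; break }
      }
      if (!placed) { all_placed <- FALSE; break }
    }
    if (all_placed) {
      masks <- lapply(axes, function(ax) capsule_mask(h, w, ax$p, ax$q, half_w))
      return(list(axes = axes, masks = masks, half_w = half_w))
    }
  }
  stop(sprintf(paste0("myotube placement infeasible: could not place %d ",
                      "footprints with pairwise axis clearance >= %.1f px ",
                      "in a %d x %d canvas (%d retries per footprint, ",
                      "10 scene restarts)"),
               cfg$n_myotubes, 2 * half_w + gap, h, w,
               MAX_PLACEMENT_TRIES), call. = FALSE)
}

plan_membership <- function(cfg) {
  n <- cfg$n_nuclei
  n_pairs <- round(cfg$touching_pair_fraction * n / 2)
  n_pair_nuclei <- 2L * n_pairs
  n_singles <- n - n_pair_nuclei
  if (!is.null(cfg$multinucleation_profile)) {
    n_inside <- sum(cfg$multinucleation_profile)
    p_in <- 0L
    s_in <- min(n_inside, n_singles)
  } else if (cfg$n_myotubes == 0L) {
    n_inside <- 0L; p_in <- 0L; s_in <- 0L
  } else {
    n_inside <- round(cfg$target_mdi * n)
    p_in <- round(n_inside * (n_pair_nuclei / max(n, 1)) / 2)
    s_in <- n_inside - 2L * p_in
    if (s_in > n_singles) {
      p_in <- ceiling((n_inside - n_singles) / 2)
      s_in <- n_inside - 2L * p_in
    }
    if (p_in > n_pairs) {
      p_in <- n_pairs
      s_in <- min(n_inside - 2L * p_in, n_singles)
    }
    if (s_in < 0) {
      p_in <- min(n_pairs, n_inside %/% 2L)
      s_in <- min(n_inside - 2L * p_in, n_singles)
    }
  }
  list(n_pairs = as.integer(n_pairs), n_singles = as.integer(n_singles),
       pairs_inside = as.integer(p_in), singles_inside = as.integer(s_in))
}

sample_nucleus_shape <- function(cfg) {
  r <- max(2, rnorm(1, cfg$nucleus_radius_mean_px, cfg$nucleus_radius_sd_px))
  e <- runif(1, 0, cfg$nucleus_eccentricity_max)
  f <- (1 - e^2)^0.25
  list(a = r / f, b = r * f, theta = runif(1, 0, pi))
}

#' Generate a synthetic two-channel micrograph with exact ground truth
#'
#' Renders elliptical nuclei (DAPI channel) and capsule-shaped myotube
#' footprints (MF20 channel), convolves both channels with a Gaussian PSF,
#' adds a flat background plus Gaussian noise and clips to 16-bit. The
#' returned ground truth records every nucleus (geometry and the id of the
#' containing myotube, 0 = outside) and every myotube footprint. The
#' realized inside fraction equals `round(target_mdi * n_nuclei) / n_nuclei`
#' whenever that many placements are feasible; the realized value is always
#' reported in the truth. Object placement uses rejection sampling with a
#' bounded retry budget and fails with an explicit error naming the violated
#' constraint. Equal configurations (including the seed) reproduce
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `image` (a [micrograph()], channel 1 =
#'   nuclei, channel 2 = myotubes) and `truth` (class `ground_truth`: a
#'   `nuclei` data frame with `id`, `center_row`, `center_col`,
#'   `semi_major`, `semi_minor`, `angle`, `inside_myotube_id`; a `myotubes`
#'   list with per-tube `id`, `footprint`, `intended_nucleus_count`; and
#'   `realized_mdi`).
#' @export
generate_image <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  h <- cfg$height_px; w <- cfg$width_px

  tubes <- place_myotubes(cfg)
  tube_union <- if (cfg$n_myotubes > 0) Reduce(`|`, tubes$masks)
                else matrix(FALSE, h, w)
  dist_to_tube <- if (any(tube_union)) cpp_edt(!tube_union)
                  else matrix(Inf, h, w)

  plan <- plan_membership(cfg)
  n <- cfg$n_nuclei

  # unit list: pairs first, then singles; inside units first within each
  units <- list()
  if (n > 0) {
    pair_flags <- c(rep(TRUE, plan$pairs_inside),
                    rep(FALSE, plan$n_pairs - plan$pairs_inside))
    single_flags <- c(rep(TRUE, plan$singles_inside),
                      rep(FALSE, plan$n_singles - plan$singles_inside))
    units <- c(lapply(pair_flags, function(f) list(size = 2L, inside = f)),
               lapply(single_flags, function(f) list(size = 1L, inside = f)))
  }

  # tube slots for inside nuclei
  slot_pool <- if (!is.null(cfg$multinucleation_profile)) {
    rep(seq_len(cfg$n_myotubes), cfg$multinucleation_profile)
  } else NULL

  out_margin <- 6  # px clearance of outside nucleus centers from footprints

  sample_inside_center <- function(tube_id, clearance) {
    ax <- tubes$axes[[tube_id]]
    band <- max(0.5, tubes$half_w - clearance)
    t <- runif(1)
    u <- runif(1, -band, band)
    dir <- (ax$q - ax$p)
    len <- sqrt(sum(dir^2))
    dirn <- if (len > 0) dir / len else c(1, 0)
    nrm <- c(-dirn[2], dirn[1])
    ax$p + t * (ax$q - ax$p) + u * nrm
  }

  place_all_nuclei <- function() {
  nuc <- data.frame(id = integer(0), center_row = numeric(0),
                    center_col = numeric(0), semi_major = numeric(0),
                    semi_minor = numeric(0), angle = numeric(0),
                    inside_myotube_id = integer(0))
  placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
  slot_used <- 0L
  next_id <- 1L
  for (u in units) {
    shp1 <- sample_nucleus_shape(cfg)
    shp2 <- if (u$size == 2L) sample_nucleus_shape(cfg) else NULL
    if (u$size == 2L) shp2$theta <- shp1$theta  # co-oriented pair
    pair_gap <- 0.6
    placed <- FALSE
    tube_id <- 0L
    for (try in seq_len(MAX_PLACEMENT_TRIES)) {
      if (u$inside) {
        tube_id <- if (!is.null(slot_pool)) slot_pool[slot_used + 1L]
                   else sample.int(cfg$n_myotubes, 1L)
        ctr1 <- sample_inside_center(tube_id, shp1$b + 1)
      } else {
        m1 <- shp1$a + 1
        ctr1 <- c(runif(1, m1, h - m1), runif(1, m1, w - m1))
        pr <- min(max(round(ctr1[1]), 1L), h)
        pc <- min(max(round(ctr1[2]), 1L), w)
        if (dist_to_tube[pr, pc] < out_margin) next
      }
      if (ctr1[1] < 2 || ctr1[1] > h - 1 || ctr1[2] < 2 || ctr1[2] > w - 1) next
      centers <- list(ctr1)
      radii <- shp1$a
      if (u$size == 2L) {
        dirp <- c(cos(shp1$theta), sin(shp1$theta))
        ctr2 <- ctr1 + (shp1$a + shp2$a + pair_gap) * dirp
        if (ctr2[1] < 2 || ctr2[1] > h - 1 || ctr2[2] < 2 || ctr2[2] > w - 1) next
        if (u$inside) {
          ax <- tubes$axes[[tube_id]]
          if (point_seg_dist(ctr2[1], ctr2[2], ax$p, ax$q) >
              tubes$half_w - 1) next
        } else {
          pr <- min(max(round(ctr2[1]), 1L), h)
          pc <- min(max(round(ctr2[2]), 1L), w)
          if (dist_to_tube[pr, pc] < out_margin) next
        }
        centers <- list(ctr1, ctr2)
        radii <- c(shp1$a, shp2$a)
      }
      ok <- TRUE
      for (k in seq_along(centers)) {
        if (length(placed_r) &&
            any((placed_r - centers[[k]][1])^2 + (placed_c - centers[[k]][2])^2 <
                (placed_rad + radii[k] + 2)^2)) { ok <- FALSE; break }
      }
      if (!ok) next
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)   # jammed: caller restarts the whole stage
    shapes <- if (u$size == 2L) list(shp1, shp2) else list(shp1)
    for (k in seq_along(centers)) {
      nuc <- rbind(nuc, data.frame(
        id = next_id,
        center_row = centers[[k]][1], center_col = centers[[k]][2],
        semi_major = shapes[[k]]$a, semi_minor = shapes[[k]]$b,
        angle = shapes[[k]]$theta,
        inside_myotube_id = if (u$inside) tube_id else 0L))
      next_id <- next_id + 1L
      placed_r <- c(placed_r, centers[[k]][1])
      placed_c <- c(placed_c, centers[[k]][2])
      placed_rad <- c(placed_rad, shapes[[k]]$a)
    }
    if (u$inside && !is.null(slot_pool)) slot_used <- slot_used + u$size
  }
  nuc
  }

  # sequential random parking can jam in dense scenes; restart the whole
  # nucleus stage (fresh geometry draws) a bounded number of times
  nuc <- NULL
  for (restart in 1:10) {
    nuc <- place_all_nuclei()
    if (!is.null(nuc)) break
  }
  if (is.null(nuc)) {
    stop(sprintf(paste0("nucleus placement infeasible: could not place %d ",
                        "nuclei (target inside fraction %.2f) without ",
                        "overlap in a %d x %d canvas after %d retries per ",
                        "nucleus and 10 stage restarts"),
                 n, cfg$target_mdi, h, w, MAX_PLACEMENT_TRIES),
         call. = FALSE)
  }

  # render channels
  nuc_raw <- matrix(0, h, w)
  for (i in seq_len(nrow(nuc))) {
    nuc_raw <- draw_ellipse(nuc_raw, nuc$center_row[i], nuc$center_col[i],
                            nuc$semi_major[i], nuc$semi_minor[i],
                            nuc$angle[i], cfg$nucleus_intensity)
  }
  tube_raw <- matrix(0, h, w)
  tube_raw[tube_union] <- cfg$myotube_intensity

  finish <- function(raw) {
    img <- gaussian_blur(raw, cfg$psf_sigma_px)
    img <- img + cfg$background_level
    if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
    matrix(round(pmin(pmax(img, 0), 65535)), h, w)
  }
  ch_nuc <- finish(nuc_raw)
  ch_tube <- finish(tube_raw)

  counts <- tabulate(nuc$inside_myotube_id[nuc$inside_myotube_id > 0L],
                     nbins = cfg$n_myotubes)
  truth <- structure(list(
    nuclei = nuc,
    myotubes = lapply(seq_len(cfg$n_myotubes), function(i)
      list(id = i, footprint = tubes$masks[[i]],
           intended_nucleus_count = counts[i])),
    realized_mdi = if (n > 0) sum(nuc$inside_myotube_id > 0L) / n else 0
  ), class = "ground_truth")

  list(image = micrograph(list(ch_nuc, ch_tube),
                          c(nuclei = 1L, myotubes = 2L)),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei (%d inside), %d myotubes, realized MDI = %.3f\n",
              nrow(x$nuclei), sum(x$nuclei$inside_myotube_id > 0L),
              length(x$myotubes), x$realized_mdi))
  invisible(x)
}

#' Reference indices computed directly from ground truth
#'
#' Computes N, MDI, MFI and the per-myotube nucleus-count histogram straight
#' from the membership flags of a [generate_image()] ground truth, using the
#' same formulas as [compute_indices()]. Serves as the recovery oracle for
#' the segmentation-based pipeline.
#'
#' @param truth a `ground_truth` object.
#' @param mfi_min_nuclei minimum nuclei per myotube for the fusion index.
#' @param histogram_bins lower bin edges for the nucleus-count histogram.
#' @return an object of class `quant_result`.
#' @export
ground_truth_indices <- function(truth, mfi_min_nuclei = 2L,
                                 histogram_bins = c(1L, 2L, 5L)) {
  stopifnot(inherits(truth, "ground_truth"), mfi_min_nuclei >= 2L)
  ids <- truth$nuclei$inside_myotube_id
  n_total <- nrow(truth$nuclei)
  n_inside <- sum(ids > 0L)
  counts <- if (length(truth$myotubes))
    tabulate(ids[ids > 0L], nbins = length(truth$myotubes)) else integer(0)
  mfi_num <- sum(counts[counts >= mfi_min_nuclei])
  new_quant_result(n_total, n_inside, mfi_num,
                   bin_histogram(counts, as.integer(histogram_bins)),
                   length(truth$myotubes), NULL,
                   degenerate = n_total == 0L)
}
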