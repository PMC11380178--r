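# Raster primitives: the building blocks of the segmentation macro.
# All operators are pure functions on plain R matrices; binary masks are
# logical matrices, label maps are integer matrices with 0 = background and
# contiguous labels 1..K. Coordinates are 1-based (row, col).

as_mask <- function(x) {
  if (is.logical(x)) {
    m <- x
  } else if (is.numeric(x)) {
    m <- x > 0
  } else {
    stop("mask must be a logical or numeric matrix", call. = FALSE)
  }
  if (!is.matrix(m)) stop("mask must be a matrix", call. = FALSE)
  storage.mode(m) <- "logical"
  m
}

#' Gaussian blur of a single-channel raster
#'
#' Separable convolution with a normalized Gaussian kernel, truncated at
#' `ceiling(3 * sigma)` and renormalized, with edge replication at the
#' borders (so a constant image is a fixed point and total intensity of an
#' interior impulse is conserved). `sigma = 0` returns the input unchanged.
#'
#' @param image numeric matrix of intensities.
#' @param sigma standard deviation of the Gaussian kernel, in pixels.
#' @return numeric matrix of the same shape.
#' @examples
#' m <- matrix(0, 11, 11); m[6, 6] <- 1
#' sum(gaussian_blur(m, 1))  # ~1: mass conserved
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative number", call. = FALSE)
  }
  if (sigma == 0) return(image)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  h <- nrow(image); w <- ncol(image)
  # rows (vertical pass), replicate padding
  p <- image[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out <- out + k[i] * p[seq.int(i, i + h - 1L), , drop = FALSE]
  }
  # columns (horizontal pass)
  p <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out <- out + k[i] * p[, seq.int(i, i + w - 1L), drop = FALSE]
  }
  out
}

#' Otsu threshold of a single-channel raster
#'
#' Bins the observed intensity range into `n_bins` equal-width bins and
#' selects the cut maximizing the between-class variance; ties are broken
#' toward the smallest qualifying cut. The foreground mask is all pixels
#' strictly above the threshold. A constant image yields an empty foreground
#' with `degenerate = TRUE` (no error).
#'
#' @param image numeric matrix of finite intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return an object of class `threshold_result`: a list with `threshold`
#'   (intensity units), `mask` (logical matrix, `image > threshold`),
#'   `degenerate` (flag for constant input), and `effectiveness` (the
#'   maximized between-class variance divided by the total variance, in
#'   \\[0, 1\\]; low values indicate the histogram is essentially unimodal).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)
  lo <- min(image); hi <- max(image)
  if (lo == hi) {
    return(structure(list(threshold = hi,
                          mask = matrix(FALSE, nrow(image), ncol(image)),
                          degenerate = TRUE, effectiveness = 0),
                     class = "threshold_result"))
  }
  n_bins <- as.integer(n_bins)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(image, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- as.numeric(tabulate(bin, nbins = n_bins))
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  total <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * centers)
  mt <- m0[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  w0t <- w0[t_idx]; w1t <- total - w0t
  sb <- (mt * w0t - m0[t_idx] * total)^2 / (w0t * w1t) / total^2
  sb[!is.finite(sb)] <- -Inf
  best <- which.max(sb)                      # first max = smallest cut
  thr <- breaks[best + 1L]
  mu <- mt / total
  tot_var <- sum(counts * (centers - mu)^2) / total
  structure(list(threshold = thr,
                 mask = image > thr,
                 degenerate = FALSE,
                 effectiveness = if (tot_var > 0) sb[best] / tot_var else 0),
            class = "threshold_result")
}

#' Despeckle (3x3 median filter)
#'
#' Replaces each pixel by the median of its 3x3 neighborhood, with edge
#' replication at the raster borders. Removes isolated noise pixels; applied
#' to the thresholded myotube mask in the segmentation chain. Logical input
#' yields logical output.
#'
#' @param mask_or_image logical or numeric matrix.
#' @return filtered matrix of the same type and shape.
#' @export
despeckle <- function(mask_or_image) {
  if (is.logical(mask_or_image)) {
    m <- mask_or_image
    storage.mode(m) <- "double"
    return(cpp_median3x3(m) > 0.5)
  }
  if (!is.matrix(mask_or_image) || !is.numeric(mask_or_image)) {
    stop("input must be a logical or numeric matrix", call. = FALSE)
  }
  cpp_median3x3(mask_or_image)
}

dilate3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(FALSE, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out | p[seq.int(1L + dr, h + dr), seq.int(1L + dc, w + dc)]
  }
  out
}

erode3x3 <- function(m) {
  # dual of dilation: pixels outside the raster count as foreground, so
  # erode(m) == !dilate(!m) exactly on a 1-px-padded domain
  h <- nrow(m); w <- ncol(m)
  p <- matrix(TRUE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(TRUE, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out & p[seq.int(1L + dr, h + dr), seq.int(1L + dc, w + dc)]
  }
  out
}

check_iterations <- function(iterations) {
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      is.na(iterations) || iterations < 0) {
    stop("iterations must be a single non-negative integer", call. = FALSE)
  }
  as.integer(iterations)
}

#' Binary dilation / erosion with a 3x3 square structuring element
#'
#' Iterated Minkowski dilation (or erosion), one pass of the 3x3 square
#' element per iteration; `iterations = 0` is the identity. Erosion is the
#' exact dual of dilation (`erode(m) == !dilate(!m)` on a 1-px-padded
#' domain): pixels beyond the raster count as background for dilation and as
#' foreground for erosion.
#'
#' @param mask logical matrix (numeric input is taken as `> 0`).
#' @param iterations non-negative number of passes.
#' @return logical matrix of the same shape.
#' @export
binary_dilate <- function(mask, iterations = 1L) {
  m <- as_mask(mask)
  iterations <- check_iterations(iterations)
  for (i in seq_len(iterations)) m <- dilate3x3(m)
  m
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, iterations = 1L) {
  m <- as_mask(mask)
  iterations <- check_iterations(iterations)
  for (i in seq_len(iterations)) m <- erode3x3(m)
  m
}

#' Binary closing (one dilation followed by one erosion)
#'
#' Bridges gaps narrower than the 3x3 structuring element; idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
binary_close <- function(mask) {
  erode3x3(dilate3x3(as_mask(mask)))
}

#' Fill holes in a binary mask
#'
#' Background regions not 4-connected to the raster border become
#' foreground. Foreground pixels are never removed; the operation is
#' idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
fill_holes <- function(mask) {
  cpp_fill_holes(as_mask(mask))
}

# Seeds for the distance-transform watershed. Regional maxima of the
# distance map are first consolidated with an h-maxima transform (grayscale
# reconstruction of dist - h under dist, h = 1 px), so maxima separated by
# dips shallower than 1 px -- e.g. the discretization ripple along the
# ridge of an elongated object -- merge into one plateau. Each plateau is
# reduced to the pixel nearest its centroid, then a greedy pass keeps, in
# decreasing order of distance value, only seeds at Euclidean distance
# >= min_separation from every already-kept seed.
find_watershed_seeds <- function(dist, min_separation, h_merge = 1.0) {
  h <- nrow(dist); w <- ncol(dist)
  seedmap <- matrix(0L, h, w)
  hmax <- cpp_reconstruct(pmax(dist - h_merge, 0), dist)
  # regional maxima of the h-maxima transform, again by reconstruction:
  # eps below the smallest spacing of distinct EDT values in range
  eps <- 0.005
  cand <- (hmax - cpp_reconstruct(hmax - eps, hmax)) > eps / 2 & dist > 0
  if (!any(cand)) return(seedmap)
  plat <- cpp_label(cand, 8L)
  comp <- cpp_label(dist > 0, 8L)
  idx <- which(cand)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  groups <- split(seq_along(idx), plat[idx])
  reps <- vapply(groups, function(g) {
    cr <- mean(rows[g]); cc <- mean(cols[g])
    g[which.min((rows[g] - cr)^2 + (cols[g] - cc)^2)]
  }, integer(1))
  sr <- rows[reps]; sc <- cols[reps]
  sv <- dist[cbind(sr, sc)]
  scomp <- comp[cbind(sr, sc)]
  o <- order(-sv, sr, sc)                  # deterministic tie order
  sr <- sr[o]; sc <- sc[o]; scomp <- scomp[o]
  keep_r <- numeric(0); keep_c <- numeric(0); keep_comp <- integer(0)
  for (i in seq_along(sr)) {
    # a seed is suppressed only by a kept seed of the same mask component;
    # every connected object keeps at least one seed
    same <- keep_comp == scomp[i]
    if (!any(same) ||
        all((keep_r[same] - sr[i])^2 + (keep_c[same] - sc[i])^2 >=
            min_separation^2)) {
      keep_r <- c(keep_r, sr[i]); keep_c <- c(keep_c, sc[i])
      keep_comp <- c(keep_comp, scomp[i])
    }
  }
  seedmap[cbind(keep_r, keep_c)] <- seq_along(keep_r)
  seedmap
}

# Euclidean distance transform with pixels beyond the raster counting as
# background (reference desktop-tool semantics), via a 1-px background pad.
edt_mask <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  cpp_edt(p)[2:(h + 1L), 2:(w + 1L)]
}

# Relabel a label map so labels are contiguous 1..K in row-major raster
# order of each label's first pixel.
relabel_contiguous <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  h <- nrow(lab)
  rank <- (((idx - 1L) %% h)) * ncol(lab) + ((idx - 1L) %/% h)  # row-major rank
  labs <- lab[idx]
  firsts <- tapply(rank, labs, min)
  ord <- order(firsts)
  map <- integer(max(labs))
  map[as.integer(names(firsts))[ord]] <- seq_along(ord)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[idx] <- map[labs]
  out
}

#' Split touching objects with a distance-transform watershed
#'
#' Computes the exact Euclidean distance transform of the mask, takes the
#' regional maxima of the distance map as seeds (plateaus merged; seeds
#' closer than `min_seed_separation` suppressed, keeping the deeper one),
#' and floods the mask from the seeds in order of decreasing distance.
#' Pixels where two basins meet become 1-px watershed lines assigned to
#' background, so split objects are disconnected in the result. An object
#' with a single surviving seed keeps a single label.
#'
#' @param mask logical matrix.
#' @param min_seed_separation minimum Euclidean distance between seeds, in
#'   pixels; a sensible default is the expected object radius.
#' @return integer label map (0 = background, labels contiguous 1..K).
#' @export
watershed_split <- function(mask, min_seed_separation) {
  m <- as_mask(mask)
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  d <- edt_mask(m)
  seeds <- find_watershed_seeds(d, min_seed_separation)
  lab <- cpp_watershed(d, seeds, m)
  relabel_contiguous(lab)
}

#' Connected-component labeling with size filtering (particle analysis)
#'
#' Labels connected foreground components under 4- or 8-connectivity,
#' removes components whose pixel area falls outside
#' `[min_area_px, max_area_px]`, and re-indexes the survivors contiguously
#' from 1 in raster-scan order of each component's first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @param min_area_px,max_area_px inclusive area bounds in pixels squared.
#' @return integer label map.
#' @export
label_particles <- function(mask, connectivity = 8L, min_area_px = 0,
                            max_area_px = Inf) {
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  if (min_area_px > max_area_px) {
    stop("min_area_px must not exceed max_area_px", call. = FALSE)
  }
  lab <- cpp_label(as_mask(mask), as.integer(connectivity))
  filter_labels(lab, min_area_px, max_area_px)
}

# Remove labels with areas outside [min_area, max_area]; relabel contiguously.
filter_labels <- function(lab, min_area, max_area = Inf) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area | areas > max_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_contiguous(lab)
}

#' Number of labels in a label map
#' @param lab integer label map.
#' @return integer count of distinct positive labels.
#' @export
n_labels <- function(lab) {
  if (length(lab) == 0L) return(0L)
  as.integer(max(lab, 0L))
}
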