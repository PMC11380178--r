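# Brute-force reference implementations used as independent oracles.
# Deliberately naive: per-pixel loops over explicit definitions, no shared
# code with the package internals.

oracle_dilate <- function(m, iterations = 1L) {
  # set definition: union of the 3x3 structuring element stamped on every
  # foreground pixel (outside the raster = background)
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (m[r, c]) {
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) out[rr, cc] <- TRUE
        }
      }
    }
    m <- out
  }
  m
}

oracle_erode <- function(m, iterations = 1L) {
  # pixel survives iff every structuring-element position inside the raster
  # is foreground (outside the raster counts as foreground)
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- matrix(TRUE, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      keep <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && !m[rr, cc]) keep <- FALSE
      }
      out[r, c] <- keep
    }
    m <- out
  }
  m
}

oracle_median3x3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (r in seq_len(h)) for (c in seq_len(w)) {
    v <- numeric(9); k <- 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r + dr, 1), h)   # edge replication
      cc <- min(max(c + dc, 1), w)
      v[k] <- img[rr, cc]; k <- k + 1
    }
    out[r, c] <- sort(v)[5]
  }
  out
}

oracle_fill_holes <- function(m) {
  # breadth-first flood of background from the border, 4-connectivity
  h <- nrow(m); w <- ncol(m)
  reach <- matrix(FALSE, h, w)
  queue <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if ((r == 1 || r == h || c == 1 || c == w) && !m[r, c] && !reach[r, c]) {
      reach[r, c] <- TRUE
      queue[[length(queue) + 1]] <- c(r, c)
    }
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- p[1] + d[1]; cc <- p[2] + d[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          !m[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
  }
  m | !reach
}

oracle_label <- function(m, connectivity = 8L) {
  # union-find connected-component labeling
  h <- nrow(m); w <- ncol(m)
  parent <- seq_len(h * w)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  offs <- list(c(-1, 0), c(0, -1))
  if (connectivity == 8L) offs <- c(offs, list(c(-1, -1), c(-1, 1)))
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (!m[r, c]) next
    for (d in offs) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && m[rr, cc]) {
        union_((c - 1) * h + r, (cc - 1) * h + rr)
      }
    }
  }
  lab <- matrix(0L, h, w)
  roots <- integer(0)
  # assign labels in row-major order of first pixel
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    root <- find((c - 1) * h + r)
    k <- match(root, roots)
    if (is.na(k)) {
      roots <- c(roots, root)
      k <- length(roots)
    }
    lab[r, c] <- k
  }
  lab
}

oracle_otsu <- function(image, n_bins = 256L) {
  # exhaustive scan of all bin cut-points, maximizing between-class variance
  lo <- min(image); hi <- max(image)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(image, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- as.numeric(tabulate(bin, nbins = n_bins))
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best_sb <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1)) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts[(t + 1):n_bins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:t] * centers[1:t]) / w0
    mu1 <- sum(counts[(t + 1):n_bins] * centers[(t + 1):n_bins]) / w1
    sb <- (w0 / (w0 + w1)) * (w1 / (w0 + w1)) * (mu0 - mu1)^2
    if (sb > best_sb + 1e-12) {   # strict improvement: ties keep smallest t
      best_sb <- sb; best_t <- t
    }
  }
  breaks[best_t + 1]
}

oracle_pooled_t <- function(a, b) {
  # textbook pooled-variance two-sample t statistic and two-sided p
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = na + nb - 2))
}

# ---- fixture builders -------------------------------------------------------

mk_disc <- function(h, w, r0, c0, rad) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}

mk_ellipse_mask <- function(h, w, r0, c0, a, b, theta) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- (rr - r0) * cos(theta) + (cc - c0) * sin(theta)
  v <- -(rr - r0) * sin(theta) + (cc - c0) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

mk_capsule <- function(h, w, p, q, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  vr <- q[1] - p[1]; vc <- q[2] - p[2]
  l2 <- vr^2 + vc^2
  t <- if (l2 == 0) matrix(0, h, w)
       else pmin(pmax(((rr - p[1]) * vr + (cc - p[2]) * vc) / l2, 0), 1)
  (rr - (p[1] + t * vr))^2 + (cc - (p[2] + t * vc))^2 <= radius^2
}

random_mask <- function(h, w, p = 0.4) {
  matrix(runif(h * w) < p, h, w)
}

# micrograph with given raw object masks rendered at fixed intensities
mk_micrograph <- function(nuc_mask, tube_mask, background = 1000,
                          nuc_int = 20000, tube_int = 15000) {
  micrograph(list(matrix(background + nuc_int * nuc_mask, nrow(nuc_mask)),
                  matrix(background + tube_int * tube_mask, nrow(tube_mask))))
}
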