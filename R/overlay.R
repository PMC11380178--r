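# QC overlay: composite of the two fluorescence channels with object
# outlines and per-myotube nucleus counts burned in, for manual validation
# of segmentation quality.

# union of per-label morphological gradients: dilate(support) minus support,
# evaluated per label on a padded bounding box
label_outlines <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  out <- matrix(FALSE, h, w)
  k <- n_labels(lab)
  if (k == 0L) return(out)
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  labs <- lab[idx]
  for (g in split(seq_along(idx), labs)) {
    r0 <- max(1L, min(rows[g]) - 1L); r1 <- min(h, max(rows[g]) + 1L)
    c0 <- max(1L, min(cols[g]) - 1L); c1 <- min(w, max(cols[g]) + 1L)
    sup <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sup[cbind(rows[g] - r0 + 1L, cols[g] - c0 + 1L)] <- TRUE
    grad <- dilate3x3(sup) & !sup
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] | grad
  }
  out
}

# 3 x 5 bitmap digit font for burned-in counts
.digit_font <- lapply(list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111")
), function(rows) {
  do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]]) == 1L))
})

burn_number <- function(rgb, number, row, col) {
  digits <- strsplit(as.character(number), "")[[1]]
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  col0 <- round(col) - 2L * length(digits)
  row0 <- round(row) - 2L
  for (d in digits) {
    glyph <- .digit_font[[d]]
    if (!is.null(glyph)) {
      for (gr in 1:5) for (gc in 1:3) {
        if (glyph[gr, gc]) {
          r <- row0 + gr - 1L; c <- col0 + gc - 1L
          if (r >= 1L && r <= h && c >= 1L && c <= w) rgb[r, c, ] <- 1
        }
      }
    }
    col0 <- col0 + 4L
  }
  rgb
}

#' Render a QC overlay of segmentation results
#'
#' Composites the myotube channel (red) and nuclear channel (blue) on a
#' fixed 16-bit scale, draws myotube ROI outlines in green and nucleus
#' outlines in white (each outline is exactly the morphological gradient,
#' dilation minus support, of the label), and burns the per-myotube nucleus
#' count at each myotube centroid. Rendering is deterministic.
#'
#' @param image a [micrograph()].
#' @param nuclei,myotubes integer label maps matching the image shape.
#' @param records optional nucleus records from [assign_nuclei()]; when
#'   given, per-myotube counts are derived from them and burned in.
#' @return a height x width x 3 RGB array in \\[0, 1\\], class
#'   `overlay_image`.
#' @export
render_overlay <- function(image, nuclei, myotubes, records = NULL) {
  nuc_ch <- get_channel(image, "nuclei")
  tub_ch <- get_channel(image, "myotubes")
  if (!all(dim(nuclei) == dim(nuc_ch)) || !all(dim(myotubes) == dim(nuc_ch))) {
    stop("label maps must match the image shape", call. = FALSE)
  }
  h <- nrow(nuc_ch); w <- ncol(nuc_ch)
  rgb <- array(0, c(h, w, 3))
  rgb[, , 1] <- pmin(tub_ch / 65535, 1)
  rgb[, , 3] <- pmin(nuc_ch / 65535, 1)
  tub_out <- label_outlines(myotubes)
  nuc_out <- label_outlines(nuclei)
  g <- rgb[, , 2]; g[tub_out] <- 1; rgb[, , 2] <- g
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[nuc_out] <- 1
    rgb[, , ch] <- plane
  }
  if (!is.null(records) && n_labels(myotubes) > 0L) {
    counts <- tabulate(records$myotube_id[records$myotube_id > 0L],
                       nbins = n_labels(myotubes))
    idx <- which(myotubes > 0L)
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    labs <- myotubes[idx]
    area <- tabulate(labs)
    cr <- rowsum(as.numeric(rows), labs)[, 1] / area
    cc <- rowsum(as.numeric(cols), labs)[, 1] / area
    for (k in seq_along(counts)) {
      rgb <- burn_number(rgb, counts[k], cr[k], cc[k])
    }
  }
  structure(rgb, class = "overlay_image")
}

#' Write an overlay image as PNG
#'
#' @param overlay an `overlay_image` from [render_overlay()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  png::writePNG(unclass(overlay), path)
  invisible(path)
}
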