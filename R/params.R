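#' Pipeline parameters for segmentation and quantification
#'
#' Collects every tunable knob of the analysis chain. Defaults follow the
#' published operator chain where it is explicit (blur sigma of 1 px, 4
#' dilations, 3 erosions) and are calibrated for 512 x 512 micrographs with
#' nuclei of ~8 px radius elsewhere; all values are echoed into every output
#' for provenance.
#'
#' @param blur_sigma_px Gaussian blur sigma applied to both channels, pixels.
#' @param nucleus_connectivity pixel connectivity for nucleus particle
#'   analysis, 4 or 8.
#' @param nucleus_min_area_px,nucleus_max_area_px accepted nucleus area
#'   range, pixels squared.
#' @param nucleus_seed_separation_px minimum separation of watershed seeds
#'   in the nuclear channel; set near the expected nucleus radius.
#' @param myotube_dilate_iters,myotube_erode_iters binary dilation/erosion
#'   passes applied to the thresholded myotube mask. The published chain is
#'   asymmetric (4 dilations, 3 erosions) and that net growth is preserved.
#' @param myotube_min_area_px minimum myotube ROI area, pixels squared.
#' @param myotube_seed_separation_px minimum separation of watershed seeds
#'   for splitting touching myotubes, pixels.
#' @param mfi_min_nuclei minimum nuclei per MF20-positive object for its
#'   nuclei to count as fused (myogenic fusion index); must be >= 2.
#' @param histogram_bins increasing lower bin edges for the per-myotube
#'   nucleus-count histogram; `c(1, 2, 5)` yields bins 1 (mononucleated,
#'   reported as reference), 2-4, and >= 5.
#' @param min_threshold_effectiveness guard against thresholding a channel
#'   with no real signal: if the Otsu between-class variance explains less
#'   than this fraction of the total variance (an essentially unimodal
#'   histogram, e.g. pure noise), segmentation returns an empty label map.
#' @return an object of class `pipeline_params`.
#' @export
pipeline_params <- function(blur_sigma_px = 1.0,
                            nucleus_connectivity = 8L,
                            nucleus_min_area_px = 40,
                            nucleus_max_area_px = Inf,
                            nucleus_seed_separation_px = 8,
                            myotube_dilate_iters = 4L,
                            myotube_erode_iters = 3L,
                            myotube_min_area_px = 500,
                            myotube_seed_separation_px = 50,
                            mfi_min_nuclei = 2L,
                            histogram_bins = c(1L, 2L, 5L),
                            min_threshold_effectiveness = 0.75) {
  p <- list(blur_sigma_px = blur_sigma_px,
            nucleus_connectivity = as.integer(nucleus_connectivity),
            nucleus_min_area_px = nucleus_min_area_px,
            nucleus_max_area_px = nucleus_max_area_px,
            nucleus_seed_separation_px = nucleus_seed_separation_px,
            myotube_dilate_iters = as.integer(myotube_dilate_iters),
            myotube_erode_iters = as.integer(myotube_erode_iters),
            myotube_min_area_px = myotube_min_area_px,
            myotube_seed_separation_px = myotube_seed_separation_px,
            mfi_min_nuclei = as.integer(mfi_min_nuclei),
            histogram_bins = as.integer(histogram_bins),
            min_threshold_effectiveness = min_threshold_effectiveness)
  stopifnot(p$blur_sigma_px >= 0,
            p$nucleus_connectivity %in% c(4L, 8L),
            p$nucleus_min_area_px > 0,
            p$nucleus_max_area_px >= p$nucleus_min_area_px,
            p$nucleus_seed_separation_px > 0,
            p$myotube_dilate_iters >= 0L,
            p$myotube_erode_iters >= 0L,
            p$myotube_min_area_px > 0,
            p$myotube_seed_separation_px > 0,
            p$mfi_min_nuclei >= 2L,
            length(p$histogram_bins) >= 1L,
            !is.unsorted(p$histogram_bins, strictly = TRUE),
            p$histogram_bins[1] >= 1L,
            p$min_threshold_effectiveness >= 0,
            p$min_threshold_effectiveness <= 1)
  structure(p, class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
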