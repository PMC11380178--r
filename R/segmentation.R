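# The two macro pipelines: nucleus segmentation from the DAPI channel and
# myotube ROI construction from the MF20 channel.

threshold_channel <- function(channel, params) {
  blurred <- gaussian_blur(channel, params$blur_sigma_px)
  th <- otsu_threshold(blurred)
  if (th$degenerate || th$effectiveness < params$min_threshold_effectiveness) {
    # essentially unimodal histogram: nothing above background to segment
    th$mask[] <- FALSE
  }
  th
}

#' Segment nuclei from the DAPI channel
#'
#' Pipeline: Gaussian blur (sigma `blur_sigma_px`) -> Otsu threshold ->
#' distance-transform watershed (splitting touching nuclei) -> per-label
#' size filter `[nucleus_min_area_px, nucleus_max_area_px]`. Watershed runs
#' before the size filter so split fragments are size-checked individually.
#'
#' @param image a [micrograph()] with a `nuclei` channel role.
#' @param params a [pipeline_params()] object.
#' @return integer label map of accepted nuclei (contiguous labels 1..K).
#' @export
segment_nuclei <- function(image, params = pipeline_params()) {
  th <- threshold_channel(get_channel(image, "nuclei"), params)
  lab <- watershed_split(th$mask, params$nucleus_seed_separation_px)
  filter_labels(lab, params$nucleus_min_area_px, params$nucleus_max_area_px)
}

#' Segment myotube regions of interest from the MF20 channel
#'
#' Pipeline: Gaussian blur -> Otsu threshold -> despeckle -> binary dilation
#' (`myotube_dilate_iters` passes) -> closing -> hole filling -> binary
#' erosion (`myotube_erode_iters` passes) -> distance-transform watershed
#' (splitting touching myotubes) -> minimum-area filter. The asymmetric
#' dilate/erode counts (defaults 4 and 3) leave a net one-pass growth that
#' consolidates ragged staining into solid ROIs.
#'
#' @inheritParams segment_nuclei
#' @return integer label map of myotube ROIs.
#' @export
segment_myotubes <- function(image, params = pipeline_params()) {
  th <- threshold_channel(get_channel(image, "myotubes"), params)
  m <- despeckle(th$mask)
  m <- binary_dilate(m, params$myotube_dilate_iters)
  m <- binary_close(m)
  m <- fill_holes(m)
  m <- binary_erode(m, params$myotube_erode_iters)
  lab <- watershed_split(m, params$myotube_seed_separation_px)
  filter_labels(lab, params$myotube_min_area_px)
}
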