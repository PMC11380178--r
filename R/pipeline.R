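# Batch orchestration: per-image quantification, output writing, group
# statistics, configuration files and ground-truth serialization.

#' Quantify a single micrograph
#'
#' Runs the full per-image analysis: nucleus segmentation, myotube ROI
#' construction, nucleus-to-ROI assignment and index computation.
#'
#' @param image a [micrograph()].
#' @param params a [pipeline_params()].
#' @return a list with `result` (a `quant_result`), `nucleus_records`,
#'   `myotube_records`, `nuclei_labels`, `myotube_labels`.
#' @export
quantify_image <- function(image, params = pipeline_params()) {
  nuclei <- segment_nuclei(image, params)
  myotubes <- segment_myotubes(image, params)
  records <- assign_nuclei(nuclei, myotubes)
  tubes <- measure_myotubes(myotubes, records)
  res <- compute_indices(records, tubes, params)
  stopifnot(res$n_inside + res$n_outside == res$n_total)  # conservation
  list(result = res, nucleus_records = records, myotube_records = tubes,
       nuclei_labels = nuclei, myotube_labels = myotubes)
}

#' Batch run configuration
#'
#' @param input_paths character vector of TIFF paths, or a single directory
#'   (all `.tif`/`.tiff` files inside, sorted).
#' @param channel_roles named vector mapping `nuclei` and `myotubes` to
#'   channel indices.
#' @param group_labels optional named character vector mapping image ids
#'   (file stems) to condition labels.
#' @param params a [pipeline_params()].
#' @param output_dir directory for outputs; created if missing.
#' @param overlay write a QC overlay PNG per image.
#' @param strict stop on the first failed image instead of skipping it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_paths, channel_roles = c(nuclei = 1L, myotubes = 2L),
                       group_labels = NULL, params = pipeline_params(),
                       output_dir, overlay = FALSE, strict = FALSE) {
  if (length(input_paths) == 1L && dir.exists(input_paths)) {
    input_paths <- sort(list.files(input_paths, pattern = "\\.tiff?$",
                                   full.names = TRUE, ignore.case = TRUE))
  }
  structure(list(input_paths = input_paths, channel_roles = channel_roles,
                 group_labels = group_labels, params = params,
                 output_dir = output_dir, overlay = isTRUE(overlay),
                 strict = isTRUE(strict)),
            class = "run_config")
}

params_echo_list <- function(params) {
  p <- unclass(params)
  p$nucleus_max_area_px <- if (is.finite(p$nucleus_max_area_px))
    p$nucleus_max_area_px else "unbounded"
  p
}

#' Run the quantification pipeline over a batch of images
#'
#' For every input image: read, segment nuclei and myotubes, assign nuclei,
#' compute indices, and write `per_myotube.csv`, `per_image.csv` and
#' `summary.json` (plus an `<id>_overlay.png` per image when requested)
#' under `config$output_dir`. All outputs embed the full parameter echo and
#' package version for provenance. When `group_labels` defines exactly two
#' conditions, per-group means/SDs and an unpaired t test on MDI and MFI
#' are added to the summary. Unreadable or failing images are reported and
#' skipped unless `strict`.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  per_image <- data.frame()
  per_myotube <- data.frame()
  failures <- list()
  if (length(config$input_paths) == 0L) {
    warning("no input images found", call. = FALSE)
  }
  for (path in config$input_paths) {
    id <- tools::file_path_sans_ext(basename(path))
    q <- tryCatch({
      img <- read_micrograph(path, config$channel_roles)
      quantify_image(img, config$params)
    }, error = function(e) e)
    if (inherits(q, "error")) {
      if (config$strict) stop(q)
      warning(sprintf("skipping %s: %s", path, conditionMessage(q)),
              call. = FALSE)
      failures[[id]] <- conditionMessage(q)
      next
    }
    r <- q$result
    per_image <- rbind(per_image, data.frame(
      image_id = id, n_total = r$n_total, n_inside = r$n_inside,
      n_outside = r$n_outside, n_myotubes = r$n_myotubes,
      mdi = r$mdi, mfi = r$mfi))
    if (nrow(q$myotube_records) > 0) {
      per_myotube <- rbind(per_myotube,
                           cbind(image_id = id, q$myotube_records))
    }
    if (config$overlay) {
      img <- read_micrograph(path, config$channel_roles)
      ov <- render_overlay(img, q$nuclei_labels, q$myotube_labels,
                           q$nucleus_records)
      write_overlay(ov, file.path(config$output_dir,
                                  paste0(id, "_overlay.png")))
    }
  }
  summary <- list(
    package_version = as.character(packageVersion("myoquant")),
    params = params_echo_list(config$params),
    n_images = nrow(per_image),
    failures = failures,
    per_image = per_image
  )
  if (!is.null(config$group_labels) && nrow(per_image) > 0) {
    groups <- unname(config$group_labels[per_image$image_id])
    per_image$group <- groups
    lv <- sort(unique(groups[!is.na(groups)]))
    summary$group_summary <- do.call(rbind, lapply(lv, function(g) {
      sel <- per_image[!is.na(groups) & groups == g, ]
      data.frame(group = g, n = nrow(sel),
                 mdi_mean = mean(sel$mdi), mdi_sd = sd(sel$mdi),
                 mfi_mean = mean(sel$mfi), mfi_sd = sd(sel$mfi))
    }))
    if (length(lv) == 2L) {
      a <- per_image[!is.na(groups) & groups == lv[1], ]
      b <- per_image[!is.na(groups) & groups == lv[2], ]
      if (nrow(a) >= 2 && nrow(b) >= 2) {
        summary$comparison <- list(
          groups = lv,
          mdi = unclass(compare_groups(a$mdi, b$mdi)),
          mfi = unclass(compare_groups(a$mfi, b$mfi)))
      }
    }
    summary$per_image <- per_image
  }
  write.csv(per_image, file.path(config$output_dir, "per_image.csv"),
            row.names = FALSE)
  write.csv(per_myotube, file.path(config$output_dir, "per_myotube.csv"),
            row.names = FALSE)
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}

# ---- configuration files ----------------------------------------------------

#' Read pipeline parameters from a YAML config
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file path; keys as in [pipeline_params()].
#' @return a [pipeline_params()].
#' @export
read_pipeline_params <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_params))
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    stop(sprintf("unknown parameter key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_params, y)
}

#' Read a simulation configuration from a YAML config
#'
#' @param path YAML file path; keys as in [simulation_config()].
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    stop(sprintf("unknown simulation key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  do.call(simulation_config, y)
}

# ---- ground-truth serialization --------------------------------------------

rle_encode_mask <- function(mask) {
  r <- rle(as.integer(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

rle_decode_mask <- function(enc) {
  m <- matrix(inverse.rle(list(lengths = enc$lengths,
                               values = enc$values)) == 1L,
              enc$dim[1], enc$dim[2])
  m
}

#' Write ground truth next to a simulated image
#'
#' Writes `<stem>.truth.json` (full ground truth; myotube footprints
#' run-length encoded column-major) and `<stem>.truth.csv` (one row per
#' nucleus).
#'
#' @param truth a `ground_truth`.
#' @param stem output path stem (no extension).
#' @return invisibly, the two paths written.
#' @export
write_ground_truth <- function(truth, stem) {
  json_path <- paste0(stem, ".truth.json")
  csv_path <- paste0(stem, ".truth.csv")
  obj <- list(
    nuclei = truth$nuclei,
    myotubes = lapply(truth$myotubes, function(m)
      list(id = m$id, intended_nucleus_count = m$intended_nucleus_count,
           footprint_rle = rle_encode_mask(m$footprint))),
    realized_mdi = truth$realized_mdi)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write.csv(truth$nuclei, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param json_path path to a `.truth.json` file.
#' @return a `ground_truth`.
#' @export
read_ground_truth <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  tubes <- obj$myotubes
  myotubes <- lapply(seq_along(tubes$id), function(i)
    list(id = as.integer(tubes$id[i]),
         footprint = rle_decode_mask(list(
           dim = unlist(tubes$footprint_rle$dim[i]),
           lengths = unlist(tubes$footprint_rle$lengths[i]),
           values = unlist(tubes$footprint_rle$values[i]))),
         intended_nucleus_count = as.integer(tubes$intended_nucleus_count[i])))
  structure(list(nuclei = as.data.frame(obj$nuclei),
                 myotubes = myotubes,
                 realized_mdi = obj$realized_mdi),
            class = "ground_truth")
}

#' Simulate a batch of micrographs to disk
#'
#' Writes `<prefix>_<i>.tif` (2-channel TIFF, channel 1 = nuclei, channel 2
#' = myotubes) plus ground-truth sidecars for `n_images` seeds derived from
#' the config seed (`seed + i - 1`).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @param n_images number of images.
#' @param prefix file-name prefix.
#' @return data frame with `image_id`, `path`, `truth_json`, `realized_mdi`.
#' @export
simulate_batch <- function(config, out_dir, n_images = 1L, prefix = "sim") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n_images), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- generate_image(cfg)
    id <- sprintf("%s_%03d", prefix, i)
    stem <- file.path(out_dir, id)
    write_micrograph(sim$image, paste0(stem, ".tif"))
    write_ground_truth(sim$truth, stem)
    data.frame(image_id = id, path = paste0(stem, ".tif"),
               truth_json = paste0(stem, ".truth.json"),
               realized_mdi = sim$truth$realized_mdi)
  })
  do.call(rbind, rows)
}
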