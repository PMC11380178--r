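# Micrograph: a two-channel fluorescence image. Channels are plain numeric
# matrices on the native intensity scale (typically 16-bit, 0..65535);
# channel_roles maps the biological stains to channel indices.

#' Construct a two-channel micrograph
#'
#' @param channels list of numeric matrices of equal shape (intensity a.u.).
#' @param channel_roles named integer vector mapping the roles `nuclei`
#'   (DAPI) and `myotubes` (MF20) to distinct channel indices.
#' @param pixel_size_um optional physical pixel size, micrometers.
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(channels, channel_roles = c(nuclei = 1L, myotubes = 2L),
                       pixel_size_um = NULL) {
  if (!is.list(channels) || length(channels) < 2L) {
    stop_myoquant("a micrograph needs at least two channels",
                  "myoquant_channel_error")
  }
  if (!all(vapply(channels, is.matrix, logical(1)))) {
    stop("all channels must be matrices", call. = FALSE)
  }
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels must have the same height and width", call. = FALSE)
  }
  roles <- check_roles(channel_roles, length(channels))
  for (ch in channels) {
    if (any(!is.finite(ch)) || any(ch < 0)) {
      stop("channel intensities must be finite and non-negative", call. = FALSE)
    }
  }
  structure(list(channels = channels, channel_roles = roles,
                 pixel_size_um = pixel_size_um),
            class = "micrograph")
}

check_roles <- function(channel_roles, n_channels) {
  needed <- c("nuclei", "myotubes")
  if (is.null(names(channel_roles)) || !all(needed %in% names(channel_roles))) {
    stop_myoquant("channel_roles must name both 'nuclei' and 'myotubes'",
                  "myoquant_role_error")
  }
  roles <- vapply(needed, function(nm) as.integer(channel_roles[[nm]]),
                  integer(1))
  if (any(is.na(roles)) || any(roles < 1L) || any(roles > n_channels)) {
    stop_myoquant(
      sprintf("channel role index out of range (image has %d channels)",
              n_channels),
      "myoquant_role_error")
  }
  if (roles[["nuclei"]] == roles[["myotubes"]]) {
    stop_myoquant("'nuclei' and 'myotubes' must map to distinct channels",
                  "myoquant_role_error")
  }
  roles
}

stop_myoquant <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "myoquant_error")))
}

#' Extract a channel by role
#'
#' @param image a `micrograph`.
#' @param role `"nuclei"` or `"myotubes"`.
#' @return numeric intensity matrix.
#' @export
get_channel <- function(image, role = c("nuclei", "myotubes")) {
  role <- match.arg(role)
  if (!inherits(image, "micrograph")) {
    stop("image must be a micrograph", call. = FALSE)
  }
  image$channels[[image$channel_roles[[role]]]]
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<micrograph> %d x %d px, %d channels (nuclei = %d, myotubes = %d)\n",
              d[1], d[2], length(x$channels),
              x$channel_roles[["nuclei"]], x$channel_roles[["myotubes"]]))
  invisible(x)
}

#' Read a multichannel TIFF as a micrograph
#'
#' Accepts channel-first TIFFs (one grayscale page per channel) and
#' channel-last TIFFs (a single page with a trailing sample axis); the axis
#' of length <= 4 is taken as the channel axis. Intensities are left on the
#' native integer scale.
#'
#' @param path TIFF file path.
#' @param channel_roles named vector mapping `nuclei` and `myotubes` to
#'   channel indices.
#' @return a `micrograph`.
#' @export
read_micrograph <- function(path, channel_roles = c(nuclei = 1L, myotubes = 2L)) {
  if (!file.exists(path)) {
    stop_myoquant(sprintf("file not found: %s", path), "myoquant_file_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) >= 2L) {
    channels <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p[, , 1L] else p
    })
  } else {
    x <- pages[[1]]
    if (is.matrix(x)) {
      stop_myoquant("TIFF has a single channel; two are required",
                    "myoquant_channel_error")
    }
    d <- dim(x)
    if (length(d) == 3L && d[3] <= 4L) {
      channels <- lapply(seq_len(d[3]), function(i) x[, , i])
    } else if (length(d) == 3L && d[1] <= 4L) {
      channels <- lapply(seq_len(d[1]), function(i) x[i, , ])
    } else {
      stop_myoquant("cannot locate a channel axis of length <= 4",
                    "myoquant_channel_error")
    }
    if (length(channels) < 2L) {
      stop_myoquant("TIFF has a single channel; two are required",
                    "myoquant_channel_error")
    }
  }
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  micrograph(channels, channel_roles)
}

#' Write a micrograph as a 16-bit multichannel TIFF
#'
#' Channels are written as successive grayscale pages (channel-first), each
#' clipped to the 16-bit range. A write-then-read round trip through
#' [read_micrograph()] reproduces integer intensities exactly.
#'
#' @param image a `micrograph` with intensities in 0..65535.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_micrograph <- function(image, path) {
  if (!inherits(image, "micrograph")) {
    stop("image must be a micrograph", call. = FALSE)
  }
  pages <- lapply(image$channels, function(m) {
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
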