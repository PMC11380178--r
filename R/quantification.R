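# Nucleus-to-myotube assignment, MDI/MFI computation, condition comparison
# and the delta-delta-Ct qPCR utility.

#' Assign segmented nuclei to myotube regions of interest
#'
#' Each nucleus is assigned by the rounded-centroid rule: its `myotube_id`
#' is the myotube label under the pixel nearest its centroid (0 if that
#' pixel is background). Every nucleus appears exactly once, which makes
#' the conservation identity `n_inside + n_outside = n_total` exact.
#'
#' @param nuclei integer label map of nuclei.
#' @param myotubes integer label map of myotube ROIs; same shape.
#' @return a data frame of nucleus records: `nucleus_id`, `centroid_row`,
#'   `centroid_col` (1-based pixel coordinates), `area_px`, `myotube_id`.
#' @export
assign_nuclei <- function(nuclei, myotubes) {
  if (!all(dim(nuclei) == dim(myotubes))) {
    stop("nucleus and myotube label maps must have the same shape",
         call. = FALSE)
  }
  idx <- which(nuclei > 0L)
  if (length(idx) == 0L) {
    return(data.frame(nucleus_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = numeric(0),
                      myotube_id = integer(0)))
  }
  h <- nrow(nuclei)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  labs <- nuclei[idx]
  area <- tabulate(labs)
  cr <- rowsum(as.numeric(rows), labs)[, 1] / area
  cc <- rowsum(as.numeric(cols), labs)[, 1] / area
  pr <- pmin(pmax(round(cr), 1L), h)
  pc <- pmin(pmax(round(cc), 1L), ncol(nuclei))
  data.frame(nucleus_id = seq_along(area),
             centroid_row = as.numeric(cr),
             centroid_col = as.numeric(cc),
             area_px = area,
             myotube_id = as.integer(myotubes[cbind(pr, pc)]))
}

#' Measure myotube ROIs
#'
#' @param myotubes integer label map of myotube ROIs.
#' @param nucleus_records nucleus records from [assign_nuclei()].
#' @return a data frame of myotube records: `myotube_id`, `area_px`,
#'   `n_nuclei`.
#' @export
measure_myotubes <- function(myotubes, nucleus_records) {
  k <- n_labels(myotubes)
  if (k == 0L) {
    return(data.frame(myotube_id = integer(0), area_px = numeric(0),
                      n_nuclei = integer(0)))
  }
  areas <- tabulate(myotubes[myotubes > 0L], nbins = k)
  inside <- nucleus_records$myotube_id[nucleus_records$myotube_id > 0L]
  counts <- tabulate(inside, nbins = k)
  data.frame(myotube_id = seq_len(k), area_px = areas, n_nuclei = counts)
}

bin_histogram <- function(counts, edges) {
  # counts: nuclei per MF20+ object; objects without nuclei are not binned
  counts <- counts[counts >= edges[1]]
  n <- length(edges)
  labels <- character(n)
  for (i in seq_len(n)) {
    if (i < n) {
      labels[i] <- if (edges[i + 1] - 1L == edges[i]) as.character(edges[i])
                   else sprintf("%d-%d", edges[i], edges[i + 1] - 1L)
    } else {
      labels[i] <- sprintf(">=%d", edges[i])
    }
  }
  bin <- findInterval(counts, edges)
  setNames(as.integer(tabulate(bin, nbins = n)), labels)
}

new_quant_result <- function(n_total, n_inside, mfi_numerator, histogram,
                             n_myotubes, params_echo, degenerate = FALSE) {
  n_total <- as.integer(n_total); n_inside <- as.integer(n_inside)
  structure(list(
    n_total = n_total,
    n_inside = n_inside,
    n_outside = n_total - n_inside,
    mdi = if (n_total > 0) n_inside / n_total else 0,
    mfi = if (n_total > 0) mfi_numerator / n_total else 0,
    histogram = histogram,
    n_myotubes = as.integer(n_myotubes),
    params_echo = params_echo,
    degenerate = degenerate
  ), class = "quant_result")
}

#' Compute the myogenic differentiation and fusion indices
#'
#' MDI = fraction of all nuclei lying inside MF20-positive objects.
#' MFI = fraction of all nuclei lying inside MF20-positive objects that
#' contain at least `mfi_min_nuclei` nuclei (default 2, i.e. truly fused
#' syncytia). The per-myotube nucleus-count histogram is also reported, the
#' mononucleated bin serving as reference, so alternative index conventions
#' remain recoverable. With zero nuclei both indices are 0 and the result
#' is flagged `degenerate`.
#'
#' @param nucleus_records data frame from [assign_nuclei()].
#' @param myotube_records data frame from [measure_myotubes()]; its
#'   `n_nuclei` must be consistent with the assignments.
#' @param params a [pipeline_params()] object.
#' @return an object of class `quant_result` with fields `n_total`,
#'   `n_inside`, `n_outside`, `mdi`, `mfi`, `histogram`, `n_myotubes`,
#'   `params_echo`, `degenerate`.
#' @export
compute_indices <- function(nucleus_records, myotube_records,
                            params = pipeline_params()) {
  if (any(myotube_records$n_nuclei < 0)) {
    stop("negative nucleus counts", call. = FALSE)
  }
  inside <- nucleus_records$myotube_id[nucleus_records$myotube_id > 0L]
  recount <- tabulate(inside, nbins = max(myotube_records$myotube_id, 0L))
  if (length(recount) && any(recount[myotube_records$myotube_id] !=
                             myotube_records$n_nuclei)) {
    stop("myotube n_nuclei inconsistent with nucleus assignments",
         call. = FALSE)
  }
  n_total <- nrow(nucleus_records)
  n_inside <- sum(nucleus_records$myotube_id > 0L)
  fused <- myotube_records$n_nuclei >= params$mfi_min_nuclei
  mfi_num <- sum(myotube_records$n_nuclei[fused])
  hist <- bin_histogram(myotube_records$n_nuclei, params$histogram_bins)
  new_quant_result(n_total, n_inside, mfi_num, hist,
                   nrow(myotube_records), params,
                   degenerate = n_total == 0L)
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> N = %d nuclei (%d inside, %d outside), %d myotubes\n",
              x$n_total, x$n_inside, x$n_outside, x$n_myotubes))
  cat(sprintf("  MDI = %.4f   MFI = %.4f%s\n", x$mdi, x$mfi,
              if (isTRUE(x$degenerate)) "   [degenerate: no nuclei]" else ""))
  cat("  nuclei per myotube:",
      paste(sprintf("%s: %d", names(x$histogram), x$histogram),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare an index between two conditions (unpaired t test)
#'
#' Two-sided unpaired Student t test with pooled variance on per-replicate
#' index values (e.g. per-image MDI). Degenerate input with zero pooled
#' variance returns t = 0, p = 1 when the means are equal.
#'
#' @param a,b numeric vectors of per-replicate values (length >= 2 each).
#' @return an object of class `group_comparison`: `t_statistic`, `df`,
#'   `p_value`, `mean_difference` (mean(a) - mean(b)), plus the input
#'   values.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  md <- mean(a) - mean(b)
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled <= .Machine$double.eps * max(abs(c(a, b)), 1)^2) {
    tstat <- if (md == 0) 0 else sign(md) * Inf
    pval <- if (md == 0) 1 else 0
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  structure(list(group_a_values = a, group_b_values = b,
                 t_statistic = tstat, df = df, p_value = pval,
                 mean_difference = md),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.4f (df = %d), p = %.4g, mean difference = %.4f\n",
              x$t_statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' qPCR fold induction by the delta-delta-Ct method
#'
#' Per condition, delta-Ct = Ct(target) - Ct(reference gene, e.g. 18S);
#' delta-delta-Ct = delta-Ct(treated) - delta-Ct(control); fold induction =
#' 2^(-delta-delta-Ct).
#'
#' @param treated,control lists (or named vectors) with elements
#'   `ct_target` and `ct_reference`, in cycles.
#' @return fold induction (dimensionless).
#' @examples
#' delta_delta_ct(list(ct_target = 22, ct_reference = 10),
#'                list(ct_target = 24, ct_reference = 10))  # 4
#' @export
delta_delta_ct <- function(treated, control) {
  ct <- function(s, nm) {
    v <- s[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a finite positive cycle number", nm),
           call. = FALSE)
    }
    v
  }
  d_treated <- ct(treated, "ct_target") - ct(treated, "ct_reference")
  d_control <- ct(control, "ct_target") - ct(control, "ct_reference")
  2^(-(d_treated - d_control))
}
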