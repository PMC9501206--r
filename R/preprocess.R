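#' Log2 transform with absolute-value handling of negatives
#'
#' The consensus fit runs on log2 intensities to tame the large dynamic range
#' and heteroscedasticity of 1D 1H NMR data. Baseline distortions leave
#' occasional small negative values which the logarithm cannot take; these
#' are replaced by their absolute values. Exact zeros are floored:
#' `y -> log2(max(|y|, zero_floor))`. The transform only touches regions
#' without clear metabolite signal, where intensities hover around zero.
#'
#' @param s A linear-scale [spectrum_set()].
#' @param zero_floor Positive floor applied to `|y|` before the log. Default
#'   `2^-30` times the largest absolute included intensity, a relative floor
#'   far below any signal.
#' @return The transformed `spectrum_set`, flagged `scale = "log2"` so that
#'   feature summation can refuse it.
#' @examples
#' s <- spectrum_set(matrix(c(4, -4), 1), ppm = c(2, 1))
#' log2_abs_transform(s)$intensities # both 2
#' @export
log2_abs_transform <- function(s, zero_floor = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$scale != "linear") stop("input is already log-scale", call. = FALSE)
  if (is.null(zero_floor)) {
    zero_floor <- 2^-30 * max(abs(s$intensities[, s$include, drop = FALSE]))
    if (!is.finite(zero_floor) || zero_floor <= 0) zero_floor <- 2^-30
  }
  stopifnot(zero_floor > 0)
  y <- s$intensities[, s$include, drop = FALSE]
  s$intensities[, s$include] <- log2(pmax(abs(y), zero_floor))
  s$scale <- "log2"
  s
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution (urine fluid intake, say) by the standard
#' PQN recipe: the reference is the position-wise median spectrum of the
#' cohort over included positions; each sample's dilution factor is the
#' median of its intensity quotients against the reference (positions with a
#' non-positive reference value are skipped); the sample is divided by its
#' factor. Applied on the linear intensity scale, before any log transform.
#'
#' @param s A linear-scale [spectrum_set()] with at least 2 samples.
#' @param reference Optional frozen reference spectrum (length-p numeric,
#'   full axis). Supplying the reference makes the operation idempotent:
#'   re-deriving factors of an already-normalized set against the same
#'   reference yields 1 for every sample.
#' @return A list with `spectra` (the normalized `spectrum_set`) and `report`,
#'   a tibble with columns `sample_id`, `factor`, plus attributes `method`
#'   and `reference`.
#' @export
pqn_normalize <- function(s, reference = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$scale != "linear") stop("PQN expects linear-scale intensities", call. = FALSE)
  if (nrow(s$intensities) < 2 && is.null(reference)) {
    stop("PQN needs >= 2 samples to form a median reference", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- rep(NA_real_, length(s$ppm))
    reference[s$include] <- apply(s$intensities[, s$include, drop = FALSE], 2,
                                  stats::median)
  }
  ref <- reference[s$include]
  use <- !is.na(ref) & ref > 0
  if (!any(use)) stop("PQN reference has no positive entries", call. = FALSE)
  y <- s$intensities[, s$include, drop = FALSE]
  factors <- apply(y[, use, drop = FALSE], 1, function(row) {
    stats::median(row / ref[use])
  })
  bad <- !is.finite(factors) | factors <= 0
  if (any(bad)) {
    stop("non-positive PQN factor for sample(s): ",
         paste(s$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  s$intensities <- s$intensities / factors
  report <- tibble::tibble(sample_id = s$sample_ids, factor = unname(factors))
  attr(report, "method") <- "pqn"
  attr(report, "reference_kind") <- "median_spectrum"
  attr(report, "reference") <- reference
  list(spectra = s, report = report)
}

#' Internal-standard normalization
#'
#' Divides every sample by the summed intensity over a reference ppm region
#' (e.g. the TSP or formic acid signal), correcting for spectrometer
#' performance drift. Applied on the linear scale.
#'
#' @param s A linear-scale [spectrum_set()].
#' @param region Length-2 numeric `(ppm_hi, ppm_lo)` bounding the internal
#'   standard signal; must overlap at least one axis position.
#' @return A list with `spectra` and `report`, as in [pqn_normalize()].
#' @export
internal_standard_normalize <- function(s, region) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$scale != "linear") {
    stop("internal-standard normalization expects linear-scale intensities",
         call. = FALSE)
  }
  region <- sort(as.numeric(region), decreasing = TRUE)
  sel <- s$ppm <= region[1] & s$ppm >= region[2]
  if (!any(sel)) stop("internal-standard region overlaps no axis position",
                      call. = FALSE)
  factors <- rowSums(s$intensities[, sel, drop = FALSE])
  bad <- !is.finite(factors) | factors <= 0
  if (any(bad)) {
    stop("non-positive internal-standard sum for sample(s): ",
         paste(s$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  s$intensities <- s$intensities / factors
  report <- tibble::tibble(sample_id = s$sample_ids, factor = unname(factors))
  attr(report, "method") <- "internal_standard"
  attr(report, "reference_kind") <- "ppm_region"
  attr(report, "reference_region") <- region
  list(spectra = s, report = report)
}

#' Equidistant binning baseline
#'
#' The classical fixed-width bucketing baseline: within each contiguous
#' included segment, consecutive blocks of `width_bins` positions are summed
#' into one feature. A trailing block shorter than `width_bins` is kept if it
#' is wider than `min_region_bins` bins, otherwise dropped (and recorded).
#' Blocks never straddle a segment boundary.
#'
#' @param s A linear-scale [spectrum_set()].
#' @param width_bins Positive integer block width in axis bins (10 or 20 bins
#'   at 0.001 ppm reproduce the usual 0.01 / 0.02 ppm buckets).
#' @param min_region_bins Trailing blocks of width `<= min_region_bins` are
#'   dropped. Default 2 (matches the 0.002 ppm minimum-width rule at
#'   0.001 ppm resolution).
#' @return A `feature_table` with regions of kind `"equidistant"`.
#' @export
equidistant_bin <- function(s, width_bins, min_region_bins = 2L) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$scale != "linear") {
    stop("equidistant binning sums linear-scale intensities", call. = FALSE)
  }
  width_bins <- as.integer(width_bins)
  stopifnot(width_bins >= 1L)
  segs <- segment_table(s)
  starts <- integer(0); ends <- integer(0); seg_ids <- integer(0)
  d_starts <- integer(0); d_ends <- integer(0); d_seg <- integer(0)
  for (k in seq_len(nrow(segs))) {
    b0 <- seq(segs$start[k], segs$end[k], by = width_bins)
    b1 <- pmin(b0 + width_bins - 1L, segs$end[k])
    w <- b1 - b0 + 1L
    keep <- w == width_bins | w > min_region_bins
    starts <- c(starts, b0[keep]); ends <- c(ends, b1[keep])
    seg_ids <- c(seg_ids, rep(segs$segment_id[k], sum(keep)))
    d_starts <- c(d_starts, b0[!keep]); d_ends <- c(d_ends, b1[!keep])
    d_seg <- c(d_seg, rep(segs$segment_id[k], sum(!keep)))
  }
  regions <- make_region_tibble(starts, ends, "equidistant", seg_ids, s)
  dropped <- make_region_tibble(d_starts, d_ends, "equidistant", d_seg, s)
  rs <- region_set(regions, dropped, bin_width_ppm = bin_width(s),
                   min_region_bins = as.integer(min_region_bins),
                   lambda = NULL,
                   method = "equidistant", width_bins = width_bins)
  summarize_features(s, rs)
}

#' Equidistant binning with the width given in ppm
#'
#' Converts a ppm bucket width to a whole number of axis bins via the axis
#' resolution, then calls [equidistant_bin()].
#'
#' @inheritParams equidistant_bin
#' @param width_ppm Bucket width in ppm (e.g. 0.01 or 0.02).
#' @return A `feature_table`.
#' @export
equidistant_bin_ppm <- function(s, width_ppm, min_region_bins = 2L) {
  wb <- round(width_ppm / bin_width(s))
  if (wb < 1) stop("width_ppm below the axis resolution", call. = FALSE)
  equidistant_bin(s, wb, min_region_bins)
}
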