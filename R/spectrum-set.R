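#' Build a spectrum set
#'
#' A `spectrum_set` holds a stack of 1D NMR spectra on a shared chemical-shift
#' axis: an `n` samples by `p` positions intensity matrix, the ppm axis, an
#' inclusion mask marking positions removed from analysis (solvent, internal
#' standard, urea regions), and segment labels for the maximal contiguous runs
#' of included positions. Excluded positions are masked, never deleted, so
#' downstream smoothing never couples intensities across a physical gap.
#'
#' The ppm axis must be strictly monotone. Descending order is the NMR
#' plotting convention and the internal storage order; an ascending axis is
#' accepted and silently reversed together with the intensity columns.
#'
#' @param intensities Numeric matrix, samples in rows, spectral positions in
#'   columns. Small negative values (baseline distortions) are allowed.
#' @param ppm Numeric vector of chemical shifts (ppm), one per column,
#'   strictly monotone.
#' @param sample_ids Optional character vector of unique sample labels;
#'   defaults to the matrix rownames or `sample_1..n`.
#' @param include Optional logical vector, one per position; `FALSE` marks an
#'   excluded position. Defaults to all included.
#' @param scale Intensity scale, `"linear"` or `"log2"`. Feature summation
#'   refuses log-scale input; the ADMM fit expects it.
#' @return A `spectrum_set` object.
#' @examples
#' y <- matrix(rlnorm(20), nrow = 2)
#' s <- spectrum_set(y, ppm = seq(4.0095, by = -0.001, length.out = 10))
#' s
#' @export
spectrum_set <- function(intensities, ppm, sample_ids = NULL, include = NULL,
                         scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (n < 1L || p < 2L) {
    stop("a spectrum_set needs at least 1 sample and 2 positions", call. = FALSE)
  }
  ppm <- as.numeric(ppm)
  if (length(ppm) != p) {
    stop("length(ppm) must equal ncol(intensities)", call. = FALSE)
  }
  if (anyNA(ppm) || anyDuplicated(ppm)) {
    stop("ppm axis must be free of NA and duplicates", call. = FALSE)
  }
  d <- diff(ppm)
  if (all(d > 0)) {
    # ascending input: reverse to the descending NMR convention
    ppm <- rev(ppm)
    intensities <- intensities[, p:1, drop = FALSE]
    if (!is.null(include)) include <- rev(include)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique, one per row", call. = FALSE)
  }
  rownames(intensities) <- sample_ids
  colnames(intensities) <- NULL
  if (is.null(include)) include <- rep(TRUE, p)
  include <- as.logical(include)
  if (length(include) != p || anyNA(include)) {
    stop("include mask must be logical, one value per position", call. = FALSE)
  }
  out <- structure(
    list(
      intensities = intensities,
      ppm = ppm,
      sample_ids = sample_ids,
      include = include,
      segment_id = segment_labels(include),
      scale = scale
    ),
    class = "spectrum_set"
  )
  out
}

# Integer labels 1,2,... for maximal contiguous runs of TRUE; NA where FALSE.
segment_labels <- function(include) {
  r <- rle(include)
  seg <- integer(length(r$lengths))
  seg[r$values] <- seq_len(sum(r$values))
  lab <- rep.int(ifelse(r$values, seg, NA_integer_), r$lengths)
  as.integer(lab)
}

#' @export
print.spectrum_set <- function(x, ...) {
  n_seg <- length(unique(stats::na.omit(x$segment_id)))
  cat(sprintf(
    "<spectrum_set> %d sample%s x %d positions (%s scale)\n",
    nrow(x$intensities), if (nrow(x$intensities) == 1) "" else "s",
    length(x$ppm), x$scale
  ))
  cat(sprintf(
    "  ppm %.4f .. %.4f | %d included / %d excluded positions in %d segment%s\n",
    x$ppm[1], x$ppm[length(x$ppm)], sum(x$include), sum(!x$include),
    n_seg, if (n_seg == 1) "" else "s"
  ))
  invisible(x)
}

#' Median bin width of the ppm axis, in ppm
#' @param s A `spectrum_set`.
#' @return A positive scalar.
#' @export
bin_width <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  stats::median(abs(diff(s$ppm)))
}

#' Exclusion regions
#'
#' An exclusion config is a set of ppm intervals `(hi, lo)` to mask out, e.g.
#' residual water/urea (6.5--4.5 ppm in urine) and the TSP reference region
#' (0.5 to -0.5 ppm). Overlapping intervals are permitted and merged.
#'
#' @param intervals A list of length-2 numeric vectors or a 2-column matrix;
#'   each row/element is `(hi, lo)` with `hi > lo`, in ppm.
#' @return An `exclusion_config` (tibble with columns `ppm_hi`, `ppm_lo`).
#' @export
exclusion_config <- function(intervals) {
  if (is.matrix(intervals)) intervals <- asplit(intervals, 1)
  iv <- purrr::map(intervals, function(x) {
    x <- as.numeric(x)
    if (length(x) != 2 || anyNA(x)) {
      stop("each exclusion interval must be two finite ppm values", call. = FALSE)
    }
    sort(x, decreasing = TRUE)
  })
  out <- tibble::tibble(
    ppm_hi = purrr::map_dbl(iv, 1),
    ppm_lo = purrr::map_dbl(iv, 2)
  )
  if (any(out$ppm_hi <= out$ppm_lo)) {
    stop("exclusion intervals must have hi > lo", call. = FALSE)
  }
  class(out) <- c("exclusion_config", class(out))
  out
}

#' Mask excluded ppm regions
#'
#' Marks every position whose chemical shift falls inside any of the given
#' intervals as excluded (boundaries inclusive: a position is excluded iff
#' `lo <= ppm <= hi`). Columns are masked, never deleted; segment labels are
#' recomputed so the fit never fuses across a gap. Idempotent, and
#' order-independent over the intervals.
#'
#' @param s A `spectrum_set`.
#' @param cfg An `exclusion_config`, or anything `exclusion_config()` accepts.
#' @return The masked `spectrum_set`.
#' @examples
#' s <- spectrum_set(matrix(1, 1, 10), ppm = seq(9.5, 0.5, by = -1))
#' apply_exclusions(s, list(c(6.5, 4.5)))
#' @export
apply_exclusions <- function(s, cfg) {
  stopifnot(inherits(s, "spectrum_set"))
  if (!inherits(cfg, "exclusion_config")) cfg <- exclusion_config(cfg)
  include <- s$include
  for (k in seq_len(nrow(cfg))) {
    include <- include & !(s$ppm >= cfg$ppm_lo[k] & s$ppm <= cfg$ppm_hi[k])
  }
  if (!any(include)) {
    stop("all positions excluded: empty problem", call. = FALSE)
  }
  s$include <- include
  s$segment_id <- segment_labels(include)
  s
}

#' Tidy a spectrum set into a long tibble
#'
#' @param x A `spectrum_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `ppm`, `intensity`, `included`,
#'   `segment_id`.
#' @method tidy spectrum_set
#' @export
tidy.spectrum_set <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = length(x$ppm)),
    ppm = rep(x$ppm, times = length(x$sample_ids)),
    intensity = as.vector(t(x$intensities)),
    included = rep(x$include, times = length(x$sample_ids)),
    segment_id = rep(x$segment_id, times = length(x$sample_ids))
  )
}

#' Plot a spectrum set
#'
#' Intensity traces against chemical shift (descending axis, NMR convention),
#' one line per sample; excluded regions are shaded.
#'
#' @param object A `spectrum_set`.
#' @param samples Optional subset of sample ids to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_set
#' @export
autoplot.spectrum_set <- function(object, samples = NULL, ...) {
  df <- tidy.spectrum_set(object)
  if (!is.null(samples)) df <- dplyr::filter(df, .data$sample_id %in% samples)
  gg <- ggplot2::ggplot(
    dplyr::filter(df, .data$included),
    ggplot2::aes(x = .data$ppm, y = .data$intensity, group = .data$sample_id,
                 colour = .data$sample_id)
  ) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = length(object$sample_ids) <= 8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
  excl <- excluded_spans(object)
  if (nrow(excl) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = excl,
      ggplot2::aes(xmin = .data$ppm_hi, xmax = .data$ppm_lo),
      ymin = -Inf, ymax = Inf, fill = "grey80", alpha = 0.4,
      inherit.aes = FALSE
    )
  }
  gg
}

excluded_spans <- function(s) {
  r <- rle(s$include)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  hw <- bin_width(s) / 2
  tibble::tibble(
    ppm_hi = s$ppm[starts[keep]] + hw,
    ppm_lo = s$ppm[ends[keep]] - hw
  )
}

# Per-segment index ranges as a tibble (segment_id, start, end), 1-based closed.
segment_table <- function(s) {
  r <- rle(!is.na(s$segment_id) & s$include)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    segment_id = s$segment_id[starts[keep]],
    start = starts[keep],
    end = ends[keep]
  )
}
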