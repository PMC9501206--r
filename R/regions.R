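#' Region sets: the shared segmentation
#'
#' A `region_set` is the consensus segmentation produced by the fit: an
#' ordered list of disjoint index intervals (1-based, closed) tagged
#' `plateau` (adjacent fitted columns exactly equal across all spectra),
#' `non_plateau` (maximal stretches between plateaus, retained as secondary
#' features), or `equidistant` (fixed-width baseline). Regions removed by
#' the minimum-width filter are kept in `dropped` so that retained and
#' dropped regions together tile every included segment exactly. A single
#' region set serves all samples: boundaries are sample-independent by
#' construction.
#'
#' @param regions,dropped Tibbles with columns `region_id`, `start`, `end`,
#'   `width_bins`, `ppm_hi`, `ppm_lo`, `kind`, `segment_id`.
#' @param bin_width_ppm Axis resolution in ppm.
#' @param min_region_bins Width filter: regions of width `<= min_region_bins`
#'   bins were dropped.
#' @param lambda Penalty used to fit (NULL for equidistant binning).
#' @param method `"bf"` or `"equidistant"`.
#' @param width_bins Block width for equidistant sets.
#' @return A `region_set` object.
#' @export
region_set <- function(regions, dropped, bin_width_ppm, min_region_bins = 2L,
                       lambda = NULL, method = "bf", width_bins = NULL) {
  structure(
    list(regions = regions, dropped = dropped,
         bin_width_ppm = bin_width_ppm,
         min_region_bins = as.integer(min_region_bins),
         lambda = lambda, method = method, width_bins = width_bins),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  k <- table(factor(x$regions$kind, levels = c("plateau", "non_plateau", "equidistant")))
  cat(sprintf(
    "<region_set> %d retained (%d plateau, %d non-plateau, %d equidistant), %d dropped\n",
    nrow(x$regions), k[["plateau"]], k[["non_plateau"]], k[["equidistant"]],
    nrow(x$dropped)
  ))
  invisible(x)
}

empty_region_tibble <- function() {
  tibble::tibble(
    region_id = character(0), start = integer(0), end = integer(0),
    width_bins = integer(0), ppm_hi = numeric(0), ppm_lo = numeric(0),
    kind = character(0), segment_id = integer(0)
  )
}

# Region tibble from global index bounds; ppm bounds are the member
# positions' shifts +/- half a bin width (descending axis).
make_region_tibble <- function(starts, ends, kind, seg_ids, s) {
  if (length(starts) == 0) return(empty_region_tibble())
  hw <- bin_width(s) / 2
  tibble::tibble(
    region_id = NA_character_,
    start = as.integer(starts), end = as.integer(ends),
    width_bins = as.integer(ends - starts + 1L),
    ppm_hi = s$ppm[starts] + hw,
    ppm_lo = s$ppm[ends] - hw,
    kind = rep_len(kind, length(starts)),
    segment_id = as.integer(seg_ids)
  )
}

#' Fused boundaries of a converged fit
#'
#' Boundary `j` (between positions `j` and `j+1` of the segment) is fused
#' iff column `j` of the auxiliary matrix `G` is exactly the zero vector --
#' an exact test, no epsilon, because the group soft-thresholding step
#' produces exact zeros. At convergence `G` equals the adjacent column
#' differences of the fit, so a fused boundary means the two fitted columns
#' are equal in every sample: a plateau interior.
#'
#' @param fit A `bf_fit`.
#' @return Logical vector of length `p - 1`. If the fit did not converge a
#'   warning is attached and the result still produced.
#' @export
fused_boundaries <- function(fit) {
  stopifnot(inherits(fit, "bf_fit"))
  if (!fit$converged) {
    warning("fit did not converge; fused boundaries may be unreliable",
            call. = FALSE)
  }
  colSums(abs(fit$G)) == 0
}

#' Build plateau / non-plateau regions from fused boundaries
#'
#' Maximal runs of fused boundaries become plateaus (a run of `r`
#' consecutive fused boundaries spans `r + 1` bins); maximal stretches of
#' positions not covered by any plateau become non-plateau regions. Both
#' kinds are then passed through the minimum-width filter: regions spanning
#' `<= min_region_bins` bins are moved to `dropped` (at the default 2 and a
#' 0.001 ppm grid this removes widths `<= 0.002` ppm). Before dropping,
#' the regions tile the segment exactly.
#'
#' @param fused Logical vector of length `p - 1` for one segment
#'   (see [fused_boundaries()]).
#' @param min_region_bins Width filter threshold in bins, default 2.
#' @return A list of two tibbles, `regions` and `dropped`, with local
#'   columns `start`, `end`, `kind` (1-based, closed, segment-local).
#' @export
build_regions <- function(fused, min_region_bins = 2L) {
  p <- length(fused) + 1L
  starts <- integer(0); ends <- integer(0); kinds <- character(0)
  covered <- rep(FALSE, p)
  if (any(fused)) {
    r <- rle(fused)
    bend <- cumsum(r$lengths)
    bstart <- bend - r$lengths + 1L
    for (k in which(r$values)) {
      a <- bstart[k]; b <- bend[k] + 1L # positions a..b
      starts <- c(starts, a); ends <- c(ends, b); kinds <- c(kinds, "plateau")
      covered[a:b] <- TRUE
    }
  }
  if (any(!covered)) {
    r <- rle(covered)
    rend <- cumsum(r$lengths)
    rstart <- rend - r$lengths + 1L
    for (k in which(!r$values)) {
      starts <- c(starts, rstart[k]); ends <- c(ends, rend[k])
      kinds <- c(kinds, "non_plateau")
    }
  }
  ord <- order(starts)
  df <- tibble::tibble(start = starts[ord], end = ends[ord], kind = kinds[ord])
  w <- df$end - df$start + 1L
  list(regions = df[w > min_region_bins, ], dropped = df[w <= min_region_bins, ])
}

#' Region set of a whole fitted spectrum stack
#'
#' Applies [fused_boundaries()] and [build_regions()] to every segment of a
#' [bf_solve_segments()] result and assembles one global `region_set`
#' (global 1-based indices, ordered by start, ids assigned `R0001...` for
#' retained and `D0001...` for dropped regions).
#'
#' @param fit_set A `bf_fit_set`.
#' @param min_region_bins Width filter threshold in bins, default 2.
#' @return A `region_set`.
#' @export
regions_from_fit <- function(fit_set, min_region_bins = 2L) {
  stopifnot(inherits(fit_set, "bf_fit_set"))
  segs <- fit_set$segments
  pseudo <- list(ppm = fit_set$ppm, include = fit_set$include)
  hw <- stats::median(abs(diff(fit_set$ppm)))
  reg_list <- list(); drop_list <- list()
  for (k in seq_len(nrow(segs))) {
    fit <- fit_set$fits[[k]]
    off <- segs$start[k] - 1L
    if (fit$p == 1L) {
      local <- list(
        regions = tibble::tibble(start = integer(0), end = integer(0),
                                 kind = character(0)),
        dropped = tibble::tibble(start = 1L, end = 1L, kind = "non_plateau")
      )
    } else {
      local <- build_regions(fused_boundaries(fit), min_region_bins)
    }
    globalize <- function(df) {
      if (nrow(df) == 0) return(NULL)
      tibble::tibble(start = df$start + off, end = df$end + off,
                     kind = df$kind, segment_id = segs$segment_id[k])
    }
    reg_list[[k]] <- globalize(local$regions)
    drop_list[[k]] <- globalize(local$dropped)
  }
  assemble <- function(lst, prefix) {
    df <- dplyr::bind_rows(lst)
    if (is.null(df) || nrow(df) == 0) return(empty_region_tibble())
    df <- dplyr::arrange(df, .data$start)
    out <- tibble::tibble(
      region_id = sprintf("%s%04d", prefix, seq_len(nrow(df))),
      start = as.integer(df$start), end = as.integer(df$end),
      width_bins = as.integer(df$end - df$start + 1L),
      ppm_hi = fit_set$ppm[df$start] + hw / 2,
      ppm_lo = fit_set$ppm[df$end] - hw / 2,
      kind = df$kind, segment_id = as.integer(df$segment_id)
    )
    out
  }
  region_set(assemble(reg_list, "R"), assemble(drop_list, "D"),
             bin_width_ppm = hw, min_region_bins = min_region_bins,
             lambda = fit_set$lambda, method = "bf")
}

#' Sum linear-scale intensities over retained regions
#'
#' Produces the method's output: one feature per retained region, valued as
#' the sum of a sample's linear-scale intensities over the region's bins.
#' Refuses log-scale input -- the fit runs on log2 spectra but features are
#' always summed on the original linear intensities.
#'
#' @param s A linear-scale [spectrum_set()] on the axis the regions were
#'   built from.
#' @param rs A `region_set`.
#' @return A `feature_table`: `values` (n x m matrix), `regions` metadata,
#'   `region_set`, and a `provenance` list.
#' @export
summarize_features <- function(s, rs) {
  stopifnot(inherits(s, "spectrum_set"), inherits(rs, "region_set"))
  if (s$scale != "linear") {
    stop("feature summation requires linear-scale intensities", call. = FALSE)
  }
  p <- length(s$ppm)
  if (nrow(rs$regions) > 0 && max(rs$regions$end) > p) {
    stop("region set extends beyond the spectrum axis", call. = FALSE)
  }
  m <- nrow(rs$regions)
  vals <- matrix(0, nrow(s$intensities), m,
                 dimnames = list(s$sample_ids, rs$regions$region_id))
  for (r in seq_len(m)) {
    idx <- rs$regions$start[r]:rs$regions$end[r]
    vals[, r] <- rowSums(s$intensities[, idx, drop = FALSE])
  }
  if (m == 0) {
    warning("region set has no retained regions; feature table is empty",
            call. = FALSE)
  }
  feature_table(vals, rs$regions, region_set = rs,
                provenance = list(method = rs$method, lambda = rs$lambda,
                                  width_bins = rs$width_bins,
                                  bin_width_ppm = rs$bin_width_ppm,
                                  min_region_bins = rs$min_region_bins))
}

#' Apply a stored region set to new spectra
#'
#' Train/apply workflow: a segmentation learned on one cohort is applied to
#' held-out samples on the same axis, reproducing exactly the features the
#' full extraction would give those samples.
#'
#' @param s A linear-scale [spectrum_set()] on the same axis (checked by
#'   length and ppm agreement).
#' @param rs A `region_set`, e.g. from [read_region_set()].
#' @return A `feature_table`.
#' @export
apply_regions <- function(s, rs) {
  stopifnot(inherits(s, "spectrum_set"))
  summarize_features(s, rs)
}

#' Constructor for feature tables
#'
#' @param values n x m numeric matrix of summed linear intensities, samples
#'   in rows.
#' @param regions Region metadata tibble (one row per column of `values`).
#' @param region_set Optional full `region_set` (including dropped regions).
#' @param provenance Named list recording method and parameters.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, regions, region_set = NULL,
                          provenance = list()) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(regions)) {
    stop("feature values and region metadata disagree in size", call. = FALSE)
  }
  structure(list(values = values, regions = regions, region_set = region_set,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d regions (%s)\n",
              nrow(x$values), ncol(x$values),
              x$provenance$method %||% "unknown method"))
  invisible(x)
}

#' Tidy a feature table into a long tibble
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `region_id`, `kind`, `ppm_hi`, `ppm_lo`,
#'   `value`.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  m <- ncol(x$values)
  tibble::tibble(
    sample_id = rep(rownames(x$values), times = m),
    region_id = rep(x$regions$region_id, each = nrow(x$values)),
    kind = rep(x$regions$kind, each = nrow(x$values)),
    ppm_hi = rep(x$regions$ppm_hi, each = nrow(x$values)),
    ppm_lo = rep(x$regions$ppm_lo, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' One-row summary of a region set
#'
#' Counts of retained plateau / non-plateau / equidistant and dropped
#' regions, plus the mean plateau width in ppm
#' (`width_bins * bin_width_ppm`).
#'
#' @param rs A `region_set`.
#' @return A one-row tibble.
#' @export
region_summary <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  kinds <- rs$regions$kind
  pw <- rs$regions$width_bins[kinds == "plateau"] * rs$bin_width_ppm
  tibble::tibble(
    n_plateau = sum(kinds == "plateau"),
    n_non_plateau = sum(kinds == "non_plateau"),
    n_equidistant = sum(kinds == "equidistant"),
    n_dropped = nrow(rs$dropped),
    n_fused_boundaries = sum(rs$regions$width_bins[kinds == "plateau"] - 1L),
    mean_plateau_width_ppm = if (length(pw)) mean(pw) else 0
  )
}
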