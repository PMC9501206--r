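#' Consensus bucket extraction, end to end
#'
#' The full pipeline on a linear-scale spectrum set: log2 transform with
#' absolute-value handling ([log2_abs_transform()]), independent ADMM fit of
#' every contiguous included segment ([bf_solve_segments()]), region
#' construction from the exact zero structure of the fit
#' ([regions_from_fit()]), and feature summation on the original
#' linear-scale intensities ([summarize_features()]). Deterministic given
#' the input and parameters. Any normalization (PQN, internal standard)
#' should be applied to `s` beforehand, on the linear scale.
#'
#' @param s A linear-scale [spectrum_set()].
#' @param lambda Penalty strength; values around 1 suit 0.001 ppm resolution.
#' @param rho ADMM step size, default 1.
#' @param min_region_bins Minimum-width filter in bins, default 2.
#' @param zero_floor Passed to [log2_abs_transform()].
#' @param max_iter,tol_primal,tol_dual Passed to [bf_solve()].
#' @return A `bucket_fuse` object: `features` (a `feature_table`), `regions`
#'   (a `region_set`), `fit` (a `bf_fit_set`), and the parameters.
#' @examples
#' sim <- simulate_spectra(synthetic_config(n_samples = 6, p_positions = 120,
#'                                          seed = 1))
#' res <- bucket_fuse(sim$spectra, lambda = 1)
#' region_summary(res$regions)
#' @export
bucket_fuse <- function(s, lambda, rho = 1, min_region_bins = 2L,
                        zero_floor = NULL, max_iter = 10000L,
                        tol_primal = 1e-6, tol_dual = 1e-6) {
  stopifnot(inherits(s, "spectrum_set"))
  s_log <- log2_abs_transform(s, zero_floor)
  fit <- bf_solve_segments(s_log, lambda, rho, max_iter, tol_primal, tol_dual)
  rs <- regions_from_fit(fit, min_region_bins)
  ft <- summarize_features(s, rs)
  structure(
    list(features = ft, regions = rs, fit = fit,
         lambda = lambda, rho = rho, min_region_bins = min_region_bins),
    class = "bucket_fuse"
  )
}

#' @export
print.bucket_fuse <- function(x, ...) {
  rsum <- region_summary(x$regions)
  cat(sprintf(
    "<bucket_fuse> lambda = %g | %d plateau + %d non-plateau regions retained, %d dropped\n",
    x$lambda, rsum$n_plateau, rsum$n_non_plateau, rsum$n_dropped
  ))
  cat(sprintf("  mean plateau width %.4f ppm | %d samples x %d features\n",
              rsum$mean_plateau_width_ppm, nrow(x$features$values),
              ncol(x$features$values)))
  invisible(x)
}

#' @rdname tidy.bucket_fuse
#' @method glance bucket_fuse
#' @export
glance.bucket_fuse <- function(x, ...) {
  conv <- vapply(x$fit$fits, `[[`, logical(1), "converged")
  iters <- vapply(x$fit$fits, `[[`, integer(1), "iterations")
  obj <- vapply(x$fit$fits, `[[`, numeric(1), "objective")
  dplyr::bind_cols(
    tibble::tibble(lambda = x$lambda, rho = x$rho,
                   n_segments = length(x$fit$fits),
                   n_converged = sum(conv),
                   total_iterations = sum(iters),
                   objective = sum(obj)),
    region_summary(x$regions)
  )
}

#' Tidy methods for extraction results
#'
#' `tidy()` returns the retained (and optionally dropped) regions as a
#' tibble; `glance()` returns a one-row fit summary (convergence, objective,
#' region counts, mean plateau width).
#'
#' @param x A `bucket_fuse` object.
#' @param include_dropped Also list width-filtered regions, flagged by the
#'   `retained` column.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bucket_fuse
#' @export
tidy.bucket_fuse <- function(x, include_dropped = FALSE, ...) {
  out <- dplyr::mutate(x$regions$regions, retained = TRUE)
  if (include_dropped) {
    out <- dplyr::bind_rows(out,
                            dplyr::mutate(x$regions$dropped, retained = FALSE))
    out <- dplyr::arrange(out, .data$start)
  }
  out
}

#' Plot a fitted consensus segmentation
#'
#' Observed spectra (thin lines) with the fitted smoothed spectra overlaid
#' (dark lines) and retained regions shaded by kind -- plateaus in cyan,
#' non-plateau regions in yellow, the usual display of this segmentation.
#'
#' @param object A `bucket_fuse` object.
#' @param samples Optional subset of sample ids.
#' @param ppm_range Optional length-2 ppm window to zoom into.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bucket_fuse
#' @export
autoplot.bucket_fuse <- function(object, samples = NULL, ppm_range = NULL, ...) {
  fit <- object$fit
  df <- tibble::tibble(
    sample_id = rep(fit$sample_ids, times = length(fit$ppm)),
    ppm = rep(fit$ppm, each = length(fit$sample_ids)),
    fitted = as.vector(fit$B)
  )
  if (!is.null(samples)) df <- dplyr::filter(df, .data$sample_id %in% samples)
  if (!is.null(ppm_range)) {
    ppm_range <- sort(ppm_range)
    df <- dplyr::filter(df, .data$ppm >= ppm_range[1], .data$ppm <= ppm_range[2])
  }
  regs <- object$regions$regions
  if (!is.null(ppm_range) && nrow(regs) > 0) {
    regs <- dplyr::filter(regs, .data$ppm_lo <= ppm_range[2],
                          .data$ppm_hi >= ppm_range[1])
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$fitted,
                                         group = .data$sample_id)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey20", na.rm = TRUE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "fitted log2 intensity") +
    ggplot2::theme_minimal()
  if (nrow(regs) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = regs,
      ggplot2::aes(xmin = .data$ppm_hi, xmax = .data$ppm_lo, fill = .data$kind),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(plateau = "cyan3",
                                            non_plateau = "gold",
                                            equidistant = "grey60"))
  }
  gg
}
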