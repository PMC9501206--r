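#' Match quantified metabolites to their best-correlating feature
#'
#' For each absolutely quantified metabolite, computes Spearman's rank
#' correlation (average-rank tie handling, pairwise-complete observations)
#' against every feature and reports the feature with the largest
#' correlation. Ties on the correlation are broken by the leftmost feature
#' (lowest start index) for determinism. Metabolites with fewer than 3
#' paired observations are skipped with a note.
#'
#' @param ft A `feature_table`.
#' @param conc A concentration table: data frame or tibble with a
#'   `metabolite` column and one column per sample id, or a metabolites x
#'   samples matrix with dimnames. Missing values allowed.
#' @return A tibble with columns `metabolite`, `best_feature_id`, `rho`,
#'   `n_used`; skipped metabolites are recorded in the `skipped` attribute.
#' @export
best_feature_match <- function(ft, conc) {
  stopifnot(inherits(ft, "feature_table"))
  cm <- as_conc_matrix(conc)
  shared <- intersect(colnames(cm), rownames(ft$values))
  if (length(shared) == 0) stop("no shared samples", call. = FALSE)
  vals <- ft$values[shared, , drop = FALSE]
  starts <- ft$regions$start
  rows <- list(); skipped <- character(0)
  for (met in rownames(cm)) {
    y <- cm[met, shared]
    ok <- !is.na(y)
    if (sum(ok) < 3) {
      skipped <- c(skipped, met)
      next
    }
    rho <- suppressWarnings(
      stats::cor(vals[ok, , drop = FALSE], y[ok], method = "spearman")[, 1]
    )
    rho[is.na(rho)] <- -Inf # constant features carry no rank signal
    best <- which(rho == max(rho))
    best <- best[which.min(starts[best])]
    rows[[met]] <- tibble::tibble(
      metabolite = met,
      best_feature_id = ft$regions$region_id[best],
      rho = unname(rho[best]), n_used = sum(ok)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (length(skipped)) {
    message("skipped (fewer than 3 paired observations): ",
            paste(skipped, collapse = ", "))
  }
  attr(out, "skipped") <- skipped
  out
}

as_conc_matrix <- function(conc) {
  if (is.matrix(conc)) {
    storage.mode(conc) <- "double"
    return(conc)
  }
  df <- as.data.frame(conc)
  met_col <- which(names(df) %in% c("metabolite", "metabolite_id", "name"))[1]
  if (is.na(met_col)) stop("concentration table needs a metabolite column",
                           call. = FALSE)
  m <- as.matrix(df[, -met_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[met_col]])
  m
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test (Welch statistic with
#' Welch-Satterthwaite degrees of freedom, two-sided p), the test used for
#' per-feature differential analysis between two sample classes.
#'
#' @param x,y Numeric vectors of the two groups, each of length `>= 2`.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both groups have zero variance: statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Per-feature p-value histogram for a two-class comparison
#'
#' Runs [welch_t_test()] on every feature against a binary class label and
#' histograms the raw p-values over `[0, 1]`. No multiple-testing correction
#' is applied: the shape of the raw distribution (excess mass near zero over
#' the uniform background) is the diagnostic. Optionally the counts are
#' split by region kind, since plateau features are expected to carry more
#' signal than non-plateau ones. Zero-variance-in-both-groups features are
#' excluded and counted.
#'
#' @param ft A `feature_table`.
#' @param labels Binary class label per sample (factor, character or
#'   logical; length must match the sample count), each class `>= 2`.
#' @param bins Number of histogram bins over `[0, 1]`, default 20.
#' @param split_kinds Split counts by region kind, default `TRUE` when
#'   several kinds are present.
#' @param adjust Optional multiple-testing correction method passed to
#'   [stats::p.adjust()] and reported in an extra `p_adj` column; default
#'   none.
#' @return A `pvalue_histogram`: list with `counts` (tibble `bin_lo`,
#'   `bin_hi`, `kind`, `count`), `pvalues` (tibble `region_id`, `kind`, `p`),
#'   `excluded` (number of degenerate features), and `low_bin_excess`, the
#'   observed minus expected share of p-values in `[0, 0.05]` under
#'   uniformity.
#' @export
pvalue_histogram <- function(ft, labels, bins = 20L, split_kinds = NULL,
                             adjust = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  labels <- as.factor(labels)
  if (length(labels) != nrow(ft$values)) {
    stop("one label per sample required", call. = FALSE)
  }
  if (nlevels(labels) != 2 || any(table(labels) < 2)) {
    stop("two classes with at least 2 samples each required", call. = FALSE)
  }
  a <- labels == levels(labels)[1]
  pvals <- rep(NA_real_, ncol(ft$values))
  for (j in seq_len(ncol(ft$values))) {
    x <- ft$values[a, j]; y <- ft$values[!a, j]
    if (stats::var(x) == 0 && stats::var(y) == 0) next
    pvals[j] <- stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  keep <- !is.na(pvals)
  ptbl <- tibble::tibble(region_id = ft$regions$region_id[keep],
                         kind = ft$regions$kind[keep],
                         p = pvals[keep])
  if (!is.null(adjust)) ptbl$p_adj <- stats::p.adjust(ptbl$p, method = adjust)
  if (is.null(split_kinds)) split_kinds <- length(unique(ptbl$kind)) > 1
  brk <- seq(0, 1, length.out = bins + 1L)
  count_one <- function(p, kind) {
    h <- graphics::hist(p, breaks = brk, plot = FALSE, include.lowest = TRUE)
    tibble::tibble(bin_lo = brk[-length(brk)], bin_hi = brk[-1],
                   kind = kind, count = h$counts)
  }
  counts <- if (split_kinds) {
    dplyr::bind_rows(purrr::imap(split(ptbl$p, ptbl$kind), count_one))
  } else {
    count_one(ptbl$p, "all")
  }
  low <- mean(ptbl$p <= 0.05)
  structure(
    list(counts = counts, pvalues = ptbl, excluded = sum(!keep),
         bins = bins, low_bin_excess = low - 0.05),
    class = "pvalue_histogram"
  )
}

#' @export
print.pvalue_histogram <- function(x, ...) {
  cat(sprintf(
    "<pvalue_histogram> %d features tested (%d excluded), %d bins | [0,0.05] excess %+.3f\n",
    nrow(x$pvalues), x$excluded, x$bins, x$low_bin_excess
  ))
  invisible(x)
}

#' Plot a p-value histogram
#' @param object A `pvalue_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pvalue_histogram
#' @export
autoplot.pvalue_histogram <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge",
                      width = (object$counts$bin_hi - object$counts$bin_lo)[1]) +
    ggplot2::scale_fill_manual(values = c(plateau = "cyan3",
                                          non_plateau = "gold",
                                          equidistant = "grey60",
                                          all = "grey40")) +
    ggplot2::labs(x = "raw p-value", y = "feature count") +
    ggplot2::theme_minimal()
}

#' Permutation null of the p-value distribution
#'
#' Permutes the class labels uniformly at random `n_perm` times and records
#' the [pvalue_histogram()] of each replicate. Under permutation the null
#' holds for every feature, so pooled p-values should be close to uniform;
#' this is the calibration check for the differential analysis. Fully
#' reproducible given `seed`.
#'
#' @inheritParams pvalue_histogram
#' @param n_perm Number of permutation replicates (`>= 0`).
#' @param seed Integer seed (mandatory).
#' @return List of `pvalue_histogram` records, length `n_perm`.
#' @export
permutation_null <- function(ft, labels, n_perm, seed, bins = 20L) {
  stopifnot(n_perm >= 0, is.finite(seed))
  out <- vector("list", n_perm)
  if (n_perm == 0) return(out)
  rng <- local({
    set.seed(as.integer(seed))
    replicate(n_perm, sample(labels), simplify = FALSE)
  })
  for (r in seq_len(n_perm)) {
    out[[r]] <- pvalue_histogram(ft, rng[[r]], bins = bins, split_kinds = FALSE)
  }
  out
}
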