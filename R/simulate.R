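#' Configuration for the synthetic spectrum generator
#'
#' Describes an NMR-like simulation with known ground truth: a set of
#' metabolites, each contributing one or more (multiplet) peaks whose
#' amplitudes are driven by latent per-sample concentrations, whose
#' positions jitter slightly from sample to sample (the pH / ionic-strength
#' / temperature effect that motivates consensus bucketing), plus additive
#' noise with occasional small negative baseline values.
#'
#' Defaults describe the package's standard validation fixture: 40 samples,
#' 600 positions at 0.001 ppm (axis 4.0995 down to 3.5005 ppm), 4
#' metabolites with Lorentzian lines of 0.002-0.003 ppm half-width at
#' half-maximum, up to 0.004 ppm of per-sample jitter, log-normal
#' concentrations (sdlog 0.5) and noise with sd 0.02 on a unit peak-height
#' scale.
#'
#' @param n_samples,p_positions Stack dimensions.
#' @param bin_width_ppm Axis resolution, default 0.001 ppm.
#' @param ppm_max Chemical shift of the first (leftmost) position's bin
#'   center, default 4.0995.
#' @param peaks Tibble with columns `metabolite_id`, `center_ppm`,
#'   `lineshape` ("lorentzian" or "gaussian"), `halfwidth_ppm` (HWHM),
#'   `multiplicity`, `spacing_ppm` (intra-multiplet spacing); `NULL` for the
#'   default 4-metabolite layout.
#' @param jitter_ppm Maximum per-sample uniform shift of a metabolite's
#'   peaks (all peaks of one metabolite shift together), default 0.004.
#' @param conc_meanlog,conc_sdlog Log-normal concentration parameters.
#' @param noise_sd Additive Gaussian noise sd on the linear scale.
#' @param negative_baseline_prob Probability that a position receives an
#'   extra negative baseline dip, exercising the absolute-value rule of the
#'   log transform. Default 0.02.
#' @param concentrations Optional fixed metabolite x sample matrix of latent
#'   concentrations, overriding the log-normal draw (rownames must match the
#'   metabolite ids in `peaks`).
#' @param seed Mandatory integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 40L, p_positions = 600L,
                             bin_width_ppm = 0.001, ppm_max = 4.0995,
                             peaks = NULL, jitter_ppm = 0.004,
                             conc_meanlog = 0, conc_sdlog = 0.5,
                             noise_sd = 0.02, negative_baseline_prob = 0.02,
                             concentrations = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  ppm <- ppm_max - bin_width_ppm * (seq_len(p_positions) - 1L)
  if (is.null(peaks)) {
    span <- ppm_max - ppm[p_positions]
    centers <- ppm_max - span * c(0.15, 0.35, 0.38, 0.60, 0.82)
    peaks <- tibble::tibble(
      metabolite_id = c("met1", "met2", "met2", "met3", "met4"),
      center_ppm = centers,
      lineshape = "lorentzian",
      halfwidth_ppm = c(0.003, 0.002, 0.002, 0.0025, 0.003),
      multiplicity = c(1L, 2L, 1L, 3L, 1L),
      spacing_ppm = c(0, 0.004, 0, 0.004, 0)
    )
  }
  peaks <- tibble::as_tibble(peaks)
  rng <- range(ppm)
  if (any(peaks$center_ppm < rng[1] + jitter_ppm |
          peaks$center_ppm > rng[2] - jitter_ppm)) {
    stop("peak centers (plus jitter) must lie inside the ppm axis", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), p_positions = as.integer(p_positions),
         bin_width_ppm = bin_width_ppm, ppm = ppm, peaks = peaks,
         jitter_ppm = jitter_ppm, conc_meanlog = conc_meanlog,
         conc_sdlog = conc_sdlog, noise_sd = noise_sd,
         negative_baseline_prob = negative_baseline_prob,
         concentrations = concentrations,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

lineshape_eval <- function(kind, x, center, hwhm) {
  d <- x - center
  switch(kind,
         lorentzian = hwhm^2 / (hwhm^2 + d^2),
         gaussian = exp(-d^2 * log(2) / hwhm^2),
         stop("unknown lineshape: ", kind, call. = FALSE))
}

#' Generate a synthetic spectrum stack with known truth
#'
#' Each sample's intensity at position `j` is the sum over peaks of
#' `concentration(metabolite, sample) * lineshape(ppm_j; jittered center)`
#' plus additive Gaussian noise; a small fraction of positions additionally
#' receive a negative baseline dip. Multiplets are rendered as
#' `multiplicity` equally weighted sub-peaks centered on `center_ppm` and
#' spaced `spacing_ppm` apart. Deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `spectra` (a linear-scale [spectrum_set()]), `truth`
#'   (`concentrations` metabolite x sample matrix, `centers` tibble of
#'   realized per-sample peak centers, `supports` tibble of per-metabolite
#'   true index intervals covering all jittered peak positions), and `conc`
#'   (the concentration table in [best_feature_match()] layout).
#' @export
simulate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; ppm <- cfg$ppm
  mets <- unique(cfg$peaks$metabolite_id)
  conc <- if (is.null(cfg$concentrations)) {
    matrix(stats::rlnorm(length(mets) * n, cfg$conc_meanlog, cfg$conc_sdlog),
           nrow = length(mets),
           dimnames = list(mets, paste0("sample_", seq_len(n))))
  } else {
    m <- as.matrix(cfg$concentrations)[mets, , drop = FALSE]
    colnames(m) <- paste0("sample_", seq_len(n))
    m
  }
  shift <- matrix(stats::runif(length(mets) * n, -cfg$jitter_ppm, cfg$jitter_ppm),
                  nrow = length(mets), dimnames = list(mets, NULL))
  Y <- matrix(0, n, length(ppm))
  centers <- list()
  for (k in seq_len(nrow(cfg$peaks))) {
    pk <- cfg$peaks[k, ]
    offs <- (seq_len(pk$multiplicity) - (pk$multiplicity + 1) / 2) * pk$spacing_ppm
    for (i in seq_len(n)) {
      c0 <- pk$center_ppm + shift[pk$metabolite_id, i]
      amp <- conc[pk$metabolite_id, i] / pk$multiplicity
      for (o in offs) {
        Y[i, ] <- Y[i, ] + amp * lineshape_eval(pk$lineshape, ppm, c0 + o,
                                                pk$halfwidth_ppm)
      }
      centers[[length(centers) + 1L]] <- tibble::tibble(
        peak = k, metabolite_id = pk$metabolite_id,
        sample_id = colnames(conc)[i], center_ppm = c0
      )
    }
  }
  if (cfg$noise_sd > 0) {
    Y <- Y + matrix(stats::rnorm(length(Y), 0, cfg$noise_sd), nrow = n)
  }
  if (cfg$negative_baseline_prob > 0) {
    dip <- matrix(stats::runif(length(Y)) < cfg$negative_baseline_prob, nrow = n)
    Y[dip] <- Y[dip] - abs(stats::rnorm(sum(dip), 0, 2 * max(cfg$noise_sd, 1e-3)))
  }
  spectra <- spectrum_set(Y, ppm, sample_ids = colnames(conc))
  centers <- dplyr::bind_rows(centers)
  supports <- truth_supports(cfg, centers)
  conc_tbl <- tibble::as_tibble(conc, rownames = "metabolite")
  list(spectra = spectra,
       truth = list(concentrations = conc, centers = centers,
                    supports = supports),
       conc = conc_tbl)
}

# Per-metabolite index intervals covering every jittered sub-peak center
# +/- one half-width (merged across peaks where they touch).
truth_supports <- function(cfg, centers) {
  ppm <- cfg$ppm
  rows <- list()
  for (met in unique(cfg$peaks$metabolite_id)) {
    pk_ids <- which(cfg$peaks$metabolite_id == met)
    for (k in pk_ids) {
      pk <- cfg$peaks[k, ]
      cs <- centers$center_ppm[centers$peak == k]
      ext <- (pk$multiplicity - 1) / 2 * pk$spacing_ppm + pk$halfwidth_ppm
      hi <- max(cs) + ext; lo <- min(cs) - ext
      idx <- which(ppm <= hi & ppm >= lo)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite_id = met, start = min(idx), end = max(idx)
      )
    }
  }
  df <- dplyr::bind_rows(rows)
  # merge overlapping intervals per metabolite
  df <- dplyr::arrange(df, .data$metabolite_id, .data$start)
  out <- list()
  for (met in unique(df$metabolite_id)) {
    sub <- df[df$metabolite_id == met, ]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (r in seq_len(nrow(sub))[-1]) {
      if (sub$start[r] <= cur_e + 1L) {
        cur_e <- max(cur_e, sub$end[r])
      } else {
        out[[length(out) + 1L]] <- tibble::tibble(metabolite_id = met,
                                                  start = cur_s, end = cur_e)
        cur_s <- sub$start[r]; cur_e <- sub$end[r]
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(metabolite_id = met,
                                              start = cur_s, end = cur_e)
  }
  dplyr::bind_rows(out)
}

#' Score recovery of planted signals
#'
#' For each simulated metabolite, the best (maximum) Spearman correlation
#' between any feature and the true latent concentrations, plus the
#' fraction of the metabolite's true support covered by retained regions.
#'
#' @param ft A `feature_table` extracted from simulated spectra.
#' @param truth The `truth` component of [simulate_spectra()].
#' @return A tibble with `metabolite_id`, `best_rho`, `support_coverage`.
#' @export
recovery_score <- function(ft, truth) {
  stopifnot(inherits(ft, "feature_table"))
  conc <- truth$concentrations
  shared <- intersect(colnames(conc), rownames(ft$values))
  vals <- ft$values[shared, , drop = FALSE]
  covered <- rep(FALSE, max(c(ft$regions$end, truth$supports$end)))
  for (r in seq_len(nrow(ft$regions))) {
    covered[ft$regions$start[r]:ft$regions$end[r]] <- TRUE
  }
  rows <- purrr::map(rownames(conc), function(met) {
    rho <- if (ncol(vals) == 0) NA_real_ else {
      suppressWarnings(
        max(stats::cor(vals, conc[met, shared], method = "spearman"),
            na.rm = TRUE)
      )
    }
    sup <- truth$supports[truth$supports$metabolite_id == met, ]
    idx <- unlist(purrr::map2(sup$start, sup$end, seq))
    tibble::tibble(metabolite_id = met, best_rho = rho,
                   support_coverage = mean(covered[idx]))
  })
  dplyr::bind_rows(rows)
}
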