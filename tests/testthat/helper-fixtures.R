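# small deterministic fixtures shared across test files

rand_Y <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

toy_spectra <- function(vals = matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE),
                        ppm = c(3, 2, 1)) {
  spectrum_set(vals, ppm = ppm)
}

# independent scalar-loop evaluation of the penalized objective
loop_objective <- function(Y, B, lambda) {
  n <- nrow(Y); p <- ncol(Y)
  fid <- 0
  for (i in seq_len(n)) for (j in seq_len(p)) fid <- fid + (Y[i, j] - B[i, j])^2
  pen <- 0
  for (j in seq_len(p - 1)) {
    ss <- 0
    for (i in seq_len(n)) ss <- ss + (B[i, j] - B[i, j + 1])^2
    pen <- pen + sqrt(ss)
  }
  fid + lambda * sqrt(n) * pen
}

# feature table with synthetic values and minimal region metadata, for
# evaluation-module tests that need no spectra
toy_feature_table <- function(values, kinds = NULL) {
  m <- ncol(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(kinds)) kinds <- rep(c("plateau", "non_plateau"), length.out = m)
  starts <- seq(1L, by = 4L, length.out = m)
  regions <- tibble::tibble(
    region_id = sprintf("R%04d", seq_len(m)),
    start = starts, end = starts + 3L, width_bins = 4L,
    ppm_hi = 4 - 0.004 * (seq_len(m) - 1), ppm_lo = 4 - 0.004 * seq_len(m),
    kind = kinds, segment_id = 1L
  )
  colnames(values) <- regions$region_id
  feature_table(values, regions,
                provenance = list(method = "synthetic_fixture"))
}
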