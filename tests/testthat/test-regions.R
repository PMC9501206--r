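test_that("fused boundaries reflect the exact zero structure of G", {
  # no penalty: no fusion on generic noisy data
  fit0 <- bf_solve(rand_Y(2, 15, 7), 0)
  expect_false(any(fused_boundaries(fit0)))

  # huge penalty: one plateau spans the segment
  Y <- rand_Y(2, 15, 8)
  fitI <- bf_solve(Y, 1e6 * norm(Y, "F"))
  expect_true(all(fused_boundaries(fitI)))

  # piecewise-constant with a large jump: only the jump survives
  Yj <- matrix(c(rep(0, 5), rep(5, 5)), 1)
  fitj <- bf_solve(Yj, 1)
  fused <- fused_boundaries(fitj)
  expect_false(fused[5])
  expect_true(all(fused[-5]))

  # a non-converged state still yields a result, with a warning
  expect_warning(fbad <- bf_solve(rand_Y(3, 40, 9), 5, max_iter = 3L),
                 "did not converge")
  expect_warning(fused_boundaries(fbad), "converge")
})

test_that("region construction follows the run/complement/width-filter rules", {
  # fused boundaries between positions (4,5) and (5,6) of a 10-bin segment:
  # one 3-bin plateau with non-plateau flanks, everything retained
  fused <- rep(FALSE, 9); fused[4:5] <- TRUE
  rs <- build_regions(fused, min_region_bins = 2)
  expect_equal(rs$regions$start, c(1L, 4L, 7L))
  expect_equal(rs$regions$end, c(3L, 6L, 10L))
  expect_equal(rs$regions$kind, c("non_plateau", "plateau", "non_plateau"))
  expect_equal(nrow(rs$dropped), 0L)

  # a lone fused boundary gives a 2-bin plateau, which the filter drops;
  # the 2-bin right flank drops too
  fused2 <- rep(FALSE, 9); fused2[7] <- TRUE
  rs2 <- build_regions(fused2, min_region_bins = 2)
  expect_equal(rs2$regions$start, 1L)
  expect_equal(rs2$regions$end, 6L)
  expect_equal(rs2$regions$kind, "non_plateau")
  expect_equal(rs2$dropped$start, c(7L, 9L))
  expect_equal(rs2$dropped$end, c(8L, 10L))
  expect_equal(rs2$dropped$kind, c("plateau", "non_plateau"))

  # all fused: one plateau covering the segment
  rs3 <- build_regions(rep(TRUE, 9))
  expect_equal(nrow(rs3$regions), 1L)
  expect_equal(rs3$regions$start, 1L)
  expect_equal(rs3$regions$end, 10L)
  expect_equal(rs3$regions$kind, "plateau")

  # retained and dropped regions always tile the segment exactly
  set.seed(12)
  for (rep_i in 1:20) {
    f <- runif(14) < 0.5
    out <- build_regions(f)
    all_reg <- rbind(out$regions, out$dropped)
    all_reg <- all_reg[order(all_reg$start), ]
    expect_equal(all_reg$start, c(1L, utils::head(all_reg$end, -1) + 1L))
    expect_equal(all_reg$end[nrow(all_reg)], 15L)
  }
})

test_that("region summaries report counts and ppm widths", {
  fused <- rep(FALSE, 9); fused[4:5] <- TRUE
  local <- build_regions(fused)
  regs <- tibble::tibble(
    region_id = sprintf("R%04d", 1:3),
    start = local$regions$start, end = local$regions$end,
    width_bins = local$regions$end - local$regions$start + 1L,
    ppm_hi = 0, ppm_lo = 0, kind = local$regions$kind, segment_id = 1L
  )
  rs <- region_set(regs, empty_dropped <- regs[0, ], bin_width_ppm = 0.001)
  sm <- region_summary(rs)
  expect_equal(sm$n_plateau, 1L)
  expect_equal(sm$n_non_plateau, 2L)
  expect_equal(sm$n_dropped, 0L)
  expect_equal(sm$mean_plateau_width_ppm, 0.003)

  empty <- region_set(regs[0, ], regs[0, ], bin_width_ppm = 0.001)
  sm0 <- region_summary(empty)
  expect_equal(sm0$n_plateau + sm0$n_non_plateau + sm0$n_dropped, 0L)
  expect_equal(sm0$mean_plateau_width_ppm, 0)
})

test_that("feature summation sums linear intensities and conserves mass", {
  sim <- simulate_spectra(synthetic_config(n_samples = 5, p_positions = 200,
                                           seed = 13))
  res <- bucket_fuse(sim$spectra, lambda = 2.5)
  rs <- res$regions
  # all-ones check on a fresh spectrum with the same axis
  ones <- spectrum_set(matrix(1, 2, 200), ppm = sim$spectra$ppm)
  ft1 <- summarize_features(ones, rs)
  expect_equal(unname(ft1$values[1, ]), as.numeric(rs$regions$width_bins))

  # partition conservation: retained + dropped mass = total included mass
  ft <- res$features
  dropped_mass <- sum(vapply(seq_len(nrow(rs$dropped)), function(r) {
    sum(sim$spectra$intensities[, rs$dropped$start[r]:rs$dropped$end[r]])
  }, numeric(1)))
  total <- sum(sim$spectra$intensities[, sim$spectra$include])
  expect_equal(sum(ft$values) + dropped_mass, total, tolerance = 1e-9)

  expect_error(summarize_features(log2_abs_transform(sim$spectra), rs),
               "linear-scale")
  short <- spectrum_set(matrix(1, 1, 50), ppm = sim$spectra$ppm[1:50])
  expect_error(summarize_features(short, rs), "beyond")
})

test_that("hand-made two-region sums match hand arithmetic", {
  s <- spectrum_set(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 1),
                    ppm = seq(0.008, 0.001, by = -0.001))
  regs <- tibble::tibble(
    region_id = c("R0001", "R0002"), start = c(1L, 5L), end = c(3L, 8L),
    width_bins = c(3L, 4L), ppm_hi = c(0.0085, 0.0045),
    ppm_lo = c(0.0055, 0.0005), kind = c("plateau", "non_plateau"),
    segment_id = 1L
  )
  rs <- region_set(regs, regs[0, ], bin_width_ppm = 0.001)
  ft <- summarize_features(s, rs)
  expect_equal(unname(ft$values[1, ]), c(1 + 2 + 3, 5 + 6 + 7 + 8))
})

test_that("lambda = 0 extraction yields one unfused region per segment", {
  sim <- simulate_spectra(synthetic_config(n_samples = 3, p_positions = 80,
                                           seed = 14))
  s <- apply_exclusions(sim$spectra,
                        list(c(sim$spectra$ppm[30], sim$spectra$ppm[36])))
  res <- bucket_fuse(s, lambda = 0)
  expect_equal(nrow(res$regions$regions), 2L)
  expect_true(all(res$regions$regions$kind == "non_plateau"))
  expect_equal(region_summary(res$regions)$n_fused_boundaries, 0L)
})

test_that("the segmentation is a consensus: sample-independent and reusable", {
  sim <- simulate_spectra(synthetic_config(n_samples = 8, p_positions = 200,
                                           seed = 15))
  res <- bucket_fuse(sim$spectra, lambda = 2.5)

  # duplicating every sample leaves the boundaries unchanged
  dup <- spectrum_set(rbind(sim$spectra$intensities, sim$spectra$intensities),
                      ppm = sim$spectra$ppm,
                      sample_ids = c(sim$spectra$sample_ids,
                                     paste0("dup_", sim$spectra$sample_ids)))
  res_dup <- bucket_fuse(dup, lambda = 2.5)
  expect_equal(res_dup$regions$regions$start, res$regions$regions$start)
  expect_equal(res_dup$regions$regions$end, res$regions$regions$end)

  # applying the frozen region set to a sample subset reproduces those rows
  sub <- spectrum_set(sim$spectra$intensities[3:5, ], ppm = sim$spectra$ppm,
                      sample_ids = sim$spectra$sample_ids[3:5])
  ft_sub <- apply_regions(sub, res$regions)
  expect_identical(ft_sub$values, res$features$values[3:5, , drop = FALSE])
})

test_that("mean plateau width grows with the penalty on a fixed fixture", {
  sim <- simulate_spectra(synthetic_config(n_samples = 10, p_positions = 300,
                                           seed = 16))
  widths <- vapply(c(1, 2.5, 5), function(lam) {
    region_summary(bucket_fuse(sim$spectra, lambda = lam)$regions)$mean_plateau_width_ppm
  }, numeric(1))
  expect_false(is.unsorted(widths))
})
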