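test_that("objective matches an independent scalar-loop evaluation", {
  Y <- rand_Y(2, 4, seed = 21)
  B <- rand_Y(2, 4, seed = 22)
  expect_equal(bf_objective(Y, B, 1.7), loop_objective(Y, B, 1.7))

  # B = Y: fidelity term vanishes, penalty-only value
  pen <- sum(sqrt(colSums((Y[, -4] - Y[, -1])^2)))
  expect_equal(bf_objective(Y, Y, 3), 3 * sqrt(2) * pen)

  # B = broadcast row means: penalty vanishes, fidelity-only value
  Bm <- matrix(rowMeans(Y), 2, 4)
  expect_equal(bf_objective(Y, Bm, 3), sum((Y - Bm)^2))

  expect_error(bf_objective(Y, Y[, 1:3], 1), "shape")
})

test_that("group soft-thresholding has an exact deadzone and norm shift", {
  expect_identical(prox_group(c(0.3, 0.4), 0.5), c(0, 0)) # boundary case
  expect_equal(prox_group(c(3, 4), 0), c(3, 4))
  expect_equal(prox_group(c(3, 4), 2.5), c(1.5, 2.0))
  expect_identical(prox_group(numeric(3), 2), c(0, 0, 0))
})

test_that("B-update solves its defining tridiagonal system", {
  # 1 x 2 hand example: (I + D t(D)) = [[2,-1],[-1,2]], Y = (3, 0) -> B = (2, 1)
  ch <- bucketfuse:::fusion_factor(2, rho = 2)
  B <- bucketfuse:::admm_b_update(matrix(c(3, 0), 1), matrix(0, 1, 1),
                                  matrix(0, 1, 1), rho = 2, ch)
  expect_equal(as.vector(B), c(2, 1))

  # constant rows are fixed points (row sums of D t(D) are zero)
  Yc <- matrix(c(rep(2.5, 6), rep(-1, 6)), 2, 6, byrow = TRUE)
  ch6 <- bucketfuse:::fusion_factor(6, rho = 1.3)
  Bc <- bucketfuse:::admm_b_update(Yc, matrix(0, 2, 5), matrix(0, 2, 5), 1.3, ch6)
  expect_equal(Bc, Yc, tolerance = 1e-12)

  # residual check against the defining linear system, dense-built here
  set.seed(31)
  n <- 3; p <- 12; rho <- 0.7
  Y <- rand_Y(n, p, 31); G <- rand_Y(n, p - 1, 32); U <- rand_Y(n, p - 1, 33)
  ch2 <- bucketfuse:::fusion_factor(p, rho)
  B2 <- bucketfuse:::admm_b_update(Y, G, U, rho, ch2)
  Dm <- -t(diff(diag(p))) # p x (p-1): +1 at row j, -1 at row j+1 of column j
  A <- diag(p) + (rho / 2) * Dm %*% t(Dm)
  rhs <- Y + (rho / 2) * (G - U / rho) %*% t(Dm)
  expect_lt(norm(B2 %*% A - rhs, "F"), 1e-10 * norm(Y, "F"))
})

test_that("G-update equals column-wise proximal steps", {
  set.seed(41)
  n <- 2; p <- 8; rho <- 1.4; lam <- 0.9
  B <- rand_Y(n, p, 41); U <- rand_Y(n, p - 1, 42)
  G <- bucketfuse:::admm_g_update(B, U, rho, lam, n)
  Z <- (B[, -p] - B[, -1]) + U / rho
  thr <- lam * sqrt(n) / rho
  for (j in seq_len(p - 1)) {
    expect_equal(G[, j], prox_group(Z[, j], thr))
  }
  # lambda = 0: identity on B D + U/rho
  expect_equal(bucketfuse:::admm_g_update(B, U, rho, 0, n), Z)
  # a column inside the deadzone comes back exactly zero
  Bz <- matrix(1, 2, 3); Uz <- matrix(0, 2, 2)
  Gz <- bucketfuse:::admm_g_update(Bz, Uz, 1, lambda = 5, n = 2)
  expect_identical(Gz, matrix(0, 2, 2))
})

test_that("dual update accumulates the scaled primal residual", {
  set.seed(51)
  B <- rand_Y(2, 6, 51); U0 <- matrix(0, 2, 5); rho <- 1
  G_feas <- B[, -6] - B[, -1]
  expect_equal(bucketfuse:::admm_u_update(U0, B, G_feas, rho), U0)
  G <- rand_Y(2, 5, 52)
  U1 <- bucketfuse:::admm_u_update(U0, B, G, rho)
  expect_equal(U1, G_feas - G)
  U2 <- bucketfuse:::admm_u_update(U1, B, G, rho)
  expect_equal(U2, 2 * (G_feas - G)) # successive updates compose additively
})

test_that("lambda = 0 returns the input exactly, with no fused boundaries", {
  Y <- rand_Y(3, 25, seed = 61)
  fit <- bf_solve(Y, 0)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$B - Y)), 1e-8)
  expect_false(any(fused_boundaries(fit)))
})

test_that("huge lambda collapses every row to its mean in one plateau", {
  Y <- rand_Y(5, 50, seed = 62)
  fit <- bf_solve(Y, 1e6 * norm(Y, "F"))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$B - rowMeans(Y))), 1e-4)
  expect_true(all(fused_boundaries(fit)))
})

test_that("solution is optimal against the certified dual-gap reference", {
  for (case in list(list(n = 2, p = 15, lam = 0.5, seed = 71),
                    list(n = 3, p = 24, lam = 2, seed = 72),
                    list(n = 1, p = 30, lam = 8, seed = 73))) {
    Y <- rand_Y(case$n, case$p, case$seed)
    fit <- bf_solve(Y, case$lam, tol_primal = 1e-9, tol_dual = 1e-9,
                    max_iter = 200000)
    ref <- bf_reference_fit(Y, case$lam)
    expect_true(ref$converged)
    expect_lt(abs(fit$objective - ref$objective) / ref$objective, 1e-6)
    # both are feasible points, so neither trivial candidate can beat the fit
    expect_lte(fit$objective,
               min(bf_objective(Y, Y, case$lam),
                   bf_objective(Y, matrix(rowMeans(Y), case$n, case$p),
                                case$lam)) + 1e-8)
  }
})

test_that("solver commutes with row permutation, column reversal, and shifts", {
  Y <- rand_Y(3, 20, seed = 81)
  lam <- 2
  fit <- bf_solve(Y, lam)
  perm <- c(3, 1, 2)
  expect_equal(bf_solve(Y[perm, ], lam)$B, fit$B[perm, ], tolerance = 1e-12)
  expect_equal(bf_solve(Y[, 20:1], lam)$B, fit$B[, 20:1], tolerance = 1e-8)
  expect_equal(bf_solve(Y + 3.25, lam)$B, fit$B + 3.25, tolerance = 1e-8)
})

test_that("G columns are exactly zero or have positive norm", {
  Y <- cbind(rand_Y(2, 5, 91), rand_Y(2, 5, 92) + 10)
  fit <- bf_solve(Y, 1.5)
  cn <- sqrt(colSums(fit$G^2))
  expect_true(all(cn == 0 | cn > 0))
  expect_true(any(cn == 0)) # fusion actually occurred somewhere
  expect_true(any(cn > 0))
  # accepted convergence respects the scaled primal tolerance
  expect_lte(fit$primal_residual,
             fit$tol_primal * sqrt(fit$n * (fit$p - 1)))
})

test_that("per-segment solving equals independent solves", {
  set.seed(101)
  Y <- matrix(rlnorm(3 * 30), 3, 30)
  s <- spectrum_set(Y, ppm = seq(0.0295, by = -0.001, length.out = 30))
  s <- apply_exclusions(s, list(c(0.0175, 0.0155))) # split into two segments
  s_log <- log2_abs_transform(s, 1e-9)
  fs <- bf_solve_segments(s_log, lambda = 1.2)
  segs <- fs$segments
  expect_equal(nrow(segs), 2L)
  for (k in 1:2) {
    idx <- segs$start[k]:segs$end[k]
    solo <- bf_solve(s_log$intensities[, idx, drop = FALSE], 1.2)
    expect_equal(fs$fits[[k]]$B, solo$B)
    expect_equal(fs$fits[[k]]$iterations, solo$iterations)
  }
  expect_true(all(is.na(fs$B[, !s$include])))

  # one full-axis segment reduces to a single solve
  s_full <- log2_abs_transform(spectrum_set(Y, seq(0.0295, by = -0.001,
                                                   length.out = 30)), 1e-9)
  fs2 <- bf_solve_segments(s_full, lambda = 1.2)
  expect_equal(fs2$fits[[1]]$B,
               bf_solve(s_full$intensities, 1.2)$B)
  expect_error(bf_solve_segments(s_full, lambda = -1), "lambda")
})
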