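#' Certified reference solution of the fused group lasso problem
#'
#' Solves the same convex program as [bf_solve()] by a completely different
#' route, for validation: accelerated projected gradient ascent on the
#' Fenchel dual. Writing `c = lambda/n`, the dual of
#' `min_B ||Y - B||_F^2 + c * sum_j ||(B D)_.j||_2` is
#' `max_V <V, Y D> - (1/4) ||V t(D)||_F^2` over matrices `V` whose columns
#' satisfy `||V_.j||_2 <= c`, with the primal recovered as
#' `B = Y - (1/2) V t(D)`. Strong duality holds, so the duality gap
#' `f(B) - g(V)` certifies how far the returned primal value is from the
#' true optimum -- independently of any iterative tolerance of the solver
#' under test.
#'
#' Intended for small instances in validation work; the production path is
#' [bf_solve()].
#'
#' @param Y n x p numeric matrix.
#' @param lambda Penalty strength `>= 0`.
#' @param n Sample count for the `lambda * sqrt(n)` coefficient; defaults
#'   to `nrow(Y)`.
#' @param tol_gap Stop when the duality gap falls below
#'   `tol_gap * max(1, |f(B)|)`. Default 1e-9.
#' @param max_iter Iteration cap for the accelerated ascent (with function
#'   restarts). Default 2e5.
#' @return A list: `B` (optimal fit), `objective` (primal value), `dual`
#'   (dual value, a lower bound on the optimum), `gap`, `iterations`,
#'   `converged`.
#' @export
bf_reference_fit <- function(Y, lambda, n = nrow(Y), tol_gap = 1e-9,
                             max_iter = 200000L) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  cc <- lambda * sqrt(n)
  if (cc == 0) {
    return(list(B = Y, objective = 0, dual = 0, gap = 0, iterations = 0L,
                converged = TRUE))
  }
  YD <- diff_right(Y)
  proj <- function(V) {
    cn <- sqrt(colSums(V^2))
    f <- ifelse(cn > cc, cc / cn, 1)
    V * rep(f, each = nrow(V))
  }
  # minimize h(V) = (1/4)||V t(D)||^2 - <V, YD>; grad = (1/2)(V t(D))D - YD
  hval <- function(V) {
    VDt <- diff_t_right(V)
    0.25 * sum(VDt^2) - sum(V * YD)
  }
  step <- 0.5 # 1/L with L = ||t(D) D||/2 <= 2
  V <- matrix(0, nrow(Y), p - 1L)
  Z <- V
  th <- 1
  h_prev <- Inf
  gap <- Inf
  primal <- NA_real_
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    grad <- 0.5 * diff_right(diff_t_right(Z)) - YD
    V_new <- proj(Z - step * grad)
    h_new <- hval(V_new)
    if (h_new > h_prev) { # function restart
      th <- 1
      Z <- V
      grad <- 0.5 * diff_right(diff_t_right(Z)) - YD
      V_new <- proj(Z - step * grad)
      h_new <- hval(V_new)
    }
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    Z <- V_new + ((th - 1) / th_new) * (V_new - V)
    V <- V_new
    th <- th_new
    h_prev <- h_new
    if (k %% 25L == 0L || k == max_iter) {
      B <- Y - 0.5 * diff_t_right(V)
      primal <- bf_objective(Y, B, lambda, n)
      gap <- primal + h_new # g(V) = -h(V)
      if (gap <= tol_gap * max(1, abs(primal))) break
    }
  }
  B <- Y - 0.5 * diff_t_right(V)
  primal <- bf_objective(Y, B, lambda, n)
  gap <- primal + hval(V)
  list(B = B, objective = primal, dual = -hval(V), gap = gap,
       iterations = k, converged = gap <= tol_gap * max(1, abs(primal)))
}
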