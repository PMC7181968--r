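#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex for problems of the form
#' \deqn{\max\ c^T x \quad s.t.\ A x = b,\ l \le x \le u,}
#' the shape flux balance analysis produces (equality mass balance plus box
#' bounds on fluxes). Phase 1 drives artificial variables out of an identity
#' basis; phase 2 optimizes the true objective. Nonbasic variables sit at a
#' bound (or at zero when free); bound flips are handled without a basis
#' change. The basis inverse is maintained by product-form updates with
#' periodic refactorization, and the pivot rule falls back from Dantzig to
#' Bland's rule after a run of degenerate steps, which guarantees
#' termination.
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Constraint matrix (m x n); equality rows only.
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds (length n); infinities allowed.
#' @param maximize Maximize (default) or minimize.
#' @param tol Feasibility tolerance.
#' @return List with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{objective}, and \code{x} (solution vector;
#'   \code{NULL} unless optimal).
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible", objective = NA_real_, x = NULL))
  obj <- if (maximize) as.numeric(obj) else -as.numeric(obj)
  sense <- if (maximize) 1 else -1

  # initial nonbasic values: the finite bound nearest zero; 0 for free vars
  start_val <- function(l, u) {
    if (is.finite(l) && is.finite(u)) { if (abs(l) <= abs(u)) l else u }
    else if (is.finite(l)) l else if (is.finite(u)) u else 0
  }
  xN0 <- mapply(start_val, lb, ub)
  r <- b - as.vector(A %*% xN0)
  s <- ifelse(r >= 0, 1, -1)

  # augmented problem: n structural + m artificial columns
  Aa <- cbind(A, diag(s, nrow = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  vals <- c(xN0, abs(r))         # current value of every variable
  basis <- n + seq_len(m)        # artificials basic
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))
  Binv <- diag(1 / s, nrow = m)

  run_simplex <- function(cost, phase) {
    degen <- 0L
    iter <- 0L
    max_iter <- 200L * (n + m) + 1000L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("simplex iteration limit reached (", max_iter, "); LP may be cycling")
      if (iter %% 60L == 0L)  # refactorize to limit update drift
        Binv <<- solve(Aa[, basis, drop = FALSE])
      nb <- which(!in_basis)
      xN <- vals[nb]
      xB <- as.vector(Binv %*% (b - Aa[, nb, drop = FALSE] %*% xN))
      vals[basis] <<- xB
      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost[nb] - as.vector(crossprod(Aa[, nb, drop = FALSE], y))

      at_lb <- abs(xN - lba[nb]) <= 1e-7
      at_ub <- abs(xN - uba[nb]) <= 1e-7
      can_up <- (at_lb | (!at_lb & !at_ub)) & (uba[nb] - xN > tol) & (d > tol)
      can_dn <- (at_ub | (!at_lb & !at_ub)) & (xN - lba[nb] > tol) & (d < -tol)
      cand <- which(can_up | can_dn)
      if (!length(cand)) {
        return(list(status = "optimal",
                    objective = sum(cost[basis] * xB) + sum(cost[nb] * xN)))
      }
      use_bland <- degen > 2L * (n + m)
      pick <- if (use_bland) cand[which.min(nb[cand])] else cand[which.max(abs(d[cand]))]
      q <- nb[pick]
      delta <- if (can_up[pick]) 1 else -1
      w <- as.vector(Binv %*% Aa[, q])

      # ratio test: entering variable's own range, then basic variables
      t_own <- if (delta > 0) uba[q] - vals[q] else vals[q] - lba[q]
      coef <- -delta * w
      t_best <- t_own; leave <- 0L; leave_to <- NA_character_
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (coef[i] < -tol) {
          ti <- (xB[i] - lba[bi]) / (-coef[i])
          if (ti < t_best - 1e-12) { t_best <- ti; leave <- i; leave_to <- "lb" }
        } else if (coef[i] > tol) {
          ti <- (uba[bi] - xB[i]) / coef[i]
          if (ti < t_best - 1e-12) { t_best <- ti; leave <- i; leave_to <- "ub" }
        }
      }
      if (!is.finite(t_best))
        return(list(status = "unbounded", objective = Inf))
      t_best <- max(t_best, 0)
      degen <- if (t_best <= tol) degen + 1L else 0L

      if (leave == 0L) {
        # bound flip: entering variable crosses its box, basis unchanged
        vals[q] <<- vals[q] + delta * t_best
      } else {
        out <- basis[leave]
        vals[q] <<- vals[q] + delta * t_best
        vals[out] <<- if (leave_to == "lb") lba[out] else uba[out]
        basis[leave] <<- q
        in_basis[q] <<- TRUE
        in_basis[out] <<- FALSE
        # product-form update of the basis inverse
        piv <- w[leave]
        Brow <- Binv[leave, ] / piv
        Binv <<- Binv - outer(w, Brow)
        Binv[leave, ] <<- Brow
      }
    }
  }

  # phase 1: minimize artificial mass (maximize its negative)
  cost1 <- c(rep(0, n), rep(-1, m))
  r1 <- run_simplex(cost1, phase = 1L)
  if (r1$status != "optimal" || -r1$objective > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  # pin artificials at zero and optimize the true objective
  uba[n + seq_len(m)] <- 0
  vals[n + seq_len(m)][!in_basis[n + seq_len(m)]] <- 0
  cost2 <- c(obj, rep(0, m))
  r2 <- run_simplex(cost2, phase = 2L)
  if (r2$status != "optimal")
    return(list(status = r2$status,
                objective = if (r2$status == "unbounded") sense * Inf else NA_real_,
                x = NULL))
  x <- vals[seq_len(n)]
  # clip roundoff-level bound violations
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", objective = sense * sum(obj * x), x = x)
}

#' Test feasibility of a bounded-variable equality system
#'
#' Runs phase 1 of [lp_solve()] only: is there \eqn{x} with \eqn{Ax = b},
#' \eqn{l \le x \le u}?
#'
#' @inheritParams lp_solve
#' @return Logical scalar.
#' @export
lp_feasible <- function(A, b, lb, ub, tol = 1e-9) {
  res <- lp_solve(rep(0, ncol(as.matrix(A))), A, b, lb, ub,
                  maximize = TRUE, tol = tol)
  res$status == "optimal"
}
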