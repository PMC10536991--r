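#' Convex quadratic programming
#'
#' The repulsive potential and linear reference energy are fit by a convex
#' quadratic program: a least-squares objective in the spline coefficients
#' subject to linear inequality constraints (curvature sign conditions on a
#' dense distance grid). Two independent solvers are provided: a primal-dual
#' interior-point method (the workhorse) and a projected-gradient method on
#' the dual (used as an algorithmically independent cross-check).
#'
#' Problem form: minimize 1/2 x' Q x + c' x subject to A x >= b.
#'
#' @name qp
NULL

#' Interior-point solver for a convex QP
#'
#' Mehrotra-style primal-dual interior-point method for
#' \code{min 1/2 x'Qx + c'x} subject to \code{A x >= b}. \code{Q} must be
#' symmetric positive definite.
#'
#' @param Q positive-definite matrix (n x n)
#' @param c linear coefficient vector (n)
#' @param A constraint matrix (m x n); may have zero rows for an
#'   unconstrained solve
#' @param b constraint right-hand side (m)
#' @param tol convergence tolerance on scaled residuals and duality gap
#'   (default 1e-10)
#' @param max_iter maximum iterations (default 100)
#' @param x0 optional starting point (the optimum of a convex program does
#'   not depend on it; exposed for restart-invariance checks)
#' @return list with \code{x}, \code{lambda} (dual multipliers),
#'   \code{objective}, \code{iterations}, \code{converged},
#'   \code{max_violation} (most negative slack, 0 if feasible)
#' @export
qp_solve_ip <- function(Q, c, A, b, tol = 1e-10, max_iter = 100L, x0 = NULL) {
  n <- length(c)
  m <- if (is.null(A)) 0L else nrow(A)
  if (m == 0L) {
    x <- solve(Q, -c)
    return(list(x = drop(x), lambda = numeric(0),
                objective = 0.5 * sum(x * (Q %*% x)) + sum(c * x),
                iterations = 0L, converged = TRUE, max_violation = 0))
  }
  scale0 <- max(1, max(abs(Q)), max(abs(c)))
  x <- if (!is.null(x0)) as.numeric(x0)
       else tryCatch(drop(solve(Q, -c)), error = function(e) numeric(n))
  s <- pmax(drop(A %*% x) - b, 1)
  lam <- rep(1, m)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Ax <- drop(A %*% x)
    rd <- drop(Q %*% x) + c - drop(crossprod(A, lam))   # dual residual
    rp <- Ax - s - b                                    # primal residual
    mu <- sum(s * lam) / m
    if (max(abs(rd)) < tol * scale0 && max(abs(rp)) < tol * scale0 &&
        mu < 0.01 * tol * scale0) {
      converged <- TRUE
      break
    }
    d <- lam / s
    M <- Q + crossprod(A * sqrt(d))
    jitter <- 1e-12 * max(diag(M))
    R <- NULL
    for (try in 1:8) {
      R <- tryCatch(chol(M), error = function(e) NULL)
      if (!is.null(R)) break
      M <- M + diag(jitter, n)
      jitter <- jitter * 100
    }
    if (is.null(R)) stop("KKT system not positive definite; add ridge to Q")
    solve_kkt <- function(rd_, rc_) {
      # eliminate ds and dlam; rc_ is the complementarity rhs (target of
      # S dlam + Lam ds = rc_ - S Lam e form, passed as vector)
      tmp <- -rd_ + drop(crossprod(A, (rc_ - lam * rp) / s))
      dx <- backsolve(R, backsolve(R, tmp, transpose = TRUE))
      ds <- drop(A %*% dx) + rp
      dlam <- (rc_ - lam * ds) / s
      list(dx = dx, ds = ds, dlam = dlam)
    }
    # affine (predictor) direction: rc = -s*lam
    aff <- solve_kkt(rd, -s * lam)
    if (!all(is.finite(aff$dx))) break
    alpha_p <- .step_frac(s, aff$ds)
    alpha_d <- .step_frac(lam, aff$dlam)
    mu_aff <- sum((s + alpha_p * aff$ds) * (lam + alpha_d * aff$dlam)) / m
    sigma <- min(max((mu_aff / mu)^3, 0), 1)
    # corrector
    cor <- solve_kkt(rd, -s * lam - aff$ds * aff$dlam + sigma * mu)
    if (!all(is.finite(cor$dx))) break
    alpha_p <- 0.995 * .step_frac(s, cor$ds)
    alpha_d <- 0.995 * .step_frac(lam, cor$dlam)
    x <- x + alpha_p * cor$dx
    s <- pmax(s + alpha_p * cor$ds, 1e-300)
    lam <- pmax(lam + alpha_d * cor$dlam, 1e-300)
  }
  viol <- min(drop(A %*% x) - b, 0)
  list(x = drop(x), lambda = lam,
       objective = 0.5 * sum(x * drop(Q %*% x)) + sum(c * x),
       iterations = iter, converged = converged, max_violation = -viol)
}

.step_frac <- function(v, dv) {
  neg <- dv < 0
  if (!any(neg)) return(1)
  min(1, min(-v[neg] / dv[neg]))
}

#' Projected-gradient (dual) solver for a convex QP
#'
#' Solves the same problem as \code{\link{qp_solve_ip}} by accelerated
#' projected gradient (FISTA) on the Lagrange dual, which has simple
#' non-negativity constraints. Slower but algorithmically independent;
#' intended for cross-checking optima on moderate problem sizes.
#'
#' @inheritParams qp_solve_ip
#' @param max_iter maximum FISTA iterations (default 20000)
#' @param tol stop when the projected gradient norm falls below
#'   \code{tol * scale}
#' @return list with \code{x}, \code{lambda}, \code{objective},
#'   \code{iterations}
#' @export
qp_solve_dual_pg <- function(Q, c, A, b, tol = 1e-12, max_iter = 20000L) {
  Qi <- solve(Q)
  xf <- function(lam) drop(Qi %*% (crossprod(A, lam) - c))
  gradf <- function(lam) drop(A %*% xf(lam)) - b  # gradient of -(dual)
  # Lipschitz constant of the dual gradient: ||A Q^-1 A'||_2 by power iteration
  v <- rep(1, nrow(A))
  for (i in 1:60) {
    w <- drop(A %*% (Qi %*% crossprod(A, v)))
    nv <- sqrt(sum(w^2))
    if (nv == 0) break
    v <- w / nv
  }
  L <- 1.05 * max(nv, 1e-12)
  lam <- rep(0, nrow(A))
  y <- lam
  tk <- 1
  scale0 <- max(1, max(abs(b)), sqrt(sum(c^2)))
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- gradf(y)
    lam_new <- pmax(y - g / L, 0)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- lam_new + ((tk - 1) / tk_new) * (lam_new - lam)
    # restart on non-monotone momentum
    if (sum((lam_new - lam) * (y - lam_new)) < 0) {
      y <- lam_new
      tk_new <- 1
    }
    moved <- max(abs(lam_new - lam))
    lam <- lam_new
    tk <- tk_new
    pg <- lam - pmax(lam - gradf(lam), 0)
    if (it %% 50 == 0 && max(abs(pg)) < tol * scale0 && moved < tol * scale0)
      break
  }
  x <- xf(lam)
  list(x = x, lambda = lam,
       objective = 0.5 * sum(x * drop(Q %*% x)) + sum(c * x),
       iterations = it)
}
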