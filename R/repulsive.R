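#' Repulsive-potential and reference-energy fitting
#'
#' Energy comparisons between methods act on atomization energies. This is
#' implemented through a linear reference energy
#' \deqn{E_ref = \sum_Z N_Z C_Z^{ref} + C_0^{ref}}
#' whose coefficients are obtained by least squares on the energy
#' differences between two methods. During training the reference energy is
#' folded into the repulsive fit: with the electronic parameters held fixed,
#' the residual target energy is fit jointly by the pairwise repulsive
#' splines and the reference coefficients. Because both are linear in their
#' coefficients and the shape constraints are linear inequalities, this is a
#' convex quadratic program with a global optimum.
#'
#' @name repulsive_ref
NULL

#' Element counts of an empirical formula string
#' @param formula canonical formula such as \code{"C2H6O1"}
#' @return named integer vector of element counts
#' @export
formula_counts <- function(formula) {
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  syms <- gsub("\\d+", "", parts)
  digits <- gsub("[A-Za-z]+", "", parts)
  cnts <- ifelse(nchar(digits), suppressWarnings(as.integer(digits)), 1L)
  out <- stats::setNames(rep(0L, length(unique(syms))), unique(syms))
  for (i in seq_along(syms)) out[syms[i]] <- out[syms[i]] + cnts[i]
  out
}

# formulas argument: character vector of formulas or a tb_dataset
.formula_design <- function(formulas, elements = NULL) {
  if (inherits(formulas, "tb_dataset")) formulas <- dataset_formulas(formulas)
  counts <- lapply(formulas, formula_counts)
  if (is.null(elements))
    elements <- sort(unique(unlist(lapply(counts, names))))
  X <- matrix(0, length(formulas), length(elements) + 1L,
              dimnames = list(NULL, c(elements, "c0")))
  for (i in seq_along(counts)) {
    ci <- counts[[i]]
    ci <- ci[names(ci) %in% elements]
    X[i, names(ci)] <- ci
  }
  X[, "c0"] <- 1
  X
}

#' Least-squares fit of the linear reference energy between two methods
#'
#' Fits \code{energies_b - energies_a} by \code{sum_Z N_Z C_Z + C_0}. The
#' residuals of this fit are the method-comparison errors; their MAE is the
#' headline comparison metric.
#'
#' @param energies_a,energies_b total energies (Hartree) of the same
#'   configurations under two methods
#' @param formulas empirical formulas (character vector or
#'   \code{tb_dataset})
#' @return list: \code{reference} (list \code{c_elements}, \code{c0}),
#'   \code{residuals} (Hartree, b - a - fit), \code{mae_ha},
#'   \code{mae_kcal}, \code{design}
#' @export
fit_reference_energy <- function(energies_a, energies_b, formulas,
                                 allow_rank_deficient = FALSE) {
  stopifnot(length(energies_a) == length(energies_b))
  X <- .formula_design(formulas)
  if (nrow(X) != length(energies_a))
    stop("formulas and energies have different lengths")
  y <- energies_b - energies_a
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (!allow_rank_deficient) {
      stop("rank-deficient reference design: collinear column(s) ",
           paste(drop_cols, collapse = ", "),
           " (e.g. all formulas identical); add compositional variety, or ",
           "set allow_rank_deficient = TRUE (the residuals are unaffected)")
    }
    # the projection (and hence the residuals) is well defined regardless of
    # rank; unidentified coefficients are reported as 0
    beta <- qr.coef(qrX, y)
    beta[is.na(beta)] <- 0
  } else {
    beta <- qr.coef(qrX, y)
  }
  res <- y - drop(X %*% beta)
  elements <- setdiff(colnames(X), "c0")
  list(reference = list(c_elements = stats::setNames(beta[elements], elements),
                        c0 = unname(beta["c0"])),
       residuals = res,
       mae_ha = mean(abs(res)),
       mae_kcal = mean(abs(res)) * KCAL_PER_HA,
       design = X)
}

# Design matrix mapping the joint repulsive + reference coefficient vector
# to per-configuration energies. Columns: free coefficients of each
# repulsive spline (sorted keys), then element reference columns, then c0.
.repulsive_design <- function(ds, ps, rep_keys = NULL) {
  if (is.null(rep_keys)) rep_keys <- sort(names(ps$repulsive))
  elements <- sort(names(ps$shells))
  nfree <- vapply(rep_keys, function(k) spline_n_free(ps$repulsive[[k]]),
                  integer(1))
  offsets <- cumsum(c(0L, nfree))[seq_along(rep_keys)]
  names(offsets) <- rep_keys
  n_rep <- sum(nfree)
  Xf <- .formula_design(ds, elements = elements)
  M <- matrix(0, length(ds), n_rep + ncol(Xf))
  # gather distances per pair key, one design evaluation per key
  dists <- stats::setNames(vector("list", length(rep_keys)), rep_keys)
  rows <- dists
  for (ci in seq_along(ds)) {
    g <- ds[[ci]]
    nat <- length(g$z)
    if (nat < 2L) next
    D <- as.matrix(stats::dist(g$xyz))
    for (a in 1:(nat - 1L)) for (b in (a + 1L):nat) {
      k <- channel_key("R", min(g$z[a], g$z[b]), max(g$z[a], g$z[b]), "rep")
      if (is.null(ps$repulsive[[k]]))
        stop("missing repulsive spline ", k)
      dists[[k]] <- c(dists[[k]], D[a, b])
      rows[[k]] <- c(rows[[k]], ci)
    }
  }
  for (k in rep_keys) {
    if (is.null(dists[[k]])) next
    Dk <- spline_free_design(ps$repulsive[[k]], dists[[k]])
    agg <- rowsum(Dk, group = rows[[k]])
    M[as.integer(rownames(agg)), offsets[[k]] + seq_len(ncol(Dk))] <- agg
  }
  M[, n_rep + seq_len(ncol(Xf))] <- Xf
  list(M = M, rep_keys = rep_keys, offsets = offsets, nfree = nfree,
       n_rep = n_rep, ref_names = colnames(Xf))
}

# Shape-constraint rows for the repulsive splines: convexity of the
# third-order spline. The second derivative of an order-3 spline is
# piecewise linear, so non-negativity at the knots is exactly equivalent to
# non-negativity everywhere; with the built-in cutoff conditions
# R(r_cut) = R'(r_cut) = 0 it also implies R' <= 0 (monotone decrease).
# A dense constraint grid can be requested instead via grid_n.
.repulsive_constraints <- function(ps, design, grid_n = NULL) {
  blocks <- list()
  for (k in design$rep_keys) {
    sp <- ps$repulsive[[k]]
    r <- if (is.null(grid_n)) {
      unique(sp$knots_full)
    } else {
      penalty_grid(sp, grid_n)
    }
    D2 <- spline_free_design(sp, r, 2L)
    blk <- matrix(0, nrow(D2), ncol(design$M))
    blk[, design$offsets[[k]] + seq_len(design$nfree[[k]])] <- D2
    blocks[[k]] <- blk
  }
  do.call(rbind, blocks)
}

#' Joint convex fit of repulsive splines and reference energy
#'
#' With electronic energies fixed, minimizes
#' \deqn{\sum_i (E_i^{target} - E_i^{elec} - \sum_{pairs} R(r) - E_i^{ref})^2}
#' over all repulsive spline coefficients and reference coefficients,
#' subject to convexity of every repulsive spline (which, with the built-in
#' zero value/slope at the cutoff, implies a monotonically decreasing
#' short-range wall). The problem is a positive-definite quadratic program;
#' the interior-point solution is the global optimum.
#'
#' @param train_set a \code{tb_dataset} (geometries and formulas)
#' @param electronic_energies electronic energies per configuration (Ha)
#' @param targets target total energies per configuration (Ha)
#' @param ps a \code{tb_paramset} supplying the repulsive spline definitions
#' @param constraint_grid_n optional dense-grid size for the convexity
#'   constraints; default NULL uses the knot grid (exact for order-3
#'   splines)
#' @param ridge relative ridge regularization keeping coefficients finite
#'   where the data contains no distances (default 1e-9)
#' @param solver \code{"ip"} (interior point) or \code{"dual_pg"}
#'   (projected-gradient cross-check solver)
#' @param design optional precomputed design from an earlier fit over the
#'   same configurations (geometry-only, so it can be reused across charge
#'   updates)
#' @return list: \code{ps} (parameter set with updated repulsive splines and
#'   reference), \code{fitted} (repulsive + reference energy per config),
#'   \code{residuals}, \code{objective} (residual sum of squares),
#'   \code{mae_kcal}, \code{solver}
#' @export
fit_repulsive_and_reference <- function(train_set, electronic_energies,
                                        targets, ps,
                                        constraint_grid_n = NULL,
                                        ridge = 1e-7, solver = c("ip", "dual_pg"),
                                        design = NULL) {
  solver <- match.arg(solver)
  stopifnot(length(electronic_energies) == length(train_set),
            length(targets) == length(train_set))
  if (is.null(design)) design <- .repulsive_design(train_set, ps)
  stopifnot(nrow(design$M) == length(train_set))
  M <- design$M
  y <- targets - electronic_energies
  # center the target by a plain least-squares reference fit; the quadratic
  # program then works at the scale of the remaining residual (targets carry
  # isolated-atom content of tens of Hartree per element, which would
  # otherwise dominate the solver's scaled tolerances). The pre-fit is added
  # back to the reference coefficients afterwards.
  Xf <- M[, design$n_rep + seq_along(design$ref_names), drop = FALSE]
  qXf <- qr(Xf)
  beta0 <- qr.coef(qXf, y)
  beta0[is.na(beta0)] <- 0
  y <- y - drop(Xf %*% beta0)
  Q <- 2 * crossprod(M)
  lam <- ridge * mean(diag(Q)[seq_len(max(design$n_rep, 1L))])
  diag(Q) <- diag(Q) + lam
  cc <- -2 * drop(crossprod(M, y))
  A <- .repulsive_constraints(ps, design, constraint_grid_n)
  b <- rep(0, nrow(A))
  sol <- if (solver == "ip") qp_solve_ip(Q, cc, A, b)
         else qp_solve_dual_pg(Q, cc, A, b)
  if (!is.null(sol$converged) && !sol$converged)
    warning("interior-point solver did not reach tolerance; max constraint violation ",
            format(sol$max_violation))
  x <- sol$x
  x[design$n_rep + seq_along(design$ref_names)] <-
    x[design$n_rep + seq_along(design$ref_names)] + beta0
  for (k in design$rep_keys) {
    z <- x[design$offsets[[k]] + seq_len(design$nfree[[k]])]
    ps$repulsive[[k]] <- spline_set_free(ps$repulsive[[k]], z)
  }
  refv <- x[design$n_rep + seq_along(design$ref_names)]
  names(refv) <- design$ref_names
  elements <- setdiff(design$ref_names, "c0")
  ps$reference <- list(c_elements = stats::setNames(as.numeric(refv[elements]),
                                                    elements),
                       c0 = unname(refv["c0"]))
  fitted <- drop(M %*% x)
  res <- y - fitted
  list(ps = ps, fitted = fitted, residuals = res,
       objective = sum(res^2), mae_kcal = mean(abs(res)) * KCAL_PER_HA,
       coefficients = x, design = design, solver = sol)
}
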