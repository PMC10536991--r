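#' Shape regularization of channel splines
#'
#' Three penalties keep trained channels physically shaped:
#' \itemize{
#'   \item a \emph{convex} penalty forcing the second derivative, evaluated
#'     on a dense grid of 500 points, to carry a physically motivated sign
#'     (upward curvature for channels approaching zero from above, downward
#'     for channels approaching from below);
#'   \item its \emph{single-inflection} extension for overlap channels,
#'     where the orbital node structure produces one curvature sign change
#'     whose location is itself optimized during training;
#'   \item a \emph{smoothing} penalty, the sum of squared third derivatives
#'     on the same grid, which removes piecewise-linear artifacts. It
#'     requires a continuous third derivative and therefore applies only to
#'     the fifth-order electronic splines, not to third-order repulsives.
#' }
#' All penalties are non-negative and (piecewise) quadratic in the spline
#' coefficients; violations are measured by a squared hinge so gradients are
#' continuous.
#'
#' @name regularization
NULL

#' Penalty configuration
#'
#' @param grid_n number of evaluation points per channel (default 500)
#' @param convex_weight weight of the curvature-sign penalty (default 1e3;
#'   only needs to be large enough that violations vanish)
#' @param smoothing_weight weight of the third-derivative penalty (default
#'   1e-4, the smallest order of magnitude that removes piecewise-linear
#'   behavior in the synthetic recovery experiments without degrading fit)
#' @param allow_inflection allow a single trainable inflection on overlap
#'   (S) channels (default TRUE)
#' @param beta smoothing width (in grid spacings) used to blend the two
#'   sign regions when the inflection location needs a gradient; the exact
#'   penalty uses a hard split (\code{beta = 0})
#' @return list of class \code{tb_penalty_config}
#' @export
penalty_config <- function(grid_n = 500L, convex_weight = 1e3,
                           smoothing_weight = 1e-4, allow_inflection = TRUE,
                           beta = 1) {
  stopifnot(grid_n >= 2, convex_weight >= 0, smoothing_weight >= 0)
  structure(list(grid_n = as.integer(grid_n), convex_weight = convex_weight,
                 smoothing_weight = smoothing_weight,
                 allow_inflection = allow_inflection, beta = beta),
            class = "tb_penalty_config")
}

#' Dense evaluation grid of a spline's range
#' @param spline a \code{channel_spline}
#' @param grid_n number of points
#' @return numeric vector of distances (Angstrom)
#' @export
penalty_grid <- function(spline, grid_n = 500L) {
  seq(spline$r_low, spline$r_cut, length.out = grid_n)
}

#' Curvature-sign (convex) penalty
#'
#' Sum of squared sign-violating second derivatives over the dense grid;
#' exactly zero iff the second derivative has the required sign (or
#' vanishes) at every grid point.
#'
#' @param spline a \code{channel_spline} (order >= 3)
#' @param config a \code{\link{penalty_config}}
#' @param sign required curvature sign (+1 upward, -1 downward); defaults
#'   to the spline's stored \code{curvature_sign}
#' @return non-negative scalar
#' @export
convex_penalty <- function(spline, config = penalty_config(), sign = NULL) {
  if (spline$degree < 2) stop("convex penalty requires spline order >= 3")
  s <- if (is.null(sign)) spline$curvature_sign else sign
  if (is.na(s)) stop("no curvature sign assigned to channel; pass `sign`")
  r <- penalty_grid(spline, config$grid_n)
  f2 <- spline_eval(spline, r, 2L)
  sum(pmax(0, -s * f2)^2)
}

#' Convex penalty with a single inflection point
#'
#' The required curvature sign flips once at \code{inflection_x}: the
#' channel must carry \code{-sign} curvature below the inflection and
#' \code{sign} curvature above it (toward the cutoff). With \code{beta = 0}
#' (default) the split is exact, so the penalty is zero iff the sign pattern
#' is satisfied on both sides; with \code{beta > 0} the two requirements are
#' blended smoothly over \code{beta} grid spacings, which makes the penalty
#' differentiable in the inflection location (used during training).
#'
#' @inheritParams convex_penalty
#' @param inflection_x inflection location in Angstrom (defaults to the
#'   spline's stored value)
#' @param beta blending width in grid spacings (0 = exact hard split)
#' @return non-negative scalar
#' @export
inflection_convex_penalty <- function(spline, inflection_x = NULL,
                                      config = penalty_config(),
                                      sign = NULL, beta = 0) {
  if (spline$degree < 2) stop("convex penalty requires spline order >= 3")
  s <- if (is.null(sign)) spline$curvature_sign else sign
  if (is.na(s)) stop("no curvature sign assigned to channel; pass `sign`")
  xi <- if (is.null(inflection_x)) spline$inflection_x else inflection_x
  if (is.null(xi)) stop("no inflection location available")
  if (xi < spline$r_low || xi > spline$r_cut)
    stop("inflection_x must lie inside [r_low, r_cut]")
  r <- penalty_grid(spline, config$grid_n)
  f2 <- spline_eval(spline, r, 2L)
  if (beta <= 0) {
    # exact hard split: tail-side sign for r >= xi, flipped sign below
    sgn <- ifelse(r >= xi, s, -s)
    sum(pmax(0, -sgn * f2)^2)
  } else {
    # smooth variant (used for the inflection-location gradient during
    # training): tanh-modulated hinge that vanishes at the flip point
    h <- (r[2] - r[1]) * beta
    sum(pmax(0, -s * tanh((r - xi) / h) * f2)^2)
  }
}

#' Third-derivative smoothing penalty
#'
#' Sum of squared third derivatives over the dense grid. Requires a
#' continuous third derivative, hence order >= 5; applying it to the
#' third-order repulsive splines is an error.
#'
#' @inheritParams convex_penalty
#' @return non-negative scalar
#' @export
smoothing_penalty <- function(spline, config = penalty_config()) {
  if (spline$degree < 5)
    stop("smoothing penalty requires order >= 5 (continuous third ",
         "derivative); it does not apply to order-", spline$degree,
         " repulsive splines")
  r <- penalty_grid(spline, config$grid_n)
  f3 <- spline_eval(spline, r, 3L)
  sum(f3^2)
}

#' Assign the curvature-sign class of a channel from its shape
#'
#' Implements the convention that channels approaching zero from above near
#' the cutoff require upward (positive) curvature there, channels
#' approaching from below require downward curvature. The sign is read from
#' the channel value just inside the cutoff.
#'
#' @param spline a \code{channel_spline} with coefficients describing a seed
#'   or reference shape
#' @param frac fraction of the range inside the cutoff at which the sign is
#'   probed (default 0.1)
#' @return +1 or -1
#' @export
assign_curvature_sign <- function(spline, frac = 0.1) {
  r <- spline$r_cut - frac * (spline$r_cut - spline$r_low) * seq(0.5, 1.5, 0.25)
  v <- spline_eval(spline, r)
  s <- sign(sum(v))
  if (s == 0) 1 else s
}

# Banded storage of a B-spline design matrix: at most `bw` consecutive
# non-zeros per row (the local support of the basis).
.band_form <- function(D, bw) {
  ng <- nrow(D); nf <- ncol(D)
  bw <- min(bw, nf)
  Db <- matrix(0, ng, bw)
  Dstart <- integer(ng)
  for (i in seq_len(ng)) {
    nz <- which(D[i, ] != 0)
    s0 <- if (length(nz)) min(nz) else 1L
    s0 <- min(s0, nf - bw + 1L)
    Dstart[i] <- s0 - 1L
    Db[i, ] <- D[i, s0:(s0 + bw - 1L)]
  }
  list(Db = Db, Dstart = Dstart)
}

# Build the penalty descriptors consumed by the compiled training kernels.
# Fixed-sign (convex) and smoothing rows of all channels are concatenated
# into one banded block ("bulk"); inflection channels keep per-channel
# descriptors because their sign pattern depends on a trainable location.
build_penalty_descriptors <- function(ps, layout, config) {
  infl <- list()
  vb <- list(); col0 <- list(); mode <- list(); wgt <- list(); sgn <- list()
  add_bulk <- function(b, global_off, m, w, s) {
    vb[[length(vb) + 1L]] <<- b$Db
    col0[[length(col0) + 1L]] <<- b$Dstart + global_off
    n <- nrow(b$Db)
    mode[[length(mode) + 1L]] <<- rep(m, n)
    wgt[[length(wgt) + 1L]] <<- rep(w, n)
    sgn[[length(sgn) + 1L]] <<- rep(s, n)
  }
  for (i in seq_len(nrow(layout$channels))) {
    key <- layout$channels$key[i]
    sp <- ps$electronic[[key]]
    off <- layout$channels$offset[i]
    nf <- layout$channels$n_free[i]
    r <- penalty_grid(sp, config$grid_n)
    b2 <- .band_form(spline_free_design(sp, r, 2L), sp$degree + 1L)
    s <- sp$curvature_sign
    if (is.na(s)) s <- assign_curvature_sign(sp)
    has_infl <- config$allow_inflection && startsWith(key, "S:") &&
      !is.null(layout$inflection) && key %in% names(layout$inflection)
    if (has_infl) {
      infl[[length(infl) + 1L]] <- list(
        type = 1L, Db = b2$Db, Dstart = b2$Dstart, n_free = nf,
        offset = off, weight = config$convex_weight,
        sign = s, r_grid = r,
        latent = as.integer(layout$inflection[[key]] - 1L),
        beta = (r[2] - r[1]) * config$beta,
        r_low = sp$r_low, r_cut = sp$r_cut)
    } else {
      add_bulk(b2, off, 0L, config$convex_weight, s)
    }
    if (config$smoothing_weight > 0) {
      b3 <- .band_form(spline_free_design(sp, r, 3L), sp$degree + 1L)
      add_bulk(b3, off, 2L, config$smoothing_weight, 0)
    }
  }
  bulk <- if (length(vb)) list(
    Vb = t(do.call(rbind, vb)), col0 = as.integer(unlist(col0)),
    mode = as.integer(unlist(mode)), weight = as.numeric(unlist(wgt)),
    sign = as.numeric(unlist(sgn))) else NULL
  structure(list(bulk = bulk, infl = infl), class = "tb_penalties")
}

#' Evaluate the training penalties (and their gradient)
#'
#' @param pdesc descriptors from \code{build_penalty_descriptors}
#' @param x flat parameter vector
#' @param want_grad compute the gradient
#' @return list with \code{penalty} and \code{grad}
#' @keywords internal
penalty_eval <- function(pdesc, x, want_grad = TRUE) {
  tot <- 0
  grad <- numeric(length(x))
  if (!is.null(pdesc$bulk)) {
    b <- pdesc$bulk
    r <- cpp_penalties_bulk(b$Vb, b$col0, b$mode, b$weight, b$sign, x, want_grad)
    tot <- tot + r$penalty
    if (want_grad) grad <- grad + r$grad
  }
  if (length(pdesc$infl)) {
    r <- cpp_penalties(pdesc$infl, x, want_grad)
    tot <- tot + r$penalty
    if (want_grad) grad <- grad + r$grad
  }
  list(penalty = tot, grad = grad)
}

#' Total regularization penalty of a parameter set
#'
#' Evaluates the configured penalties over all electronic channels exactly
#' (hard inflection split), as used for reporting.
#'
#' @param ps a \code{tb_paramset}
#' @param config a \code{\link{penalty_config}}
#' @return list with \code{total}, \code{convex}, \code{smoothing}
#' @export
penalty_report <- function(ps, config = penalty_config()) {
  cv <- sm <- 0
  for (key in names(ps$electronic)) {
    sp <- ps$electronic[[key]]
    s <- sp$curvature_sign
    if (is.na(s)) s <- assign_curvature_sign(sp)
    if (config$allow_inflection && startsWith(key, "S:") &&
        !is.null(sp$inflection_x)) {
      cv <- cv + config$convex_weight *
        inflection_convex_penalty(sp, config = config, sign = s)
    } else {
      cv <- cv + config$convex_weight * convex_penalty(sp, config, sign = s)
    }
    if (config$smoothing_weight > 0)
      sm <- sm + config$smoothing_weight * smoothing_penalty(sp, config)
  }
  list(total = cv + sm, convex = cv, smoothing = sm)
}
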