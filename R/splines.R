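#' Distance-dependent channel splines
#'
#' Every trainable distance-dependent quantity in the model -- a Slater-Koster
#' electronic channel (Hamiltonian \code{H1} or overlap \code{S}) or a pairwise
#' repulsive potential (\code{R}) -- is a B-spline of the interatomic distance
#' on a uniform knot grid over \code{[r_low, r_cut]} (Angstrom). Electronic
#' channels use polynomial order 5 (so the third derivative is continuous,
#' which the smoothing penalty requires), repulsive channels order 3.
#'
#' Boundary conditions at the upper cutoff (value and first derivative zero,
#' so interactions vanish smoothly at long range) are enforced structurally:
#' with the open B-spline basis used here only the last basis function is
#' non-zero at \code{r_cut} and only the last two have non-zero derivative
#' there, so pinning the last two coefficients at zero imposes the conditions
#' exactly for every value of the remaining ("free") coefficients. All
#' training and fitting operates on the free coefficients, which keeps every
#' penalty and the repulsive fit linear in the parameters. No boundary
#' condition is applied at the lower limit; below \code{r_low} the first
#' polynomial piece is continued (Taylor extrapolation).
#'
#' @param kind one of \code{"H1"}, \code{"S"}, \code{"R"}
#' @param pair integer length-2 vector of atomic numbers (ordered pair)
#' @param channel Slater-Koster channel label (\code{"ss_sigma"},
#'   \code{"sp_sigma"}, \code{"pp_sigma"}, \code{"pp_pi"}) or \code{"rep"}
#'   for repulsive splines
#' @param r_low,r_cut spline range in Angstrom
#' @param n_basis number of B-spline basis functions (default 100 for
#'   electronic channels, 50 for repulsive)
#' @param coefficients optional full-length coefficient vector; the last two
#'   entries are forced to zero
#' @param inflection_x optional inflection location in Angstrom (overlap
#'   channels only), used by the curvature penalty
#' @param curvature_sign required sign of the second derivative near the
#'   cutoff (+1 upward, -1 downward); assigned automatically when a channel
#'   is fitted to a seed shape
#' @return an object of class \code{channel_spline}
#' @export
channel_spline <- function(kind, pair, channel, r_low, r_cut,
                           n_basis = if (kind == "R") 50L else 100L,
                           coefficients = NULL, inflection_x = NULL,
                           curvature_sign = NA_real_) {
  kind <- match.arg(kind, c("H1", "S", "R"))
  stopifnot(r_cut > r_low)
  degree <- if (kind == "R") 3L else 5L
  n_interior <- n_basis - degree - 1L
  if (n_interior < 0L) stop("n_basis too small for degree ", degree)
  interior <- if (n_interior > 0)
    seq(r_low, r_cut, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric(0)
  knots_full <- c(rep(r_low, degree + 1L), interior, rep(r_cut, degree + 1L))
  if (is.null(coefficients)) coefficients <- numeric(n_basis)
  if (length(coefficients) != n_basis) stop("coefficients must have length ", n_basis)
  coefficients[c(n_basis - 1L, n_basis)] <- 0
  structure(list(
    kind = kind, pair = as.integer(pair), channel = channel,
    degree = degree, n_basis = as.integer(n_basis),
    knots_full = knots_full, r_low = r_low, r_cut = r_cut,
    coefficients = coefficients, inflection_x = inflection_x,
    curvature_sign = curvature_sign
  ), class = "channel_spline")
}

#' @export
print.channel_spline <- function(x, ...) {
  cat(sprintf("<channel_spline %s %s-%s %s: order %d, %d basis, [%.3f, %.3f] A>\n",
              x$kind, element_symbol(x$pair[1]), element_symbol(x$pair[2]),
              x$channel, x$degree, x$n_basis, x$r_low, x$r_cut))
  invisible(x)
}

.check_deriv <- function(spline, deriv) {
  if (deriv < 0 || deriv != round(deriv)) stop("deriv must be a non-negative integer")
  if (deriv > spline$degree - 1L) {
    stop("derivative order ", deriv, " exceeds the smoothness class of an order-",
         spline$degree, " spline (maximum useful derivative: ", spline$degree - 1L, ")")
  }
}

#' Design matrix mapping spline coefficients to derivative values
#'
#' Returns the matrix \code{M} with \code{spline_eval(s, r, deriv) == M \%*\%
#' coefficients} exactly, for every coefficient vector. Rows for \code{r >=
#' r_cut} are identically zero (interactions vanish beyond the cutoff); rows
#' for \code{r < r_low} continue the first polynomial piece.
#'
#' @param spline a \code{channel_spline}
#' @param r distances in Angstrom
#' @param deriv derivative order (0 to order-1)
#' @return numeric matrix, \code{length(r)} x \code{n_basis}
#' @export
spline_design_matrix <- function(spline, r, deriv = 0L) {
  .check_deriv(spline, deriv)
  n <- length(r)
  nb <- spline$n_basis
  M <- matrix(0, n, nb)
  inside <- which(r >= spline$r_low & r < spline$r_cut)
  if (length(inside)) {
    M[inside, ] <- splines::splineDesign(spline$knots_full, r[inside],
                                         ord = spline$degree + 1L,
                                         derivs = rep(deriv, length(inside)))
  }
  below <- which(r < spline$r_low)
  if (length(below)) {
    # Taylor continuation of the first polynomial piece around r_low:
    # f^(d)(r) = sum_k f^(k)(r_low) (r - r_low)^(k-d) / (k-d)!
    dr <- r[below] - spline$r_low
    for (k in deriv:spline$degree) {
      Dk <- splines::splineDesign(spline$knots_full, spline$r_low,
                                  ord = spline$degree + 1L, derivs = k)
      M[below, ] <- M[below, ] +
        outer(dr^(k - deriv) / factorial(k - deriv), drop(Dk))
    }
  }
  M
}

#' Evaluate a channel spline (or a derivative)
#'
#' @inheritParams spline_design_matrix
#' @return numeric vector of values; zero for \code{r >= r_cut}
#' @export
spline_eval <- function(spline, r, deriv = 0L) {
  drop(spline_design_matrix(spline, r, deriv) %*% spline$coefficients)
}

# Number of free (trainable) coefficients: all but the two pinned at zero.
spline_n_free <- function(spline) spline$n_basis - 2L

# Design matrix restricted to the free coefficients.
spline_free_design <- function(spline, r, deriv = 0L) {
  spline_design_matrix(spline, r, deriv)[, seq_len(spline_n_free(spline)), drop = FALSE]
}

spline_set_free <- function(spline, z) {
  stopifnot(length(z) == spline_n_free(spline))
  spline$coefficients <- c(z, 0, 0)
  spline
}

spline_get_free <- function(spline) {
  spline$coefficients[seq_len(spline_n_free(spline))]
}

#' Least-squares fit of a channel spline to sampled values
#'
#' Fits the free coefficients to \code{(r, y)} by (weighted) least squares;
#' the upper boundary conditions hold automatically. A small ridge keeps the
#' problem well-posed when some basis functions are unsupported by the data.
#'
#' @param spline a \code{channel_spline} defining basis and range
#' @param r,y sample locations (Angstrom) and values
#' @param weights optional non-negative weights
#' @param ridge ridge regularization (relative to the mean squared column
#'   norm); default \code{1e-10}
#' @return the spline with fitted coefficients
#' @export
spline_fit <- function(spline, r, y, weights = NULL, ridge = 1e-10) {
  M <- spline_free_design(spline, r)
  if (!is.null(weights)) {
    w <- sqrt(weights)
    M <- M * w
    y <- y * w
  }
  A <- crossprod(M)
  lam <- ridge * mean(diag(A))
  z <- solve(A + diag(lam, ncol(M)), crossprod(M, y))
  spline_set_free(spline, drop(z))
}
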