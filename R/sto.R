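#' Analytic two-center overlaps of Slater-type orbitals
#'
#' The synthetic ground-truth parameter set uses a valence minimal basis of
#' normalized Slater-type orbitals (STOs): 1s for hydrogen, 2s/2p for first
#' row elements. Two-center overlap integrals are evaluated in closed form in
#' prolate spheroidal coordinates: every integrand reduces to a bivariate
#' polynomial in (xi, eta) times exp(-p xi - q eta), so the integral is a
#' finite sum of auxiliary integrals A_j(p) = int_1^Inf x^j exp(-p x) dx and
#' B_k(q) = int_-1^1 y^k exp(-q y) dy.
#'
#' Channel orientation convention used throughout the package: for the
#' ordered pair (A, B) at distance R, the local z axis points from A to B and
#' p-sigma orbitals on both centers point along +z. Channels:
#' \itemize{
#'   \item \code{ss_sigma}: <s_A | s_B>
#'   \item \code{sp_sigma}: <s_A | p_z B>
#'   \item \code{pp_sigma}: <p_z A | p_z B>
#'   \item \code{pp_pi}:    <p_x A | p_x B>
#' }
#' @name sto
#' @keywords internal
NULL

# A_j(p) = int_1^Inf x^j e^{-px} dx, j = 0..jmax (vector of length jmax+1)
.aux_A <- function(jmax, p) {
  A <- numeric(jmax + 1)
  ep <- exp(-p)
  A[1] <- ep / p
  if (jmax > 0) for (j in 1:jmax) A[j + 1] <- ep / p + (j / p) * A[j]
  A
}

# B_k(q) = int_-1^1 y^k e^{-qy} dy, k = 0..kmax; series for small |q|
.aux_B <- function(kmax, q) {
  B <- numeric(kmax + 1)
  if (abs(q) < 1e-3) {
    for (k in 0:kmax) {
      s <- 0
      term_pow <- 1  # (-q)^m / m!
      for (m in 0:30) {
        if ((k + m) %% 2 == 0) s <- s + term_pow * 2 / (k + m + 1)
        term_pow <- term_pow * (-q) / (m + 1)
      }
      B[k + 1] <- s
    }
  } else {
    em <- exp(-q); ep <- exp(q)
    B[1] <- (ep - em) / q
    if (kmax > 0) for (k in 1:kmax) {
      B[k + 1] <- ((-1)^k * ep - em) / q + (k / q) * B[k]
    }
  }
  B
}

# --- tiny bivariate polynomial algebra: coefficient matrices C[j+1, k+1] ~ u^j v^k
.pmul <- function(P, Q) {
  out <- matrix(0, nrow(P) + nrow(Q) - 1, ncol(P) + ncol(Q) - 1)
  for (j in seq_len(nrow(P))) for (k in seq_len(ncol(P))) {
    c <- P[j, k]
    if (c != 0) out[j:(j + nrow(Q) - 1), k:(k + ncol(Q) - 1)] <-
        out[j:(j + nrow(Q) - 1), k:(k + ncol(Q) - 1)] + c * Q
  }
  out
}

.pconst <- function(c) matrix(c, 1, 1)

# Polynomial factor of a normalized STO on center a or b (excluding the
# exponential and the normalization), in units where s = R/2.
#   n = 1 s-type: 1;  n = 2 s-type: r;  p-sigma: z-displacement; handled by caller
.sto_norm <- function(n, l, zeta) {
  radial <- (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))
  angular <- if (l == 0) 1 / sqrt(4 * pi) else sqrt(3 / (4 * pi))
  radial * angular
}

#' Overlap of two Slater-type orbitals at separation R
#'
#' @param n1,l1,zeta1 principal quantum number, angular momentum (0 or 1) and
#'   exponent (1/bohr) of the orbital on the first center
#' @param n2,l2,zeta2 the same for the second center
#' @param R separation in bohr (vectorized)
#' @param m 0 for sigma alignment, 1 for pi (requires l1 = l2 = 1)
#' @return overlap values (dimensionless)
#' @export
sto_overlap <- function(n1, l1, zeta1, n2, l2, zeta2, R, m = 0L) {
  if (m == 1L && (l1 != 1L || l2 != 1L)) stop("pi overlap requires two p orbitals")
  vapply(R, function(Rb) {
    if (Rb <= 0) stop("R must be positive")
    s <- Rb / 2
    p <- s * (zeta1 + zeta2)
    q <- s * (zeta1 - zeta2)
    # elementary polynomials in (u, v)
    ra <- matrix(c(0, s, s, 0), 2, 2)           # s*(u + v): [u][1] and [1][v]
    rb <- matrix(c(0, s, -s, 0), 2, 2)          # s*(u - v)
    za <- matrix(c(s, 0, 0, s), 2, 2)           # s*(1 + uv)
    zb <- matrix(c(-s, 0, 0, s), 2, 2)          # s*(uv - 1)
    rho2 <- s^2 * matrix(c(-1, 0, 1, 0, 0, 0, 1, 0, -1), 3, 3)  # s^2 (u^2-1)(1-v^2)
    meas <- matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3)         # u^2 - v^2

    if (m == 1L) {
      # p_x on both centers: product of transverse parts is rho^2 cos^2(phi)
      poly <- rho2
      phi_int <- pi
    } else {
      fa <- if (l1 == 1L) za else if (n1 == 2L) ra else .pconst(1)
      fb <- if (l2 == 1L) zb else if (n2 == 2L) rb else .pconst(1)
      poly <- .pmul(fa, fb)
      phi_int <- 2 * pi
    }
    poly <- .pmul(poly, meas)
    A <- .aux_A(nrow(poly) - 1, p)
    B <- .aux_B(ncol(poly) - 1, q)
    val <- 0
    for (j in seq_len(nrow(poly))) for (k in seq_len(ncol(poly))) {
      if (poly[j, k] != 0) val <- val + poly[j, k] * A[j] * B[k]
    }
    .sto_norm(n1, l1, zeta1) * .sto_norm(n2, l2, zeta2) * phi_int * s^3 * val
  }, numeric(1))
}

# Standard Slater-rule valence exponents (1/bohr)
.sto_default_zeta <- c(H = 1.2, C = 1.625, N = 1.95, O = 2.275)

# STO definition for one element shell.
.sto_shell <- function(z, shell, zeta = NULL) {
  sym <- element_symbol(z)
  zt <- if (!is.null(zeta) && !is.na(zeta[sym])) zeta[[sym]]
        else .sto_default_zeta[[sym]]
  n <- if (z == 1L) 1L else 2L
  l <- if (shell == "p") 1L else 0L
  list(n = n, l = l, zeta = zt)
}

#' Analytic overlap channel between two elements
#'
#' Evaluates the STO overlap for one Slater-Koster channel of the ordered
#' element pair (zA, zB) as a function of distance in Angstrom.
#'
#' @param zA,zB atomic numbers of the ordered pair
#' @param channel one of \code{"ss_sigma"}, \code{"sp_sigma"},
#'   \code{"pp_sigma"}, \code{"pp_pi"} (\code{sp_sigma}: s on A, p on B)
#' @param r_ang distances in Angstrom
#' @param zeta optional named vector of per-element exponents overriding the
#'   standard Slater values
#' @return overlap values
#' @export
sto_channel_overlap <- function(zA, zB, channel, r_ang, zeta = NULL) {
  Rb <- r_ang * BOHR_PER_ANG
  ch <- match.arg(channel, c("ss_sigma", "sp_sigma", "pp_sigma", "pp_pi"))
  sa <- switch(ch, ss_sigma = "s", sp_sigma = "s", pp_sigma = "p", pp_pi = "p")
  sb <- switch(ch, ss_sigma = "s", sp_sigma = "p", pp_sigma = "p", pp_pi = "p")
  oa <- .sto_shell(zA, sa, zeta); ob <- .sto_shell(zB, sb, zeta)
  m <- if (ch == "pp_pi") 1L else 0L
  sto_overlap(oa$n, oa$l, oa$zeta, ob$n, ob$l, ob$zeta, Rb, m = m)
}
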