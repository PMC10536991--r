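# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_toy_ho <- function() {
  if (is.null(.fx$toy_ho)) .fx$toy_ho <- make_toy_paramset(c("H", "O"), seed = 3)
  .fx$toy_ho
}

fx_seed_ho <- function() {
  if (is.null(.fx$seed_ho)) .fx$seed_ho <- seed_paramset(c("H", "O"))
  .fx$seed_ho
}

fx_toy_chno <- function() {
  if (is.null(.fx$toy_chno))
    .fx$toy_chno <- make_toy_paramset(c("H", "C", "N", "O"), seed = 11)
  .fx$toy_chno
}

# small H/O dataset with toy-truth targets (with per-element offsets)
fx_ho_data <- function() {
  if (is.null(.fx$ho_data)) {
    ds <- sample_geometries(c("H2", "H2O", "H2O2"), n_per_template = 12,
                            distortion_scale = 0.04, seed = 21)
    .fx$ho_data <- make_targets(ds, fx_toy_ho(),
                                element_offsets = c(H = -0.5, O = -75.0),
                                seed = 22)
  }
  .fx$ho_data
}

fx_water <- function() geometry_templates("H2O")[[1]]

# random rigid motion (proper rotation + translation); uses the session RNG
rigid_motion <- function(xyz) {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(xyz = t(R %*% t(xyz)) + matrix(rnorm(3), nrow(xyz), 3, byrow = TRUE),
       R = R)
}

# generalized eigenvalues of a tb_matrix_pair (symmetric-definite problem)
geigen_vals <- function(mp) {
  es <- eigen(mp$S, symmetric = TRUE)
  Q <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  eigen(Q %*% mp$H1 %*% Q, symmetric = TRUE, only.values = TRUE)$values
}

formula_counts2 <- function(f) {
  ct <- formula_counts(f)
  c(H = unname(ct["H"]), O = if ("O" %in% names(ct)) unname(ct["O"]) else 0)
}

# Synthetic H/O geometries with connected distance coverage across the full
# repulsive ranges and varying compositions; used to test the convex
# repulsive + reference fit where it is identifiable (electronic energies
# are an input to that operation, so the geometries need not be physical).
fx_repulsive_probe_set <- function() {
  if (!is.null(.fx$rep_probe)) return(.fx$rep_probe)
  set.seed(71)
  geoms <- list()
  # H-H scans (composition H2)
  for (r in seq(0.62, 1.08, by = 0.023))
    geoms[[length(geoms) + 1L]] <- geometry(c(1L, 1L),
                                            rbind(c(0, 0, 0), c(0, 0, r)))
  # O-H scans (composition H2O: one H parked far away)
  for (r in seq(0.74, 1.48, by = 0.037))
    geoms[[length(geoms) + 1L]] <- geometry(c(8L, 1L, 1L),
      rbind(c(0, 0, 0), c(0, 0, r), c(0, 6, 0)))
  # O-O scans with 4 H far away (composition H4O2)
  for (r in seq(1.08, 1.97, by = 0.046))
    geoms[[length(geoms) + 1L]] <- geometry(c(8L, 8L, 1L, 1L, 1L, 1L),
      rbind(c(0, 0, 0), c(0, 0, r), c(0, 6, 0), c(0, -6, 0),
            c(6, 0, 0), c(-6, 0, 0)))
  # mixed clusters (composition H6O2)
  for (k in 1:10)
    geoms[[length(geoms) + 1L]] <- geometry(c(8L, 8L, rep(1L, 6)),
      rbind(c(0, 0, 0), c(0, 0, 1.2 + 0.5 * runif(1)),
            c(0.9 + 0.3 * runif(1), 0, 0), c(-0.95, 0.2, 0),
            c(0, 0.85 + 0.3 * runif(1), 1.4), c(0, -0.9, 1.3),
            c(4, 4, 0), c(-4, -4, 0)))
  # O-H scans with three parked H (composition H4O)
  for (r in seq(0.76, 1.46, by = 0.07))
    geoms[[length(geoms) + 1L]] <- geometry(c(8L, 1L, 1L, 1L, 1L),
      rbind(c(0, 0, 0), c(0, 0, r), c(0, 6, 0), c(6, 0, 0), c(-6, 0, 0)))
  # two H2 units far apart (composition H4, two H-H bonds)
  for (r in seq(0.64, 1.06, by = 0.042))
    geoms[[length(geoms) + 1L]] <- geometry(rep(1L, 4),
      rbind(c(0, 0, 0), c(0, 0, r), c(8, 0, 0), c(8, 0, 0.74)))
  .fx$rep_probe <- dataset(geoms)
  .fx$rep_probe
}

# Numerical-integration oracle for two-center orbital products. The
# azimuthal integral is done analytically (2*pi for sigma alignments, pi for
# the p_x-p_x product); the remaining (rho, z) integral uses piecewise
# Gauss-Legendre quadrature with panel boundaries at the two nuclei, where
# the integrand has cusps.
quad_overlap <- function(fa, fb, R, m = 0L, L = 12, n_rho = 240, n_z = 240) {
  gl <- function(n, a, b) pracma::gaussLegendre(n, a, b)
  grho <- gl(n_rho, 0, L)
  panels <- list(c(-L, 0), c(0, R), c(R, R + L))
  phi_fac <- if (m == 0L) 2 * pi else pi
  acc <- 0
  for (p in panels) {
    gz <- gl(n_z, p[1], p[2])
    for (iz in seq_along(gz$x)) {
      z <- gz$x[iz]
      ra <- sqrt(grho$x^2 + z^2)
      rb <- sqrt(grho$x^2 + (z - R)^2)
      # for m = 1 the transverse parts contribute rho_a * rho_b = rho^2,
      # already folded into fa/fb through the `x` argument = rho
      vals <- fa(ra, z, grho$x) * fb(rb, z - R, grho$x) * grho$x
      acc <- acc + gz$w[iz] * sum(grho$w * vals)
    }
  }
  phi_fac * acc
}

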