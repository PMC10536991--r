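#' Synthetic ground truth and data generation
#'
#' Fully offline fixtures for development and verification: a "toy" ground
#' truth parameter set built from analytic Slater-type-orbital overlaps,
#' a library of small-molecule templates, a sampler producing distorted
#' geometries, and a target generator that evaluates the toy model (plus
#' per-element energy offsets and optional noise) to produce energy, dipole
#' and charge targets. Training against these targets closes the loop:
#' parameter recovery can be measured against the known generating channels.
#'
#' @name synthetic_data
NULL

# Reference constants (Hartree) for valence shells; onsite energies are
# standard atomic orbital energies, Hubbard parameters standard atomic
# chemical hardness values, slightly shell-split.
.toy_onsite <- c("H.s" = -0.2386, "C.s" = -0.5049, "C.p" = -0.1944,
                 "N.s" = -0.6400, "N.p" = -0.2607,
                 "O.s" = -0.8788, "O.p" = -0.3321)
.toy_hubbard <- c("H.s" = 0.4195, "C.s" = 0.3993, "C.p" = 0.3647,
                  "N.s" = 0.4613, "N.p" = 0.4309,
                  "O.s" = 0.5279, "O.p" = 0.4954)

# Per-pair range tables (Angstrom): lower electronic spline bound, repulsive
# (nearest-neighbor) cutoff, and a typical bond length used for calibration.
.pair_table <- function(zA, zB, what) {
  key <- paste(sort(element_symbol(c(zA, zB))), collapse = "")
  tab <- list(
    #        r_low  rep_cut bond
    "HH" = c(0.55, 1.10, 0.741),
    "CH" = c(0.75, 1.60, 1.09),
    "HN" = c(0.72, 1.55, 1.01),
    "HO" = c(0.70, 1.50, 0.96),
    "CC" = c(1.10, 2.10, 1.53),
    "CN" = c(0.95, 2.00, 1.47),
    "CO" = c(1.02, 1.95, 1.43),
    "NN" = c(1.05, 2.00, 1.45),
    "NO" = c(1.02, 1.95, 1.40),
    "OO" = c(1.05, 2.00, 1.48))
  key <- paste(sort(strsplit(key, "")[[1]]), collapse = "")
  v <- tab[[key]]
  if (is.null(v)) stop("no range table for pair ", key)
  switch(what, r_low = v[1], rep_cut = v[2], bond = v[3])
}

#' Electronic long-range cutoff (Angstrom) beyond which all channels vanish
#' @export
ELECTRONIC_CUTOFF <- 4.5

#' Shape-constrained spline fit
#'
#' Fits a channel spline to sampled values by least squares subject to the
#' curvature-sign class the regularizers enforce: a fixed curvature sign
#' (read from the value approaching the cutoff: positive values require
#' upward curvature, negative downward), optionally with a single sign
#' change (inflection) whose location is detected from the data. The fit is
#' a convex quadratic program; the returned spline carries its
#' \code{curvature_sign} and (if allowed) \code{inflection_x}.
#'
#' @param spline a \code{channel_spline} defining basis and range
#' @param r,y sample locations (Angstrom) and values
#' @param allow_inflection permit one curvature sign change (overlap
#'   channels)
#' @param grid_n constraint grid size (matches the penalty grid, default 500)
#' @return the fitted spline
#' @export
spline_fit_shaped <- function(spline, r, y, allow_inflection = FALSE,
                              grid_n = 500L) {
  sp0 <- spline_fit(spline, r, y)
  grid <- penalty_grid(sp0, grid_n)
  D2 <- spline_free_design(sp0, grid, 2L)
  z0 <- spline_get_free(sp0)
  f2 <- drop(D2 %*% z0)
  # tail sign from the data just inside the cutoff
  probe <- sp0$r_cut - c(0.05, 0.1, 0.15) * (sp0$r_cut - sp0$r_low)
  yp <- stats::approx(r, y, xout = probe, rule = 2)$y
  s_tail <- sign(sum(yp))
  if (s_tail == 0) s_tail <- 1

  x0 <- sp0$r_low
  sgn <- rep(s_tail, grid_n)
  if (allow_inflection) {
    # place the sign flip where the total squared curvature violation of the
    # unconstrained fit is smallest (1-D scan over all split points)
    viol_left <- pmax(0, s_tail * f2)^2    # violation of the flipped (-s) rule
    viol_right <- pmax(0, -s_tail * f2)^2  # violation of the tail-side rule
    tot_right <- sum(viol_right)
    # total(k): split before grid point k (k = 1 means pure convex)
    totals <- c(0, cumsum(viol_left)[-grid_n]) +
      (tot_right - c(0, cumsum(viol_right)[-grid_n]))
    k <- which.min(totals)
    if (k > 1L) {
      x0 <- (grid[k - 1] + grid[k]) / 2
      sgn <- ifelse(grid < x0, -s_tail, s_tail)
    }
  }
  A <- sgn * D2
  feasible <- min(A %*% z0) >= 0
  if (!feasible) {
    M <- spline_free_design(sp0, r)
    Q <- 2 * crossprod(M)
    diag(Q) <- diag(Q) + 1e-10 * mean(diag(Q))
    sol <- qp_solve_ip(Q, -2 * drop(crossprod(M, y)), A, rep(0, nrow(A)))
    sp0 <- spline_set_free(sp0, sol$x)
  }
  sp0$curvature_sign <- s_tail
  if (allow_inflection) sp0$inflection_x <- x0
  sp0
}

# C2 taper to zero over [r_on, r_cut]: exactly 1 below r_on, exactly 0 at
# r_cut with zero slope, so tapered channels meet the cutoff boundary
# conditions without a boundary-layer artifact in the spline fit.
.taper <- function(r, r_cut = ELECTRONIC_CUTOFF, width = 0.7) {
  r_on <- r_cut - width
  t <- pmin(pmax((r - r_on) / width, 0), 1)
  1 - t^3 * (10 - 15 * t + 6 * t^2)
}

# Wolfsberg-Helmholz shell energies entering an H1 channel.
.wh_eps <- function(onsite, zA, zB, channel) {
  sh <- switch(channel,
               ss_sigma = c("s", "s"), sp_sigma = c("s", "p"),
               pp_sigma = c("p", "p"), pp_pi = c("p", "p"))
  onsite[[paste0(element_symbol(zA), ".", sh[1])]] +
    onsite[[paste0(element_symbol(zB), ".", sh[2])]]
}

#' Toy ground-truth parameter set from analytic orbitals
#'
#' Builds a complete, physically shaped parameter set for the requested
#' elements. Overlap channels are shape-constrained spline fits of analytic
#' Slater-type-orbital overlaps (\code{\link{sto_channel_overlap}});
#' Hamiltonian channels follow a Wolfsberg-Helmholz bond-integral ansatz
#' (K = 1.75 times the mean on-site energy times the overlap) projected
#' onto the pure-convex curvature class the regularizers enforce -- where
#' the raw ansatz is incompatible with that class (overlaps with nodes),
#' a magnitude-calibrated decaying exponential of the same tail sign is
#' used instead. Repulsive splines are convex decaying exponentials that
#' vanish with zero slope at their nearest-neighbor cutoff. On-site
#' energies and Hubbard parameters are standard atomic values with a small
#' seeded jitter so that different seeds define different ground truths.
#'
#' @param elements character vector of element symbols (subset of H,C,N,O)
#' @param seed integer seed for the constant jitter
#' @param n_basis_electronic,n_basis_repulsive spline basis sizes
#' @return a \code{tb_paramset} with every channel conforming to its
#'   assigned curvature class (zero convex penalty)
#' @export
make_toy_paramset <- function(elements = c("H", "C", "N", "O"), seed = 1L,
                              n_basis_electronic = 100L,
                              n_basis_repulsive = 50L) {
  zs <- sort(element_z(elements))
  rng <- .seeded_rng(seed)
  jit <- function(v) v * (1 + 0.02 * (2 * rng$runif(length(v)) - 1))
  labels <- unlist(lapply(zs, function(z)
    paste0(element_symbol(z), ".", element_shells(z))))
  onsite <- stats::setNames(jit(.toy_onsite[labels]), labels)
  hubbard <- stats::setNames(jit(.toy_hubbard[labels]), labels)
  shells <- .shells_from_constants(zs, onsite, hubbard)
  electronic <- .build_electronic_channels(zs, onsite, zeta = NULL,
                                           n_basis_electronic)
  repulsive <- list()
  for (ai in seq_along(zs)) for (bi in ai:length(zs)) {
    a <- zs[ai]; b <- zs[bi]
    bond <- .pair_table(a, b, "bond")
    rep_cut <- .pair_table(a, b, "rep_cut")
    rho <- 0.35
    amp <- 0.08 * exp(bond / rho)
    rg <- seq(0, rep_cut, length.out = 400)
    yR <- amp * (exp(-rg / rho) - exp(-rep_cut / rho) +
                 (1 / rho) * exp(-rep_cut / rho) * (rg - rep_cut))
    key_r <- channel_key("R", a, b, "rep")
    repulsive[[key_r]] <- spline_fit_shaped(
      channel_spline("R", c(a, b), "rep", 0, rep_cut,
                     n_basis = n_basis_repulsive),
      rg, yR, allow_inflection = FALSE)
  }
  parameter_set(shells, electronic, repulsive,
                meta = list(kind = "toy-truth", seed = seed))
}

.shells_from_constants <- function(zs, onsite, hubbard) {
  shells <- list()
  for (z in zs) {
    sym <- element_symbol(z)
    shells[[sym]] <- list()
    for (sh in element_shells(z)) {
      lab <- paste0(sym, ".", sh)
      shells[[sym]][[sh]] <- list(onsite = unname(onsite[lab]),
                                  hubbard = unname(hubbard[lab]))
    }
  }
  shells
}

# Electronic channels for all pairs of zs: shape-constrained fits of STO
# overlaps (with the given exponents) and Wolfsberg-Helmholz Hamiltonian
# curves projected on the pure-convex class.
.build_electronic_channels <- function(zs, onsite, zeta, n_basis) {
  electronic <- list()
  K_WH <- 1.75
  for (ai in seq_along(zs)) for (bi in ai:length(zs)) {
    a <- zs[ai]; b <- zs[bi]
    r_low <- .pair_table(a, b, "r_low")
    bond <- .pair_table(a, b, "bond")
    rgrid <- seq(r_low, ELECTRONIC_CUTOFF, length.out = 600)
    for (ch in pair_channels(a, b, "S")) {
      yS <- sto_channel_overlap(ch$zA, ch$zB, ch$channel, rgrid, zeta = zeta) *
        .taper(rgrid)
      key_s <- channel_key("S", ch$zA, ch$zB, ch$channel)
      electronic[[key_s]] <- spline_fit_shaped(
        channel_spline("S", c(ch$zA, ch$zB), ch$channel, r_low,
                       ELECTRONIC_CUTOFF, n_basis = n_basis),
        rgrid, yS, allow_inflection = TRUE)
      eps <- .wh_eps(onsite, ch$zA, ch$zB, ch$channel)
      yH <- 0.5 * K_WH * eps * yS
      key_h <- channel_key("H1", ch$zA, ch$zB, ch$channel)
      sp_h <- channel_spline("H1", c(ch$zA, ch$zB), ch$channel, r_low,
                             ELECTRONIC_CUTOFF, n_basis = n_basis)
      if (.convex_conforming(sp_h, rgrid, yH)) {
        electronic[[key_h]] <- spline_fit_shaped(sp_h, rgrid, yH,
                                                 allow_inflection = FALSE)
      } else {
        ysur <- .exp_surrogate(rgrid, yH, bond) * .taper(rgrid)
        electronic[[key_h]] <- spline_fit_shaped(sp_h, rgrid, ysur,
                                                 allow_inflection = FALSE)
      }
    }
  }
  electronic
}

# Does the least-squares fit of (r, y) conform to the pure-convex class?
.convex_conforming <- function(spline, r, y, rel_tol = 0.02) {
  sp <- spline_fit(spline, r, y)
  grid <- penalty_grid(sp, 500L)
  f2 <- spline_eval(sp, grid, 2L)
  probe <- sp$r_cut - c(0.05, 0.1, 0.15) * (sp$r_cut - sp$r_low)
  s <- sign(sum(stats::approx(r, y, xout = probe, rule = 2)$y))
  if (s == 0) s <- 1
  max(pmax(0, -s * f2)) <= rel_tol * max(abs(f2))
}

# Tail-sign preserving exponential surrogate calibrated to the magnitude and
# decay of y around the typical bond length.
.exp_surrogate <- function(r, y, bond) {
  ab <- stats::approx(r, abs(y), xout = c(bond, bond + 1.2), rule = 2)$y
  rho <- 1.2 / log(max(ab[1], 1e-8) / max(ab[2], 1e-9))
  rho <- min(max(rho, 0.25), 1.0)
  s_tail <- sign(stats::approx(r, y, xout = max(r) - 0.3, rule = 2)$y)
  if (s_tail == 0) s_tail <- 1
  s_tail * ab[1] * exp(-(r - bond) / rho)
}

#' Physically shaped initialization for training
#'
#' Generic starting parameter set: overlap channels come from Slater-type
#' orbitals with deliberately coarse, rounded exponents (H 1.0, C 1.5,
#' N 1.8, O 2.1 per bohr), so the starting overlap matrices are genuine
#' Gram matrices (always positive definite) while differing substantially
#' from any particular target parameterization; Hamiltonian channels use
#' the Wolfsberg-Helmholz ansatz on those overlaps, projected on the
#' convex curvature classes. On-site energies and Hubbard parameters start
#' from standard atomic values; repulsive splines start at zero (they are
#' refit by convex optimization at the first charge update).
#'
#' @inheritParams make_toy_paramset
#' @return a \code{tb_paramset}
#' @export
seed_paramset <- function(elements = c("H", "C", "N", "O"),
                          n_basis_electronic = 100L,
                          n_basis_repulsive = 50L) {
  zs <- sort(element_z(elements))
  labels <- unlist(lapply(zs, function(z)
    paste0(element_symbol(z), ".", element_shells(z))))
  onsite <- .toy_onsite[labels]
  hubbard <- .toy_hubbard[labels]
  shells <- .shells_from_constants(zs, onsite, hubbard)
  # generic rounded exponents: same orbital physics, deliberately coarse
  zeta_seed <- c(H = 1.0, C = 1.5, N = 1.8, O = 2.1)
  electronic <- .build_electronic_channels(zs, onsite, zeta = zeta_seed,
                                           n_basis_electronic)
  repulsive <- list()
  for (ai in seq_along(zs)) for (bi in ai:length(zs)) {
    a <- zs[ai]; b <- zs[bi]
    rep_cut <- .pair_table(a, b, "rep_cut")
    key_r <- channel_key("R", a, b, "rep")
    sp_r <- channel_spline("R", c(a, b), "rep", 0, rep_cut,
                           n_basis = n_basis_repulsive)
    sp_r$curvature_sign <- 1
    repulsive[[key_r]] <- sp_r
  }
  parameter_set(shells, electronic, repulsive,
                meta = list(kind = "seed"))
}

# ---------------------------------------------------------------------------
# Template library (coordinates in Angstrom, standard bond lengths/angles)

.template_coords <- function() {
  deg <- pi / 180
  tpl <- list()
  tpl$H2 <- list(sym = c("H", "H"),
                 xyz = rbind(c(0, 0, 0), c(0, 0, 0.741)))
  st <- sin(52.25 * deg) * 0.958; ct <- cos(52.25 * deg) * 0.958
  tpl$H2O <- list(sym = c("O", "H", "H"),
                  xyz = rbind(c(0, 0, 0), c(st, 0, ct), c(-st, 0, ct)))
  sn <- sqrt((1 - cos(106.7 * deg)) / 1.5); cn <- sqrt(1 - sn^2)
  tpl$NH3 <- list(sym = c("N", "H", "H", "H"),
                  xyz = rbind(c(0, 0, 0), t(vapply(0:2, function(k)
                    1.012 * c(sn * cos(2 * pi * k / 3),
                              sn * sin(2 * pi * k / 3), cn),
                    numeric(3)))))
  u <- 1.087 / sqrt(3)
  tpl$CH4 <- list(sym = c("C", "H", "H", "H", "H"),
                  xyz = rbind(c(0, 0, 0), u * c(1, 1, 1), u * c(1, -1, -1),
                              u * c(-1, 1, -1), u * c(-1, -1, 1)))
  ch_z <- cos(111.2 * deg); ch_xy <- sin(111.2 * deg)
  mkch3 <- function(cpos, zdir, phi0) {
    t(vapply(0:2, function(k) {
      phi <- phi0 + 2 * pi * k / 3
      cpos + 1.09 * c(ch_xy * cos(phi), ch_xy * sin(phi), zdir * ch_z)
    }, numeric(3)))
  }
  tpl$C2H6 <- list(sym = c("C", "C", rep("H", 6)),
                   xyz = rbind(c(0, 0, -0.768), c(0, 0, 0.768),
                               mkch3(c(0, 0, -0.768), -1, 0),
                               mkch3(c(0, 0, 0.768), 1, pi / 3)))
  oh <- 0.96
  tpl$CH3OH <- list(sym = c("C", "O", "H", rep("H", 3)),
                    xyz = rbind(c(0, 0, 0), c(0, 0, 1.43),
                                c(oh * sin(108.5 * deg), 0,
                                  1.43 - oh * cos(108.5 * deg)),
                                mkch3(c(0, 0, 0), -1, pi / 3)))
  nh_z <- cos(110 * deg); nh_xy <- sin(110 * deg)
  tpl$CH3NH2 <- list(sym = c("C", "N", rep("H", 5)),
                     xyz = rbind(c(0, 0, 0), c(0, 0, 1.47),
                                 c(0, 0, 1.47) + 1.01 *
                                   c(nh_xy * cos(pi / 3), nh_xy * sin(pi / 3), -nh_z),
                                 c(0, 0, 1.47) + 1.01 *
                                   c(nh_xy * cos(-pi / 3), nh_xy * sin(-pi / 3), -nh_z),
                                 mkch3(c(0, 0, 0), -1, pi)))
  hx <- sin(121.9 * deg) * 1.101; hz <- cos(121.9 * deg) * 1.101
  tpl$H2CO <- list(sym = c("C", "O", "H", "H"),
                   xyz = rbind(c(0, 0, 0), c(0, 0, 1.205),
                               c(hx, 0, hz), c(-hx, 0, hz)))
  tpl$HCN <- list(sym = c("H", "C", "N"),
                  xyz = rbind(c(0, 0, -1.064), c(0, 0, 0), c(0, 0, 1.156)))
  ho_x <- 0.95 * sin(94.8 * deg); ho_z <- 0.95 * cos(94.8 * deg)
  dih <- 111.5 * deg
  tpl$H2O2 <- list(sym = c("O", "O", "H", "H"),
                   xyz = rbind(c(0, 0, 0), c(0, 0, 1.475),
                               c(ho_x, 0, ho_z),
                               c(ho_x * cos(dih), ho_x * sin(dih),
                                 1.475 - ho_z)))
  nnh_z <- cos(108 * deg); nnh_xy <- sin(108 * deg)
  nh2 <- function(npos, zdir, phi0) {
    t(vapply(c(phi0, phi0 + 109 * deg), function(phi)
      npos + 1.016 * c(nnh_xy * cos(phi), nnh_xy * sin(phi), zdir * nnh_z),
      numeric(3)))
  }
  tpl$N2H4 <- list(sym = c("N", "N", rep("H", 4)),
                   xyz = rbind(c(0, 0, 0), c(0, 0, 1.446),
                               nh2(c(0, 0, 0), -1, 0),
                               nh2(c(0, 0, 1.446), 1, pi / 2)))
  ex <- sin(121.3 * deg) * 1.086; ez <- -cos(121.3 * deg) * 1.086
  tpl$C2H4 <- list(sym = c("C", "C", rep("H", 4)),
                   xyz = rbind(c(0, 0, -0.6695), c(0, 0, 0.6695),
                               c(ex, 0, -0.6695 - ez), c(-ex, 0, -0.6695 - ez),
                               c(ex, 0, 0.6695 + ez), c(-ex, 0, 0.6695 + ez)))
  # three X-H bonds in a tetrahedral arrangement around `cpos`, pointing
  # away from the neighbor direction `u`
  tetra_h <- function(cpos, u, bond = 1.09, phi0 = 0) {
    u <- u / sqrt(sum(u^2))
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ct <- cos(109.47 * deg); st <- sin(109.47 * deg)
    t(vapply(0:2, function(k) {
      phi <- phi0 + 2 * pi * k / 3
      cpos + bond * (ct * u + st * (cos(phi) * e1 + sin(phi) * e2))
    }, numeric(3)))
  }
  # acetonitrile: methyl + C#N (covers the short C-N band together with HCN)
  tpl$CH3CN <- list(sym = c("C", "C", "N", rep("H", 3)),
                    xyz = rbind(c(0, 0, 0), c(0, 0, 1.46), c(0, 0, 2.616),
                                tetra_h(c(0, 0, 0), c(0, 0, 1), 1.095)))
  # propene: C=C and C-C in one molecule
  c1 <- c(0, 0, 0); c2 <- c(0, 0, 1.33)
  c3 <- c2 + 1.50 * c(sin(55.7 * deg), 0, cos(55.7 * deg))
  tpl$C3H6 <- list(sym = c("C", "C", "C", rep("H", 6)),
                   xyz = rbind(c1, c2, c3,
                               c1 + 1.086 * c(sin(121 * deg), 0, -cos(121 * deg)),
                               c1 + 1.086 * c(-sin(121 * deg), 0, -cos(121 * deg)),
                               c2 + 1.09 * c(-sin(61 * deg), 0, cos(61 * deg)),
                               tetra_h(c3, c2 - c3, 1.09, phi0 = pi / 6)))
  # formic acid: C=O, C-O and O-H in a planar frame
  o1 <- c(1.202, 0, 0)
  o2 <- 1.343 * c(cos(125 * deg), 0, sin(125 * deg))
  hc <- 1.097 * c(cos(-115 * deg), 0, sin(-115 * deg))
  vCO <- -o2 / sqrt(sum(o2^2))
  rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[3], 0,
                           sin(th) * v[1] + cos(th) * v[3])
  tpl$HCOOH <- list(sym = c("C", "O", "O", "H", "H"),
                    xyz = rbind(c(0, 0, 0), o1, o2, hc,
                                o2 + 0.972 * rot(vCO, 106 * deg)))
  # methyl hydroperoxide: O-O plus C-O
  oo1 <- c(0, 0, 1.42)
  oo2 <- oo1 + 1.46 * c(sin(105 * deg), 0, cos(105 * deg))
  hoo <- oo2 + 0.97 * c(0.35 * cos(100 * deg), 0.94, 0.35 * sin(100 * deg)) /
    sqrt(0.35^2 + 0.94^2)
  tpl$CH3OOH <- list(sym = c("C", "O", "O", "H", rep("H", 3)),
                     xyz = rbind(c(0, 0, 0), oo1, oo2, hoo,
                                 tetra_h(c(0, 0, 0), oo1, 1.09, phi0 = pi / 5)))
  # methylhydrazine: N-N plus C-N
  nn1 <- c(0, 0, 1.47)
  nn2 <- nn1 + 1.45 * c(sin(112 * deg), 0, cos(112 * deg))
  h_n1 <- nn1 + 1.01 * c(-0.55, 0.78, 0.30) / sqrt(0.55^2 + 0.78^2 + 0.30^2)
  h_n2 <- tetra_h(nn2, nn1 - nn2, 1.01, phi0 = 6.2)[1:2, ]
  tpl$CH3NHNH2 <- list(sym = c("C", "N", "N", rep("H", 6)),
                       xyz = rbind(c(0, 0, 0), nn1, nn2, h_n1, h_n2,
                                   tetra_h(c(0, 0, 0), nn1, 1.09, phi0 = 0.3)))
  tpl
}

#' Built-in molecular templates
#'
#' Standard-geometry templates of small C/N/O/H molecules used by the
#' synthetic-data sampler.
#'
#' @param names optional subset of template names
#' @return named list of \code{tb_geometry}
#' @export
geometry_templates <- function(names = NULL) {
  tpl <- .template_coords()
  if (!is.null(names)) {
    missing <- setdiff(names, names(tpl))
    if (length(missing)) stop("unknown template(s): ",
                              paste(missing, collapse = ", "))
    tpl <- tpl[names]
  }
  lapply(tpl, function(t) geometry(element_z(t$sym), t$xyz))
}

#' Sample distorted geometries from templates
#'
#' Applies independent Gaussian perturbations to every Cartesian coordinate
#' and rejects samples with any interatomic distance below the hard floor
#' (0.6 Angstrom) or below the electronic spline range of the pair (plus a
#' small margin), so that every emitted geometry is inside the trained
#' model's domain. The pairwise-distance distributions of the result show
#' the band structure typical of distorted equilibrium structures: sharp
#' bonded peaks truncated at the nearest-neighbor boundary and broader
#' long-range structure.
#'
#' @param templates template names (default: all built-ins)
#' @param n_per_template number of samples per template
#' @param distortion_scale Gaussian standard deviation per coordinate in
#'   Angstrom (default 0.05, a moderately distorted ensemble)
#' @param seed integer seed
#' @param hard_floor absolute minimum distance (default 0.6 Angstrom)
#' @param range_margin margin above each pair's spline lower bound
#'   (default 0.02 Angstrom)
#' @return a \code{tb_dataset}
#' @export
sample_geometries <- function(templates = NULL, n_per_template = 100L,
                              distortion_scale = 0.05, seed = 1L,
                              hard_floor = 0.6, range_margin = 0.02) {
  tpls <- geometry_templates(templates)
  rng <- .seeded_rng(seed)
  out <- list()
  n_tried <- 0L
  n_rejected <- 0L
  for (nm in names(tpls)) {
    g0 <- tpls[[nm]]
    nat <- length(g0$z)
    pair_lows <- matrix(hard_floor, nat, nat)
    for (a in seq_len(nat)) for (b in seq_len(nat)) {
      if (a != b)
        pair_lows[a, b] <- max(hard_floor,
                               .pair_table(g0$z[a], g0$z[b], "r_low") +
                                 range_margin)
    }
    made <- 0L
    while (made < n_per_template) {
      n_tried <- n_tried + 1L
      if (n_tried > 50L && n_rejected / n_tried > 0.9)
        stop("rejection rate above 90%; reduce distortion_scale")
      xyz <- g0$xyz + matrix(rng$rnorm(3L * nat, sd = distortion_scale),
                             nat, 3L)
      if (nat > 1L) {
        D <- as.matrix(stats::dist(xyz))
        diag(D) <- Inf
        if (any(D < pair_lows)) {
          n_rejected <- n_rejected + 1L
          next
        }
      }
      made <- made + 1L
      out[[length(out) + 1L]] <- geometry(g0$z, xyz)
    }
  }
  dataset(out)
}

#' Attach toy-model targets to a dataset
#'
#' Evaluates the toy parameter set on every configuration by a full SCC
#' calculation. The energy target is the toy total (electronic + repulsive)
#' energy plus per-element offsets \code{sum_Z N_Z offset_Z} (emulating the
#' isolated-atom content of ab initio totals) plus optional Gaussian noise;
#' dipole and charge targets come from the converged charge fluctuations
#' (plus optional independent noise). Configurations whose SCF fails are
#' dropped with a message.
#'
#' @param ds a \code{tb_dataset}
#' @param toy_params the generating \code{tb_paramset}
#' @param element_offsets named numeric (Hartree per element symbol),
#'   default all zero
#' @param noise_sd energy noise standard deviation in Hartree (default 0)
#' @param dipole_noise_sd,charge_noise_sd optional independent noise
#' @param seed integer seed for the noise
#' @param method target label (default \code{"toy-truth"})
#' @param scf \code{\link{scf_options}}
#' @return the dataset with targets attached
#' @export
make_targets <- function(ds, toy_params, element_offsets = NULL,
                         noise_sd = 0, dipole_noise_sd = 0,
                         charge_noise_sd = 0, seed = 1L,
                         method = "toy-truth", scf = scf_options()) {
  if (!length(ds)) return(ds)
  layout <- params_layout(toy_params)
  x <- params_pack(toy_params, layout)
  cache <- precompute_batch(ds, toy_params, layout)
  design <- .repulsive_design(ds, toy_params)
  rep_coef <- unlist(lapply(design$rep_keys, function(k)
    spline_get_free(toy_params$repulsive[[k]])))
  erep <- drop(design$M[, seq_len(design$n_rep), drop = FALSE] %*% rep_coef)
  rng <- .seeded_rng(seed)
  out <- list()
  n_dropped <- 0L
  for (i in seq_along(ds)) {
    res <- cpp_scf_mol(cache[[i]], x, scf)
    if (!isTRUE(res$ok) || !isTRUE(res$converged)) {
      n_dropped <- n_dropped + 1L
      next
    }
    g <- ds[[i]]
    off <- 0
    if (!is.null(element_offsets)) {
      syms <- element_symbol(g$z)
      for (s in names(element_offsets))
        off <- off + sum(syms == s) * element_offsets[[s]]
    }
    energy <- res$e_electronic + erep[i] + off +
      (if (noise_sd > 0) rng$rnorm(1, sd = noise_sd) else 0)
    dip <- drop(res$dipole)
    if (dipole_noise_sd > 0) dip <- dip + rng$rnorm(3, sd = dipole_noise_sd)
    ch <- drop(res$q_atom)
    if (charge_noise_sd > 0) ch <- ch + rng$rnorm(length(ch), sd = charge_noise_sd)
    g$targets[[method]] <- list(energy = energy, dipole = dip, charges = ch)
    out[[length(out) + 1L]] <- g
  }
  if (n_dropped > 0L)
    message(n_dropped, " configuration(s) dropped: SCF did not converge")
  dataset(out)
}
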