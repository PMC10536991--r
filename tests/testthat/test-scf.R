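test_that("Coulomb kernel limits: long range 1/R, on-site U, monotone bounded", {
  ps <- fx_toy_ho()
  g <- geometry(c(8L, 8L), rbind(c(0, 0, 0), c(0, 0, 50 * ANG_PER_BOHR)))
  gm <- gamma_matrix(g, ps)
  expect_lt(abs(gm$gamma[1, 3] - 1 / 50), 1e-9)   # s(O1) with s(O2)
  # same shell at R = 0 gives the Hubbard parameter
  g1 <- geometry(8L, matrix(0, 1, 3))
  gm1 <- gamma_matrix(g1, ps)
  expect_equal(gm1$gamma[1, 1], hubbard_of(ps, 8L, "s"), tolerance = 1e-14)
  expect_equal(gm1$gamma[2, 2], hubbard_of(ps, 8L, "p"), tolerance = 1e-14)
  # dense grid: strictly decreasing, positive, below both U and 1/R
  Ua <- 0.42; Ub <- 0.31
  R <- seq(0.05, 40, length.out = 800)
  gam <- vapply(R, function(r)
    cpp_gamma_matrix(c(Ua, Ub), matrix(c(0, r, r, 0), 2, 2))[1, 2], numeric(1))
  expect_true(all(diff(gam) < 0))
  expect_true(all(gam > 0))
  # bounded by the on-site limit (a mean of the two hardnesses) and by 1/R
  g0 <- cpp_gamma_matrix(c(Ua, Ub), matrix(0, 2, 2))[1, 2]
  expect_true(all(gam <= g0 + 1e-12))
  expect_lte(g0, max(Ua, Ub))
  expect_gte(g0, min(Ua, Ub))
  expect_true(all(gam <= 1 / R + 1e-12))
})

test_that("zero Coulomb kernel gives the band-structure limit in one pass", {
  ps <- fx_toy_ho()
  g <- fx_water()
  mp <- assemble_matrices(g, ps)
  gm <- gamma_matrix(g, ps)
  res <- scf_solve(mp, matrix(0, nrow(gm$gamma), ncol(gm$gamma)),
                   n_electrons(g))
  expect_true(res$converged)
  expect_equal(res$n_iterations, 1L)
  expect_equal(res$electronic_energy, sum(res$density_matrix * mp$H1),
               tolerance = 1e-12)
})

test_that("homonuclear diatomics carry zero charge fluctuations", {
  ps <- fx_toy_ho()
  for (r in c(0.65, 0.741, 0.85)) {
    g <- geometry(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, r)))
    res <- scf_solve(assemble_matrices(g, ps), gamma_matrix(g, ps), 2L)
    expect_true(res$converged)
    expect_lt(max(abs(res$delta_q)), 1e-12)
    # minimal-model H2: each atom population exactly 1
    expect_equal(drop(res$populations), c(1, 1), tolerance = 1e-12)
  }
})

test_that("converged solutions satisfy the fixed point and energy identity", {
  ps <- fx_toy_ho()
  opts <- scf_options()
  for (g in fx_ho_data()[seq(1, 36, by = 4)]) {
    mp <- assemble_matrices(g, ps)
    gm <- gamma_matrix(g, ps)
    res <- scf_solve(mp, gm, n_electrons(g), opts)
    expect_true(res$converged)
    # electron conservation
    expect_lt(abs(sum(res$populations) - n_electrons(g)), 1e-10)
    # re-entering the converged state changes charges by < 10x tolerance
    pop2 <- mulliken_populations(res$density_matrix, mp$S, mp$orbital_map)
    dq2 <- pop2 - gm$shells$occupancy
    expect_lt(max(abs(dq2 - res$delta_q)), 10 * opts$tol)
    # independent energy expression: E = Tr(P H1) + 1/2 dq G dq
    e_direct <- sum(res$density_matrix * mp$H1) +
      0.5 * drop(res$delta_q %*% gm$gamma %*% res$delta_q)
    expect_lt(abs(e_direct - res$electronic_energy), 1e-10)
  }
})

test_that("converged energy does not exceed the first-iteration energy", {
  ps <- fx_toy_ho()
  for (g in fx_ho_data()[c(14, 26, 30)]) {
    mp <- assemble_matrices(g, ps)
    gm <- gamma_matrix(g, ps)
    res <- scf_solve(mp, gm, n_electrons(g))
    res1 <- scf_solve(mp, gm, n_electrons(g), scf_options(max_iter = 1L))
    e1 <- sum(res1$density_matrix * mp$H1) +
      0.5 * drop(res1$delta_q %*% gm$gamma %*% res1$delta_q)
    expect_lte(res$electronic_energy, e1 + 1e-12)
  }
})

test_that("Mulliken populations with identity overlap are diagonal sums", {
  P <- diag(c(2, 1.5, 0.5, 2))
  om <- data.frame(atom = c(1, 2, 2, 2), z = c(1, 8, 8, 8),
                   shell = c("s", "s", "p", "p"), m = c("s", "s", "x", "y"),
                   shell_id = c(1, 2, 3, 3))
  pops <- mulliken_populations(P, diag(4), om)
  expect_equal(pops, c(2, 1.5, 2.5))
})

test_that("dipole definition, translation invariance and sign convention", {
  g <- geometry(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(dipole_moment(g, c(-0.1, 0.1)), c(0, 0, 0.1))
  expect_equal(dipole_moment(g, c(0, 0)), c(0, 0, 0))
  # neutral molecule: invariant under origin shift
  ps <- fx_toy_ho()
  gw <- fx_water()
  res <- scf_compute(gw, ps)
  shift <- c(1.3, -2.2, 0.7)
  g2 <- geometry(gw$z, sweep(gw$xyz, 2, -shift))
  res2 <- scf_compute(g2, ps)
  expect_lt(max(abs(res2$dipole - res$dipole)), 1e-12)
  # oxygen is electron-rich: negative charge, positive on hydrogens
  expect_lt(res$charges[1], 0)
  expect_gt(res$charges[2], 0)
})

test_that("structural failures raise errors, non-convergence only flags", {
  ps <- fx_toy_ho()
  g <- fx_water()
  mp <- assemble_matrices(g, ps)
  gm <- gamma_matrix(g, ps)
  expect_error(scf_solve(mp, gm, 7L), "odd electron")
  bad <- mp
  bad$S <- diag(-1, nrow(mp$S))
  expect_error(scf_solve(bad, gm, n_electrons(g)), "positive definite")
  res <- scf_solve(mp, gm, n_electrons(g), scf_options(max_iter = 2L,
                                                       mixing = 0.01))
  expect_false(res$converged)   # flagged, not thrown
})
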