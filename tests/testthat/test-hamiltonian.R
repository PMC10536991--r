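test_that("axis-aligned Slater-Koster block reduces to channel values", {
  vals <- list(ss = 0.3, sp_ab = 0.2, sp_ba = -0.15, pp_sigma = -0.4,
               pp_pi = 0.1)
  blk <- sk_pair_block(vals, c(0, 0, 1), TRUE, TRUE)
  expect_equal(blk[1, 1], 0.3)
  expect_equal(blk[1, 4], 0.2)          # s_a with p_z(b) along the bond
  expect_equal(blk[1, 2:3], c(0, 0))    # s-p cross terms off-axis vanish
  expect_equal(blk[4, 1], 0.15)         # p_z(a) with s_b carries -d * sp_ba
  expect_equal(blk[4, 4], -0.4)         # pp sigma
  expect_equal(blk[2, 2], 0.1)          # pp pi (x-x)
  expect_equal(blk[3, 3], 0.1)
  expect_equal(blk[2, 3], 0)
  expect_error(sk_pair_block(vals, c(0, 0, 2), TRUE, TRUE), "unit")
})

test_that("rotating the geometry commutes with rotating the block", {
  vals <- list(ss = 0.31, sp_ab = 0.22, sp_ba = -0.18, pp_sigma = -0.37,
               pp_pi = 0.12)
  set.seed(12)
  for (k in 1:20) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    blk <- sk_pair_block(vals, d, TRUE, TRUE)
    blk_rot <- sk_pair_block(vals, drop(R %*% d), TRUE, TRUE)
    # orbital rotation: s invariant, p rotates with R
    U <- rbind(c(1, 0, 0, 0), cbind(0, R))
    expect_lt(max(abs(blk_rot - U %*% blk %*% t(U))), 1e-12)
  }
})

test_that("single atoms give on-site H1 and identity S", {
  ps <- fx_toy_ho()
  g <- geometry(8L, matrix(c(1, 2, 3), 1))
  mp <- assemble_matrices(g, ps)
  expect_equal(mp$S, diag(4))
  expect_equal(diag(mp$H1),
               c(onsite_of(ps, 8L, "s"), rep(onsite_of(ps, 8L, "p"), 3)))
  expect_equal(mp$H1 - diag(diag(mp$H1)), matrix(0, 4, 4))
})

test_that("off-diagonal blocks vanish beyond the electronic cutoff", {
  ps <- fx_toy_ho()
  g <- geometry(c(8L, 8L), rbind(c(0, 0, 0), c(0, 0, 5.0)))
  mp <- assemble_matrices(g, ps)
  expect_identical(max(abs(mp$H1[1:4, 5:8])), 0)
  expect_identical(max(abs(mp$S[1:4, 5:8])), 0)
})

test_that("assembled matrices are symmetric with unit overlap diagonal", {
  ps <- fx_toy_ho()
  for (g in fx_ho_data()[c(1, 15, 30)]) {
    mp <- assemble_matrices(g, ps)
    expect_identical(mp$H1, t(mp$H1))
    expect_identical(mp$S, t(mp$S))
    expect_equal(diag(mp$S), rep(1, nrow(mp$S)))
  }
})

test_that("eigenspectrum is invariant under rigid rotations and translations", {
  ps <- fx_toy_ho()
  g <- fx_ho_data()[[30]]  # an H2O2 configuration
  mp <- assemble_matrices(g, ps)
  e_ref <- sort(geigen_vals(mp))
  set.seed(77)
  worst <- 0
  for (k in 1:100) {
    rm <- rigid_motion(g$xyz)
    mp2 <- assemble_matrices(geometry(g$z, rm$xyz), ps)
    worst <- max(worst, max(abs(sort(geigen_vals(mp2)) - e_ref)))
  }
  expect_lt(worst, 1e-10)
})

test_that("toy-orbital pair blocks match numerical integration of orbitals", {
  # overlap block of an O-H pair from the generated channels vs the analytic
  # STO values rotated into the molecular frame
  ps <- fx_toy_ho()
  d <- c(1, 2, 2) / 3
  r <- 1.1
  g <- geometry(c(8L, 1L), rbind(c(0, 0, 0), r * d))
  mp <- assemble_matrices(g, ps)
  blk <- mp$S[1:4, 5, drop = TRUE]   # O orbitals with H s
  ss <- sto_channel_overlap(1, 8, "ss_sigma", r)
  # <p_i(O)|s(H)> = d_i <p_d(O)|s(H)> = -d_i * (sp sigma of the ordered
  # pair (H, O), whose p points from H toward O)
  sp <- sto_channel_overlap(1, 8, "sp_sigma", r)
  expect_lt(abs(blk[1] - ss), 2e-6)
  expect_lt(max(abs(blk[2:4] + d * sp)), 2e-6)
})

test_that("cache rebuild equals direct assembly for random coefficients", {
  ps <- fx_toy_ho()
  layout <- params_layout(ps)
  ds <- fx_ho_data()[c(2, 20)]
  cache <- precompute_batch(ds, ps, layout)
  set.seed(3)
  for (k in 1:5) {
    x <- params_pack(ps, layout) + 0.05 * rnorm(layout$n_par)
    psx <- params_unpack(ps, layout, x)
    for (i in seq_along(ds)) {
      ca <- cache_assemble(cache[[i]], x)
      mp <- assemble_matrices(ds[[i]], psx)
      expect_lt(max(abs(ca$H1 - mp$H1)), 1e-12)
      expect_lt(max(abs(ca$S - mp$S)), 1e-12)
    }
  }
})

test_that("cache construction is deterministic and parameter independent", {
  ps <- fx_toy_ho()
  layout <- params_layout(ps)
  ds <- fx_ho_data()[c(1, 5)]
  c1 <- precompute_batch(ds, ps, layout, method = "toy-truth")
  c2 <- precompute_batch(ds, ps, layout, method = "toy-truth")
  expect_identical(serialize(unclass(c1), NULL), serialize(unclass(c2), NULL))
  # the cache stays valid for any coefficients: no field depends on them
  x1 <- params_pack(ps, layout)
  x2 <- x1 + 0.1
  a1 <- cache_assemble(c1[[1]], x1)
  a2 <- cache_assemble(c1[[1]], x2)
  expect_false(isTRUE(all.equal(a1$H1, a2$H1)))  # values respond to x ...
  expect_identical(c1[[1]]$h1_tv, c2[[1]]$h1_tv) # ... while the map is fixed
})

test_that("distances below the guard raise an error, inside it a warning", {
  ps <- fx_toy_ho()
  g_warn <- geometry(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, 0.52)))
  expect_warning(assemble_matrices(g_warn, ps), "extrapolation")
  g_err <- geometry(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, 0.4)))
  expect_error(assemble_matrices(g_err, ps), "below the spline range")
})
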