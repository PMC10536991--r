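test_that("upper boundary conditions hold structurally for any coefficients", {
  sp <- channel_spline("S", c(1, 8), "ss_sigma", 0.6, 4.5)
  set.seed(1)
  sp <- spline_set_free(sp, rnorm(spline_n_free(sp)))
  expect_identical(spline_eval(sp, 4.5), 0)
  expect_identical(spline_eval(sp, 4.5, 1L), 0)
  expect_identical(spline_eval(sp, c(4.6, 7, 100)), c(0, 0, 0))
  # zero coefficients: zero everywhere, all derivatives too
  sp0 <- channel_spline("H1", c(1, 1), "ss_sigma", 0.5, 4.5)
  r <- seq(0.3, 5, by = 0.17)
  for (d in 0:3) expect_identical(spline_eval(sp0, r, d), rep(0, length(r)))
})

# independent oracle: Cox-de Boor recursion for B-spline basis values
cox_de_boor <- function(knots, i, k, x) {
  if (k == 0) {
    # right-closed at the final knot so the last basis function is 1 there
    hi <- knots[i + 1]
    lo <- knots[i]
    return(as.numeric(x >= lo & (x < hi | (x == hi & hi == max(knots)))))
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(knots, i, k - 1, x) else 0
  t2 <- if (d2 > 0) (knots[i + k + 1] - x) / d2 *
    cox_de_boor(knots, i + 1, k - 1, x) else 0
  t1 + t2
}

test_that("evaluation matches an independent Cox-de Boor recursion", {
  sp <- channel_spline("S", c(1, 1), "ss_sigma", 0.5, 4.5, n_basis = 20L)
  set.seed(7)
  z <- rnorm(spline_n_free(sp))
  sp <- spline_set_free(sp, z)
  r <- runif(100, 0.5, 4.4999)
  ref <- rowSums(vapply(seq_len(sp$n_basis), function(i)
    sp$coefficients[i] * cox_de_boor(sp$knots_full, i, sp$degree, r),
    numeric(length(r))))
  got <- spline_eval(sp, r)
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-12)
})

test_that("design matrix is the exact linear map and obeys linearity", {
  sp <- channel_spline("R", c(1, 6), "rep", 0, 1.6)
  r <- seq(-0.2, 2.0, by = 0.13)   # includes extrapolation and beyond-cutoff
  M <- spline_design_matrix(sp, r, 0L)
  set.seed(2)
  for (k in 1:5) {
    c1 <- rnorm(sp$n_basis); c1[sp$n_basis - 1:0] <- 0
    sp1 <- sp; sp1$coefficients <- c1
    expect_equal(drop(M %*% c1), spline_eval(sp1, r), tolerance = 1e-14)
  }
  # one-hot columns equal basis functions
  onehot <- numeric(sp$n_basis); onehot[4] <- 1
  sph <- sp; sph$coefficients <- onehot
  expect_equal(M[, 4], spline_eval(sph, r), tolerance = 1e-14)
  # linearity to machine precision
  c2 <- rnorm(sp$n_basis); c2[sp$n_basis - 1:0] <- 0
  expect_equal(drop(M %*% (2 * c1 - 3 * c2)),
               2 * drop(M %*% c1) - 3 * drop(M %*% c2), tolerance = 1e-13)
})

test_that("second-derivative design equals finite differences of values", {
  sp <- channel_spline("S", c(6, 6), "pp_pi", 1.0, 4.5)
  set.seed(3)
  sp <- spline_set_free(sp, rnorm(spline_n_free(sp)) * 0.1)
  r <- seq(1.2, 4.2, by = 0.05)
  h <- 1e-4
  fd2 <- (spline_eval(sp, r + h) - 2 * spline_eval(sp, r) +
            spline_eval(sp, r - h)) / h^2
  f2 <- spline_eval(sp, r, 2L)
  expect_lt(max(abs(fd2 - f2)) / max(abs(f2)), 1e-4)  # O(h^2) agreement
})

test_that("derivatives beyond the smoothness class raise errors", {
  sp_e <- channel_spline("S", c(1, 1), "ss_sigma", 0.5, 4.5)
  expect_silent(spline_eval(sp_e, 2, 3L))
  expect_error(spline_eval(sp_e, 2, 5L), "smoothness")
  sp_r <- channel_spline("R", c(1, 1), "rep", 0, 1.1)
  expect_silent(spline_eval(sp_r, 0.8, 2L))
  expect_error(spline_eval(sp_r, 0.8, 3L), "smoothness")
})

test_that("extrapolation below r_low continues the first polynomial piece", {
  sp <- spline_fit(channel_spline("H1", c(1, 6), "ss_sigma", 0.7, 4.5),
                   seq(0.7, 4.5, 0.01), -0.4 * exp(-seq(0.7, 4.5, 0.01) / 0.8))
  h <- 1e-6
  f0 <- spline_eval(sp, 0.7)
  f1 <- spline_eval(sp, 0.7, 1L)
  f2 <- spline_eval(sp, 0.7, 2L)
  # Taylor continuation: f(r_low - d) = f - d f' + d^2/2 f'' + O(d^3)
  for (d in c(1e-4, 1e-3, 1e-2)) {
    expect_lt(abs(spline_eval(sp, 0.7 - d) - (f0 - d * f1 + d^2 / 2 * f2)),
              10 * d^3 * abs(f2) / abs(f0) + 1e-12)
  }
})
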