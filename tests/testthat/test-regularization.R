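test_that("convex penalty is zero exactly on conforming shapes, positive otherwise", {
  # decaying exponential approaching zero from above: upward curvature
  sp <- spline_fit_shaped(channel_spline("H1", c(1, 1), "ss_sigma", 0.6, 4.5),
                          seq(0.6, 4.5, 0.01),
                          0.3 * exp(-seq(0.6, 4.5, 0.01) / 0.7) *
                            tbtrain:::.taper(seq(0.6, 4.5, 0.01)))
  expect_equal(sp$curvature_sign, 1)
  expect_lt(convex_penalty(sp), 1e-16)
  # every generated toy channel conforms to its assigned class
  ps <- fx_toy_ho()
  for (k in names(ps$electronic)) {
    spk <- ps$electronic[[k]]
    pen <- if (startsWith(k, "S:") && !is.null(spk$inflection_x))
      inflection_convex_penalty(spk) else convex_penalty(spk)
    expect_lt(pen, 1e-16)
  }
  for (k in names(ps$repulsive))
    expect_lt(convex_penalty(ps$repulsive[[k]], sign = 1), 1e-16)
  # sinusoidal coefficients violate everywhere
  spb <- spline_set_free(sp, sin(seq_len(spline_n_free(sp)) / 2))
  expect_gt(convex_penalty(spb, sign = 1), 1)
})

test_that("convex penalty equals the brute-force grid sum", {
  sp <- channel_spline("S", c(1, 8), "ss_sigma", 0.7, 4.5)
  set.seed(5)
  sp <- spline_set_free(sp, rnorm(spline_n_free(sp)))
  cfg <- penalty_config()
  for (s in c(1, -1)) {
    r <- penalty_grid(sp, cfg$grid_n)
    f2 <- drop(spline_design_matrix(sp, r, 2L) %*% sp$coefficients)
    brute <- sum(pmax(0, -s * f2)^2)
    expect_equal(convex_penalty(sp, cfg, sign = s), brute, tolerance = 1e-12)
  }
})

test_that("smoothing penalty: zero on quadratics, degree-2 homogeneous", {
  sp <- channel_spline("S", c(1, 1), "ss_sigma", 0.5, 4.5)
  # represent a global quadratic with the boundary conditions at the cutoff:
  # q(r) = (r - r_cut)^2 has q(rc) = q'(rc) = 0 and zero third derivative
  r <- seq(0.5, 4.5, length.out = 400)
  spq <- spline_fit(sp, r, (r - 4.5)^2, ridge = 0)
  expect_lt(smoothing_penalty(spq), 1e-12)
  set.seed(6)
  spr <- spline_set_free(sp, rnorm(spline_n_free(sp)))
  p1 <- smoothing_penalty(spr)
  spr2 <- spline_set_free(sp, 2 * spline_get_free(spr))
  expect_equal(smoothing_penalty(spr2), 4 * p1, tolerance = 1e-12)
  # refusing repulsive splines
  expect_error(smoothing_penalty(channel_spline("R", c(1, 1), "rep", 0, 1.1)),
               "order")
})

test_that("smoothing penalty matches the closed form for single-piece quintics", {
  # no interior knots: a single quintic polynomial piece
  sp <- channel_spline("H1", c(1, 1), "ss_sigma", 1, 3, n_basis = 6L)
  # f(r) = (r - 3)^2 (a + b r + c r^2 + d r^3) satisfies the cutoff conditions
  co <- c(0.4, -0.3, 0.25, -0.08)
  f <- function(r) (r - 3)^2 * (co[1] + co[2] * r + co[3] * r^2 + co[4] * r^3)
  rs <- seq(1, 3, length.out = 30)
  spf <- spline_fit(sp, rs, f(rs), ridge = 0)
  expect_lt(max(abs(spline_eval(spf, rs) - f(rs))), 1e-10)
  # monomial coefficients of f: expand (r-3)^2 * cubic
  pc <- convolve(c(9, -6, 1), rev(co), type = "open")  # a0..a5
  a3 <- pc[4]; a4 <- pc[5]; a5 <- pc[6]
  # the final grid point sits at the cutoff, where the channel (and all its
  # derivatives) are zero by convention, so it drops out of the closed form
  grid <- penalty_grid(spf, 500L)
  grid <- grid[-length(grid)]
  closed <- sum((6 * a3 + 24 * a4 * grid + 60 * a5 * grid^2)^2)
  expect_equal(smoothing_penalty(spf), closed, tolerance = 1e-10)
})

test_that("inflection penalty recovers a constructed inflection point", {
  # logistic (sigmoid) overlap shape with analytic inflection at x0
  x0 <- 2.1
  r <- seq(0.8, 4.5, length.out = 500)
  y <- 0.5 / (1 + exp((r - x0) / 0.35)) * tbtrain:::.taper(r)
  sp <- spline_fit(channel_spline("S", c(1, 8), "ss_sigma", 0.8, 4.5), r, y)
  sp$curvature_sign <- 1   # approaches zero from above
  # zero (numerically) at the true inflection, positive 0.5 A away
  p_at <- inflection_convex_penalty(sp, inflection_x = x0)
  expect_lt(p_at, 1e-8)
  expect_gt(inflection_convex_penalty(sp, inflection_x = x0 - 0.5), 1e4 * max(p_at, 1e-12))
  expect_gt(inflection_convex_penalty(sp, inflection_x = x0 + 0.5), 1e4 * max(p_at, 1e-12))
  # 1-D scan: the minimizer lies within one grid spacing of x0
  cand <- penalty_grid(sp, 500L)
  vals <- vapply(cand, function(xc)
    inflection_convex_penalty(sp, inflection_x = xc), numeric(1))
  expect_lt(abs(cand[which.min(vals)] - x0), 2 * (cand[2] - cand[1]))
  # degenerate placement at r_low reduces to the plain convex penalty
  sp2 <- spline_set_free(sp, rnorm(spline_n_free(sp)))
  expect_equal(inflection_convex_penalty(sp2, inflection_x = sp2$r_low, sign = 1),
               convex_penalty(sp2, sign = 1), tolerance = 1e-14)
})

test_that("penalty gradients match finite differences", {
  ps <- fx_seed_ho()
  layout <- params_layout(ps)
  x <- params_pack(ps, layout)
  set.seed(8)
  # small perturbation keeps the penalty magnitude low enough that central
  # differences stay rounding-accurate
  xr <- x + 2e-4 * rnorm(length(x))
  pens <- tbtrain:::build_penalty_descriptors(ps, layout, penalty_config())
  pf <- function(xv) tbtrain:::penalty_eval(pens, xv, FALSE)$penalty
  pg <- tbtrain:::penalty_eval(pens, xr, TRUE)$grad
  idx <- c(1, 55, 300, 700, unname(layout$inflection))
  h <- 1e-5
  num <- vapply(idx, function(i) {
    xp <- xr; xp[i] <- xp[i] + h
    xm <- xr; xm[i] <- xm[i] - h
    (pf(xp) - pf(xm)) / (2 * h)
  }, numeric(1))
  # relative to each gradient, floored at a small fraction of the dominant
  # gradient scale (tiny components are checked absolutely: central
  # differences of the large objective cannot resolve them more finely)
  floor_ <- 1e-3 * max(abs(pg[idx]))
  rel <- abs(pg[idx] - num) / pmax(abs(num), abs(pg[idx]), floor_)
  expect_lt(max(rel), 1e-5)
})
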