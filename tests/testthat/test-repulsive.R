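test_that("reference fit: identical methods, exact recovery, orthogonality", {
  # formula strings with compositional variety (H and O counts both vary)
  fml <- c("H2", "H2O", "H2O2", "H4O", "H2O", "H4O2", "H2", "H6O2")
  counts <- vapply(fml, formula_counts2, numeric(2))
  e_a <- rnorm(length(fml), -10, 1)
  f0 <- fit_reference_energy(e_a, e_a, fml)
  expect_lt(max(abs(unlist(f0$reference))), 1e-12)
  expect_lt(max(abs(f0$residuals)), 1e-12)
  truth <- c(H = -0.53, O = -74.9)
  e_b <- e_a + truth["H"] * counts[1, ] + truth["O"] * counts[2, ] + 0.017
  fit <- fit_reference_energy(e_a, e_b, fml)
  expect_lt(abs(fit$reference$c_elements[["H"]] - truth[["H"]]), 1e-12)
  expect_lt(abs(fit$reference$c_elements[["O"]] - truth[["O"]]), 1e-12)
  expect_lt(abs(fit$reference$c0 - 0.017), 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  # normal equations: residuals orthogonal to every design column
  e_c <- e_b + rnorm(length(fml), sd = 1e-3)
  fit2 <- fit_reference_energy(e_a, e_c, fml)
  orth <- drop(crossprod(fit2$design, fit2$residuals))
  expect_lt(max(abs(orth)), 1e-10)
})

test_that("rank-deficient reference designs error, naming the columns", {
  expect_error(fit_reference_energy(c(1, 2, 3), c(1.2, 2.2, 3.2),
                                    c("H2O", "H2O", "H2O")),
               "collinear")
})

test_that("zero targets give zero repulsive coefficients and objective", {
  ps <- fx_toy_ho()
  ds <- fx_ho_data()[1:12]
  elec <- vapply(seq_along(ds), function(i) i * 0.1 - 3, numeric(1))
  fit <- fit_repulsive_and_reference(ds, elec, elec, ps, ridge = 1e-12)
  expect_lt(fit$objective, 1e-8)
  expect_lt(max(abs(fit$fitted)), 1e-4)
})

test_that("repulsive + offsets are recovered from exact electronic energies", {
  ps <- fx_toy_ho()
  ds <- fx_repulsive_probe_set()
  # targets built from the known toy repulsive plus per-element offsets;
  # electronic energies are an input to the fit and are set to a known shape
  offsets <- c(H = -0.51, O = -74.8)
  des_true <- tbtrain:::.repulsive_design(ds, ps)
  rep_true <- unlist(lapply(des_true$rep_keys, function(k)
    spline_get_free(ps$repulsive[[k]])))
  erep_true <- drop(des_true$M[, seq_len(des_true$n_rep), drop = FALSE] %*%
                      rep_true)
  elec <- vapply(seq_along(ds), function(i) -1 - 0.01 * i, numeric(1))
  nH <- vapply(ds, function(g) sum(g$z == 1L), numeric(1))
  nO <- vapply(ds, function(g) sum(g$z == 8L), numeric(1))
  targets <- elec + erep_true + offsets["H"] * nH + offsets["O"] * nO
  ps0 <- ps
  for (k in names(ps0$repulsive))
    ps0$repulsive[[k]] <- spline_set_free(
      ps0$repulsive[[k]], numeric(spline_n_free(ps0$repulsive[[k]])))
  fit <- fit_repulsive_and_reference(ds, elec, targets, ps0, ridge = 1e-14)
  expect_lt(abs(fit$ps$reference$c_elements[["H"]] - offsets[["H"]]), 1e-6)
  expect_lt(abs(fit$ps$reference$c_elements[["O"]] - offsets[["O"]]), 1e-6)
  # recovered repulsive curves match the generating splines over the
  # sampled distance range
  for (k in names(ps$repulsive)) {
    rc <- ps$repulsive[[k]]$r_cut
    dd <- unlist(lapply(ds, function(g) {
      D <- as.matrix(stats::dist(g$xyz)); zz <- g$z
      o <- c()
      for (a in 1:(length(zz) - 1)) for (b in (a + 1):length(zz)) {
        kk <- channel_key("R", min(zz[a], zz[b]), max(zz[a], zz[b]), "rep")
        if (kk == k && D[a, b] < rc) o <- c(o, D[a, b])
      }
      o
    }))
    if (length(dd) < 5) next
    dev <- abs(spline_eval(fit$ps$repulsive[[k]], dd) -
                 spline_eval(ps$repulsive[[k]], dd))
    expect_lt(max(dev) * KCAL_PER_HA, 0.1)
  }
  # boundary conditions hold exactly
  for (k in names(fit$ps$repulsive)) {
    sp <- fit$ps$repulsive[[k]]
    expect_identical(spline_eval(sp, sp$r_cut), 0)
    expect_identical(spline_eval(sp, sp$r_cut, 1L), 0)
  }
})

test_that("interior-point and dual solvers find the same global optimum", {
  ps <- fx_toy_ho()
  set.seed(9)
  ds <- fx_ho_data()
  idx <- sample(length(ds), 30)
  layout <- params_layout(ps)
  cache <- precompute_batch(ds[idx], ps, layout, method = "toy-truth")
  rf <- tbtrain:::.scf_refresh(cache, params_pack(ps, layout), scf_options())
  te <- vapply(cache, function(m) m$t_energy, numeric(1))
  f1 <- fit_repulsive_and_reference(ds[idx], rf$elec, te, ps, solver = "ip")
  f2 <- fit_repulsive_and_reference(ds[idx], rf$elec, te, ps,
                                    solver = "dual_pg")
  scale_ <- sum((te - rf$elec)^2)
  expect_lt(abs(f1$objective - f2$objective) / scale_, 1e-8)
  # restart invariance of the interior point (criterion: convexity)
  des <- tbtrain:::.repulsive_design(ds[idx], ps)
  y <- te - rf$elec
  Q <- 2 * crossprod(des$M); diag(Q) <- diag(Q) + 1e-7 * mean(diag(Q))
  cc <- -2 * drop(crossprod(des$M, y))
  A <- tbtrain:::.repulsive_constraints(ps, des)
  ref <- qp_solve_ip(Q, cc, A, rep(0, nrow(A)))
  set.seed(10)
  for (k in 1:3) {
    s <- qp_solve_ip(Q, cc, A, rep(0, nrow(A)),
                     x0 = rnorm(length(cc), sd = 0.5))
    expect_lt(abs(s$objective - ref$objective) /
                max(abs(ref$objective), 1), 1e-8)
  }
})

test_that("formula parsing round trips", {
  expect_equal(formula_counts("C2H6O"), c(C = 2L, H = 6L, O = 1L))
  expect_equal(formula_counts("H2O"), c(H = 2L, O = 1L))
  expect_equal(empirical_formula(c(6, 1, 1, 1, 1)), "CH4")
  expect_equal(empirical_formula(c(8, 1, 1)), "H2O")
  expect_equal(empirical_formula(c(7, 7, 1, 1, 1, 1)), "H4N2")
  expect_error(formula_counts("xyz"), "cannot parse")
})
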