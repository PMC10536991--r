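test_that("loss follows the weighted L2 form with per-property normalization", {
  preds <- list(list(energy = -5.0, dipole = c(0.1, 0, 0), charges = c(0.2, -0.2),
                     n_heavy = 2),
                list(energy = -3.0, dipole = c(0, 0, 0), charges = c(0, 0),
                     n_heavy = 1))
  targs <- list(list(energy = -5.001, dipole = c(0.12, 0, -0.01),
                     charges = c(0.25, -0.21)),
                list(energy = -3.0, dipole = c(0, 0, 0), charges = c(0, 0)))
  cfg <- loss_config()
  l <- compute_loss(preds, targs, cfg)
  # hand evaluation of each component
  e_manual <- ((6270 * (-0.001) / 2)^2 + 0) / 2
  d_manual <- (100^2 * ((-0.02)^2 + 0.01^2)) / 6
  q_manual <- ((-0.05)^2 + 0.01^2) / 4
  expect_equal(l$energy, e_manual, tolerance = 1e-12)
  expect_equal(l$dipole, d_manual, tolerance = 1e-12)
  expect_equal(l$charge, q_manual, tolerance = 1e-12)
  expect_equal(l$total, e_manual + d_manual + q_manual, tolerance = 1e-12)
  # perfect predictions give zero
  expect_equal(compute_loss(preds, lapply(preds, function(p)
    p[c("energy", "dipole", "charges")]), cfg)$total, 0)
  # doubling a weight quadruples that component
  cfg2 <- loss_config(w_dipole = 200)
  expect_equal(compute_loss(preds, targs, cfg2)$dipole, 4 * d_manual,
               tolerance = 1e-12)
})

test_that("batches have frozen membership and reshuffled order", {
  bt <- make_batches(35, 10, seed = 4)
  sizes <- vapply(bt$batches, length, integer(1))
  expect_equal(sort(sizes, decreasing = TRUE), c(10, 10, 10, 5))
  expect_identical(make_batches(35, 10, seed = 4)$batches, bt$batches)
  # union over batches is the full index set, no duplicates, many seeds
  for (seed in 1:100) {
    b <- make_batches(53, 10, seed = seed)
    expect_identical(sort(unlist(b$batches)), 1:53)
  }
  # order reshuffles per epoch but membership stays fixed
  expect_false(identical(bt$order(1), bt$order(2)))
  expect_identical(bt$order(3), bt$order(3))
})

test_that("kernel loss with frozen charges matches the reference computation", {
  ps <- fx_toy_ho()
  ds <- fx_ho_data()[1:6]
  layout <- params_layout(ps)
  x <- params_pack(ps, layout)
  cache <- precompute_batch(ds, ps, layout, method = "toy-truth")
  rf <- tbtrain:::.scf_refresh(cache, x, scf_options())
  wts <- tbtrain:::.batch_weights(cache, 1:6, loss_config())
  erep <- vapply(seq_along(ds), function(i)
    repulsive_energy(ds[[i]], ps), numeric(1))
  res <- cpp_batch_loss_grad(cache, rf$dq, erep, rep(FALSE, 6), x, wts, FALSE)
  # reference path: full SCF predictions via scf_compute
  preds <- lapply(ds, function(g) {
    r <- scf_compute(g, ps)
    list(energy = r$electronic_energy + r$repulsive_energy,
         dipole = r$dipole, charges = r$charges,
         n_heavy = sum(g$z != 1L))
  })
  targs <- lapply(ds, function(g) g$targets[["toy-truth"]])
  ref <- compute_loss(preds, targs, loss_config())
  expect_equal(res$loss_energy, ref$energy, tolerance = 1e-7)
  expect_equal(res$loss_dipole, ref$dipole, tolerance = 1e-7)
  expect_equal(res$loss_charge, ref$charge, tolerance = 1e-7)
})

test_that("training gradient matches central differences on a two-molecule batch", {
  ps <- fx_toy_ho()
  seed_ps <- fx_seed_ho()
  ds <- fx_ho_data()[c(14, 30)]   # one H2O, one H2O2
  layout <- params_layout(seed_ps)
  x <- params_pack(seed_ps, layout)
  cache <- precompute_batch(ds, seed_ps, layout, method = "toy-truth")
  rf <- tbtrain:::.scf_refresh(cache, x, scf_options())
  te <- vapply(cache, function(m) m$t_energy, numeric(1))
  fit <- fit_repulsive_and_reference(ds, rf$elec, te, seed_ps)
  idx <- c(layout$channels$offset[c(2, 4, 9, 11)] + 25L,
           layout$channels$offset[c(3, 10)] + 40L,
           unname(layout$onsite), unname(layout$hubbard))
  gc <- gradient_check(cache, seed_ps, layout, x, frozen_dq = rf$dq,
                       frozen_erep = fit$fitted,
                       pcfg = penalty_config(convex_weight = 0,
                                             smoothing_weight = 0),
                       indices = idx, h = 1e-6)
  expect_gt(nrow(gc), 10)
  # relative per gradient with a floor at a small fraction of the dominant
  # gradient (tiny components are limited by FD rounding of the objective)
  floor_ <- 1e-3 * max(abs(gc$analytic))
  rel <- abs(gc$analytic - gc$numeric) /
    pmax(abs(gc$numeric), abs(gc$analytic), floor_)
  expect_lt(max(rel), 1e-5)
})

test_that("zero learning rate leaves every parameter unchanged", {
  ps <- fx_toy_ho()
  ds <- fx_ho_data()
  spl <- list(train = ds[1:20], validation = ds[21:26])
  seed_ps <- fx_seed_ho()
  fit <- train(spl, seed_ps,
               config = train_config(epochs = 3, learning_rate = 0, seed = 2))
  layout <- fit$layout
  expect_equal(fit$final_x, params_pack(seed_ps, layout), tolerance = 1e-14)
})

test_that("training runs are bitwise reproducible for a fixed seed", {
  ps <- fx_toy_ho()
  ds <- fx_ho_data()
  spl <- list(train = ds[1:24], validation = ds[25:30])
  cfg <- train_config(epochs = 6, seed = 9)
  f1 <- train(spl, fx_seed_ho(), config = cfg)
  f2 <- train(spl, fx_seed_ho(), config = cfg)
  expect_identical(serialize(f1$history, NULL), serialize(f2$history, NULL))
  expect_identical(f1$final_x, f2$final_x)
})

test_that("loop inversion: refresh-epoch loss equals a from-scratch SCF loss", {
  ps <- fx_toy_ho()
  ds <- fx_ho_data()[1:10]
  seed_ps <- fx_seed_ho()
  layout <- params_layout(seed_ps)
  x <- params_pack(seed_ps, layout)
  cache <- precompute_batch(ds, seed_ps, layout, method = "toy-truth")
  # refresh: converged charges frozen at the current parameters
  rf <- tbtrain:::.scf_refresh(cache, x, scf_options())
  te <- vapply(cache, function(m) m$t_energy, numeric(1))
  fit <- fit_repulsive_and_reference(ds, rf$elec, te, seed_ps)
  wts <- tbtrain:::.batch_weights(cache, 1:10, loss_config())
  frozen <- cpp_batch_loss_grad(cache, rf$dq, fit$fitted, rep(FALSE, 10),
                                x, wts, FALSE)
  # from-scratch: full SCF per configuration at the same parameters
  ps_now <- params_unpack(fit$ps, layout, x)
  preds <- lapply(ds, function(g) {
    r <- scf_compute(g, ps_now)
    list(energy = r$total_energy, dipole = r$dipole, charges = r$charges,
         n_heavy = sum(g$z != 1L))
  })
  targs <- lapply(ds, function(g) g$targets[["toy-truth"]])
  direct <- compute_loss(preds, targs, loss_config())
  expect_lt(abs(frozen$loss - direct$total) / max(direct$total, 1e-8), 1e-8)
})

test_that("training reduces the loss and keeps boundary conditions intact", {
  ps <- fx_toy_ho()
  ds <- fx_ho_data()
  spl <- list(train = ds[1:26], validation = ds[27:32])
  fit <- train(spl, fx_seed_ho(), config = train_config(epochs = 25, seed = 5))
  h <- fit$history
  expect_lt(h$train_total[25], h$train_total[1])
  for (k in names(fit$params$electronic)) {
    sp <- fit$params$electronic[[k]]
    expect_identical(spline_eval(sp, sp$r_cut), 0)
    expect_identical(spline_eval(sp, sp$r_cut, 1L), 0)
  }
  # penalties-off training reaches an equal or lower data loss
  fit0 <- train(spl, fx_seed_ho(), config = train_config(epochs = 25, seed = 5),
                pcfg = penalty_config(convex_weight = 0, smoothing_weight = 0))
  data_loss <- function(f) {
    hh <- f$history[25, ]
    hh$train_energy + hh$train_dipole + hh$train_charge
  }
  expect_lte(data_loss(fit0), data_loss(fit) * (1 + 1e-6))
})
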