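test_that("templates are valid closed-shell molecules inside the model domain", {
  tpls <- geometry_templates()
  expect_gte(length(tpls), 12L)
  for (nm in names(tpls)) {
    g <- tpls[[nm]]
    expect_equal(n_electrons(g) %% 2, 0)
    if (length(g$z) > 1) {
      D <- as.matrix(stats::dist(g$xyz))
      diag(D) <- Inf
      expect_gte(min(D), 0.6)
    }
  }
  expect_error(geometry_templates("nosuch"), "unknown template")
})

test_that("zero distortion reproduces the templates; sampling is deterministic", {
  ds <- sample_geometries(c("H2O", "CH4"), n_per_template = 3,
                          distortion_scale = 0, seed = 12)
  tpl <- geometry_templates(c("H2O", "CH4"))
  expect_equal(ds[[1]]$xyz, tpl$H2O$xyz, tolerance = 1e-14)
  expect_equal(ds[[4]]$xyz, tpl$CH4$xyz, tolerance = 1e-14)
  d1 <- sample_geometries(n_per_template = 4, seed = 31)
  d2 <- sample_geometries(n_per_template = 4, seed = 31)
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(d1, f1); write_dataset(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every sampled distance respects the hard floor over many draws", {
  # ~1e4 geometries across the template library
  ds <- sample_geometries(n_per_template = 600, distortion_scale = 0.06,
                          seed = 13)
  expect_gte(length(ds), 1e4)
  min_d <- min(vapply(ds, function(g) {
    D <- as.matrix(stats::dist(g$xyz)); diag(D) <- Inf; min(D)
  }, numeric(1)))
  expect_gte(min_d, 0.6)
})

test_that("distance distributions show bonded bands below a long-range tail", {
  ds <- sample_geometries(n_per_template = 40, distortion_scale = 0.05,
                          seed = 14)
  h <- distance_histograms(ds)
  ch <- h[["H-C"]]
  expect_false(ch$absent)
  # the repulsive cutoff separates the bonded peak from the rest
  expect_gt(ch$suggested_repulsive_range[2], 1.2)
  expect_lt(ch$suggested_repulsive_range[2], 2.2)
})

test_that("excessive rejection triggers an explicit error", {
  # a hard floor above the bonded distance rejects every draw
  expect_error(sample_geometries("H2", n_per_template = 10,
                                 distortion_scale = 0.05, seed = 15,
                                 hard_floor = 1.5),
               "rejection rate")
})

test_that("energy noise of 1 kcal/mol yields the folded-normal MAE", {
  ps <- fx_toy_chno()
  n_cfg <- 2000L
  ds <- sample_geometries(n_per_template = ceiling(n_cfg / 17),
                          distortion_scale = 0.05, seed = 16)
  ds <- ds[seq_len(n_cfg)]
  sd_ha <- 1 / KCAL_PER_HA
  ds <- make_targets(ds, ps, noise_sd = sd_ha, seed = 17)
  ev <- evaluate(ps, ds, "toy-truth", outlier_threshold = NULL)
  mae <- ev$metrics$value[1]
  # E|N(0, sigma)| = sigma sqrt(2/pi); SE of the MAE ~ sigma sqrt((1-2/pi)/n)
  expected <- sqrt(2 / pi)
  se <- sqrt(1 - 2 / pi) / sqrt(length(ds))
  expect_lt(abs(mae - expected), 3 * se)
})
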