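test_that("XYZ parsing handles single frames, empty files and bad records", {
  tf <- tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0 0 0", "H 0.7572 0 0.5865",
               "H -0.7572 0 0.5865"), tf)
  ds <- read_dataset(tf)
  expect_length(ds, 1L)
  expect_equal(ds[[1]]$formula, "H2O")
  expect_equal(nrow(ds[[1]]$xyz), 3L)

  empty <- tempfile(fileext = ".xyz")
  file.create(empty)
  expect_length(read_dataset(empty), 0L)

  bad <- tempfile(fileext = ".xyz")
  writeLines(c("2", "", "H 0 0 0"), bad)   # truncated record
  expect_error(read_dataset(bad), "truncated")

  bad2 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "", "Xx 0 0 0"), bad2)
  expect_error(read_dataset(bad2), "unsupported element")
})

test_that("write/read round trip preserves coordinates and targets", {
  ds <- sample_geometries(c("H2O", "NH3"), n_per_template = 3,
                          distortion_scale = 0.03, seed = 4)
  ds <- make_targets(ds, fx_toy_chno(), seed = 5)
  tf <- tempfile(fileext = ".xyz")
  write_dataset(ds, tf)
  ds2 <- read_dataset(tf)
  expect_length(ds2, length(ds))
  for (i in seq_along(ds)) {
    expect_lt(max(abs(ds2[[i]]$xyz - ds[[i]]$xyz)), 1e-6)
    expect_equal(ds2[[i]]$formula, ds[[i]]$formula)
    t1 <- ds[[i]]$targets[["toy-truth"]]
    t2 <- ds2[[i]]$targets[["toy-truth"]]
    expect_equal(t2$energy, t1$energy, tolerance = 1e-12)
    expect_equal(t2$charges, t1$charges, tolerance = 1e-12)
  }
})

test_that("filter_complete retains exactly complete, small-enough records", {
  ds <- fx_ho_data()
  # remove dipoles from two configurations
  broken <- unclass(ds)
  broken[[2]]$targets[["toy-truth"]]$dipole <- NULL
  broken[[5]]$targets[["toy-truth"]]$dipole <- NULL
  broken <- dataset(broken)
  kept <- filter_complete(broken[1:5], required_fields = c("energy", "dipole"))
  expect_length(kept, 3L)
  # idempotent
  expect_identical(
    dataset_formulas(filter_complete(filter_complete(broken))),
    dataset_formulas(filter_complete(broken)))
  # heavy-atom bound
  expect_length(filter_complete(ds, max_heavy_atoms = 1L),
                sum(dataset_formulas(ds) %in% c("H2", "H2O")))
  expect_length(filter_complete(dataset(), max_heavy_atoms = 3L), 0L)
})

test_that("formula-disjoint splits hold for many seeds and honor counts", {
  ds <- fx_ho_data()  # 3 formulas x 12
  for (seed in 1:100) {
    spl <- split_by_formula(ds, list(train = 12, validation = 4, test = 10),
                            seed = seed)
    expect_length(spl$train, 12L)
    expect_length(spl$validation, 4L)
    expect_length(spl$test, 10L)
    expect_length(intersect(dataset_formulas(spl$train),
                            dataset_formulas(spl$test)), 0L)
  }
})

test_that("single-formula dataset lands in exactly one split", {
  ds <- sample_geometries("H2O", n_per_template = 8, seed = 3)
  spl <- split_by_formula(ds, list(train = 0, validation = 0, test = 5), seed = 1)
  expect_length(spl$test, 5L)
  expect_length(spl$train, 0L)
  expect_error(split_by_formula(ds, list(train = 3, validation = 0, test = 3),
                                seed = 1),
               "infeasible")
})

test_that("far-transfer heavy-atom rule bounds both sides", {
  ds <- sample_geometries(c("H2O", "CH4", "C2H6", "CH3OH", "N2H4"),
                          n_per_template = 6, seed = 9)
  spl <- split_by_formula(ds, list(train = 10, validation = 2, test = 6),
                          seed = 2,
                          heavy_atom_rule = list(train_max = 1, test_min = 2))
  expect_true(all(vapply(spl$train, function(g) sum(g$z != 1L), numeric(1)) <= 1))
  expect_true(all(vapply(spl$test, function(g) sum(g$z != 1L), numeric(1)) >= 2))
  expect_length(intersect(dataset_formulas(spl$train),
                          dataset_formulas(spl$test)), 0L)
})

test_that("distance histograms: single pair, counts, fixed electronic bound", {
  g <- geometry(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  h <- distance_histograms(dataset(list(g)))
  hh <- h[["H-H"]]
  expect_false(hh$absent)
  expect_equal(hh$min_distance, 0.74)
  expect_equal(sum(hh$histogram$counts), 1L)
  expect_equal(hh$suggested_electronic_range, c(0.72, 4.5))

  ds <- fx_ho_data()
  h2 <- distance_histograms(ds)
  for (nm in names(h2)) {
    p <- h2[[nm]]
    if (isTRUE(p$absent)) next
    expect_equal(p$suggested_electronic_range[2], 4.5)
    expect_equal(p$suggested_electronic_range[1], p$min_distance - 0.02)
    # counts sum to number of pairs considered
    expect_gt(sum(p$histogram$counts), 0)
  }
  # absent pair flagged
  h3 <- distance_histograms(ds, element_pairs = list(c(6, 6)))
  expect_true(h3[["C-C"]]$absent)
})

test_that("repulsive cutoff falls between the modes of a bimodal distribution", {
  # two atoms per geometry; distances drawn from a mixture of two normals
  set.seed(31)
  d <- c(rnorm(400, 1.0, 0.05), rnorm(400, 1.8, 0.08))
  ds <- dataset(lapply(d, function(r)
    geometry(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, r)))))
  h <- distance_histograms(ds)[["H-H"]]
  cutoff <- h$suggested_repulsive_range[2]
  # analytic minimum of the generating mixture density lies between the modes
  dens <- function(x) 0.5 * dnorm(x, 1.0, 0.05) + 0.5 * dnorm(x, 1.8, 0.08)
  xs <- seq(1.1, 1.7, by = 1e-3)
  x_min <- xs[which.min(dens(xs))]
  expect_gt(cutoff, 1.15)
  expect_lt(cutoff, 1.75)
  expect_lt(abs(cutoff - x_min), 0.25)
})
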