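test_that("SKF write/read round trip preserves tables and constants", {
  ps <- fx_toy_ho()
  dir <- tempfile("skf")
  skf_write(ps, dir)
  skf <- skf_read(dir, c("H", "O"))
  # tabulated channel values on the SKF grid match the splines to 1e-10
  pr <- skf$pairs[["1-8"]]
  r_ang <- pr$r_bohr * ANG_PER_BOHR
  inside <- r_ang > 0.8 & r_ang < 4.4
  expect_lt(max(abs(pr$table[inside, 20] -
                    tbtrain:::.skf_eval_channel(ps, "S", 1, 8, "ss_sigma",
                                                r_ang[inside]))), 1e-10)
  expect_lt(max(abs(pr$table[inside, 10] -
                    tbtrain:::.skf_eval_channel(ps, "H1", 1, 8, "ss_sigma",
                                                r_ang[inside]))), 1e-10)
  # beyond-cutoff rows are exactly zero
  beyond <- r_ang >= 4.5
  expect_true(any(beyond))
  expect_identical(max(abs(pr$table[beyond, ])), 0)
  # on-site energies and Hubbards survive the round trip
  expect_equal(onsite_of(skf, 8L, "p"), onsite_of(ps, 8L, "p"),
               tolerance = 1e-12)
  expect_equal(hubbard_of(skf, 1L, "s"), hubbard_of(ps, 1L, "s"),
               tolerance = 1e-12)
})

test_that("matrices assembled from SKF tables agree with the splines", {
  ps <- fx_toy_ho()
  dir <- tempfile("skf")
  skf_write(ps, dir)
  skf <- skf_read(dir, c("H", "O"))
  for (g in fx_ho_data()[c(3, 16, 29)]) {
    mp1 <- assemble_matrices(g, ps)
    mp2 <- assemble_matrices(g, skf)
    expect_lt(max(abs(mp1$H1 - mp2$H1)), 1e-8)
    expect_lt(max(abs(mp1$S - mp2$S)), 1e-8)
  }
})

test_that("written files satisfy the classic SKF grammar", {
  ps <- fx_toy_ho()
  dir <- tempfile("skf")
  paths <- skf_write(ps, dir)
  expect_setequal(basename(paths),
                  c("H-H.skf", "H-O.skf", "O-H.skf", "O-O.skf"))
  for (p in paths) {
    lines <- readLines(p)
    hdr <- tbtrain:::.skf_tokens(lines[1])
    expect_length(hdr, 2L)
    n_grid <- as.integer(hdr[2])
    homo <- basename(p) %in% c("H-H.skf", "O-O.skf")
    # homonuclear files carry the 10-entry on-site line; heteronuclear not
    expect_equal(length(tbtrain:::.skf_tokens(lines[2])), if (homo) 10L else 20L)
    tab_start <- if (homo) 4L else 3L
    # every table row has the 20 standard columns
    for (i in tab_start:(tab_start + n_grid - 1L))
      expect_length(tbtrain:::.skf_tokens(lines[i]), 20L)
    # spline block: header, exponential head, segments (last with 8 coefs)
    spl <- which(trimws(lines) == "Spline")
    expect_length(spl, 1L)
    nc <- tbtrain:::.skf_tokens(lines[spl + 1L])
    n_int <- as.integer(nc[1])
    expect_length(tbtrain:::.skf_tokens(lines[spl + 2L]), 3L)
    segs <- lapply((spl + 3L):(spl + 2L + n_int),
                   function(i) tbtrain:::.skf_tokens(lines[i]))
    expect_true(all(lengths(segs[-n_int]) == 6L))
    expect_length(segs[[n_int]], 8L)
    starts <- vapply(segs, `[`, numeric(1), 1L)
    expect_true(all(diff(starts) > 0))
    expect_equal(segs[[n_int]][2], nc[2], tolerance = 1e-10)
  }
})

test_that("the repulsive spline block reproduces the spline", {
  ps <- fx_toy_ho()
  dir <- tempfile("skf")
  skf_write(ps, dir)
  skf <- skf_read(dir, c("H", "O"))
  for (k in names(ps$repulsive)) {
    sp <- ps$repulsive[[k]]
    r <- seq(0.3, sp$r_cut + 0.2, by = 0.01)
    got <- skf_repulsive_eval(skf, sp$pair[1], sp$pair[2], r)
    expect_lt(max(abs(got - spline_eval(sp, r))), 1e-10)
  }
})

test_that("format errors are explicit", {
  ps <- fx_toy_ho()
  dir <- tempfile("skf")
  skf_write(ps, dir)
  expect_error(skf_read(dir, c("H", "C")), "missing SKF file")
  # doctor one file with an inconsistent grid spacing
  p <- file.path(dir, "H-O.skf")
  lines <- readLines(p)
  lines[1] <- "0.035000  400"
  writeLines(lines, p)
  expect_error(skf_read(dir, c("H", "O")), "grid spacing|truncated")
  # truncated table
  skf_write(ps, dir)
  lines <- readLines(p)
  writeLines(lines[1:10], p)
  expect_error(skf_read(dir, c("H", "O")), "truncated")
})
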