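#' Molecular geometries and datasets
#'
#' A geometry is one molecular configuration: atomic numbers, Cartesian
#' coordinates in Angstrom, and optional per-method targets (total energy in
#' Hartree, Cartesian dipole in e*Angstrom, per-atom charges in e). A dataset
#' is an ordered list of geometries. Training, splitting and evaluation all
#' operate on these objects.
#'
#' @param z integer vector of atomic numbers
#' @param xyz numeric matrix (n_atoms x 3) of coordinates in Angstrom
#' @param targets named list: method label -> list(energy=, dipole=, charges=)
#' @return object of class \code{tb_geometry}
#' @export
geometry <- function(z, xyz, targets = list()) {
  z <- as.integer(z)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (nrow(xyz) != length(z)) stop("coordinate rows must match atom count")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!all(z %in% supported_z())) {
    stop("unsupported element(s): ",
         paste(unique(z[!z %in% supported_z()]), collapse = ", "))
  }
  for (m in names(targets)) {
    ch <- targets[[m]]$charges
    if (!is.null(ch) && length(ch) != length(z))
      stop("charges length must equal atom count for method ", m)
  }
  structure(list(z = z, xyz = xyz, targets = targets,
                 formula = empirical_formula(z)),
            class = "tb_geometry")
}

#' @export
print.tb_geometry <- function(x, ...) {
  cat(sprintf("<tb_geometry %s, %d atoms, targets: %s>\n", x$formula,
              length(x$z),
              if (length(x$targets)) paste(names(x$targets), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Construct a dataset from a list of geometries
#' @param geoms list of \code{tb_geometry}
#' @return object of class \code{tb_dataset}
#' @export
dataset <- function(geoms = list()) {
  structure(geoms, class = "tb_dataset")
}

#' @export
print.tb_dataset <- function(x, ...) {
  cat(sprintf("<tb_dataset: %d configurations, %d empirical formulas>\n",
              length(x), length(unique(dataset_formulas(x)))))
  invisible(x)
}

#' @export
`[.tb_dataset` <- function(x, i) {
  out <- unclass(x)[i]
  if (any(vapply(out, is.null, logical(1))))
    stop("dataset index out of bounds")
  dataset(out)
}

#' Empirical formulas of all configurations
#' @param ds a \code{tb_dataset}
#' @return character vector
#' @export
dataset_formulas <- function(ds) {
  vapply(ds, function(g) g$formula, character(1))
}

n_heavy_atoms <- function(g) sum(g$z != 1L)

# ---------------------------------------------------------------------------
# XYZ input/output. Standard multi-frame XYZ; the comment line may carry a
# JSON object with per-method targets, e.g.
#   {"toy-truth":{"energy":-1.17,"dipole":[0,0,0.1],"charges":[0.1,-0.1]}}

#' Read a molecular dataset
#'
#' @param path path to a file
#' @param format currently \code{"xyz"} (standard multi-frame XYZ with JSON
#'   targets in the comment line)
#' @return a \code{tb_dataset}
#' @export
read_dataset <- function(path, format = c("xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  geoms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("XYZ parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("XYZ parse error: record starting at line ", i,
           " truncated (expected ", nat, " atoms)")
    comment <- lines[i + 1L]
    targets <- list()
    cm <- trimws(comment)
    if (startsWith(cm, "{")) {
      targets <- tryCatch(
        jsonlite::fromJSON(cm, simplifyVector = TRUE),
        error = function(e) stop("XYZ parse error at line ", i + 1L,
                                 ": bad JSON targets: ", conditionMessage(e)))
      targets <- lapply(targets, function(t) {
        list(energy = if (!is.null(t$energy)) as.numeric(t$energy),
             dipole = if (!is.null(t$dipole)) as.numeric(t$dipole),
             charges = if (!is.null(t$charges)) as.numeric(t$charges))
      })
    }
    sym <- character(nat)
    xyz <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      tok <- strsplit(trimws(lines[i + 1L + k]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop("XYZ parse error at line ", i + 1L + k, ": expected 'El x y z'")
      sym[k] <- tok[1]
      xyz[k, ] <- as.numeric(tok[2:4])
    }
    if (anyNA(xyz))
      stop("XYZ parse error in record starting at line ", i,
           ": non-numeric coordinate")
    geoms[[length(geoms) + 1L]] <- geometry(element_z(sym), xyz, targets)
    i <- i + 2L + nat
  }
  dataset(geoms)
}

#' Write a dataset to a multi-frame XYZ file
#'
#' Coordinates are serialized with 8 decimals (0.01 micro-Angstrom), targets
#' as a JSON object on the comment line.
#'
#' @param ds a \code{tb_dataset}
#' @param path output path
#' @export
write_dataset <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in ds) {
    writeLines(as.character(length(g$z)), con)
    cm <- if (length(g$targets)) {
      as.character(jsonlite::toJSON(g$targets, auto_unbox = FALSE, digits = NA))
    } else ""
    writeLines(cm, con)
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f",
                       element_symbol(g$z), g$xyz[, 1], g$xyz[, 2], g$xyz[, 3]),
               con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Filter a dataset to complete records of bounded size
#'
#' Retains exactly the configurations with at most \code{max_heavy_atoms}
#' non-hydrogen atoms and, for target method \code{method} (or any method if
#' \code{NULL}), all of the \code{required_fields} present.
#'
#' @param ds a \code{tb_dataset}
#' @param max_heavy_atoms maximum number of heavy atoms (default 8)
#' @param required_fields character vector among
#'   \code{c("energy","dipole","charges")}
#' @param method target method label; \code{NULL} accepts any single method
#'   that carries all required fields
#' @return filtered \code{tb_dataset} (possibly empty)
#' @export
filter_complete <- function(ds, max_heavy_atoms = 8L,
                            required_fields = c("energy", "dipole", "charges"),
                            method = NULL) {
  keep <- vapply(ds, function(g) {
    if (n_heavy_atoms(g) > max_heavy_atoms) return(FALSE)
    if (!length(required_fields)) return(TRUE)
    pool <- if (is.null(method)) g$targets else g$targets[method]
    any(vapply(pool, function(t) {
      !is.null(t) && all(vapply(required_fields,
                                function(f) !is.null(t[[f]]), logical(1)))
    }, logical(1)))
  }, logical(1))
  ds[keep]
}

#' Split a dataset by empirical formula
#'
#' Assigns whole empirical-formula groups to the train/validation/test splits
#' so that the formula sets of train and test are disjoint, then trims each
#' split to the requested configuration count. With \code{heavy_atom_rule},
#' training (and validation) formulas are restricted to at most
#' \code{train_max} heavy atoms and test formulas to at least \code{test_min}
#' (far-transfer protocol).
#'
#' @param ds a \code{tb_dataset}
#' @param counts named list or vector with \code{train}, \code{validation},
#'   \code{test} configuration counts
#' @param seed integer seed controlling the random assignment
#' @param heavy_atom_rule optional list(train_max=, test_min=)
#' @return list with elements \code{train}, \code{validation}, \code{test}
#'   (each a \code{tb_dataset}), class \code{tb_split}
#' @export
split_by_formula <- function(ds, counts, seed = 1L, heavy_atom_rule = NULL) {
  counts <- as.list(counts)
  for (nm in c("train", "validation", "test"))
    if (is.null(counts[[nm]])) counts[[nm]] <- 0L
  formulas <- dataset_formulas(ds)
  heavy <- vapply(ds, n_heavy_atoms, numeric(1))
  groups <- split(seq_along(ds), formulas)
  g_heavy <- vapply(groups, function(ix) max(heavy[ix]), numeric(1))

  if (!is.null(heavy_atom_rule)) {
    g_hmin <- vapply(groups, function(ix) min(heavy[ix]), numeric(1))
    train_pool <- names(groups)[g_heavy <= heavy_atom_rule$train_max]
    test_pool <- names(groups)[g_hmin >= heavy_atom_rule$test_min]
    test_pool <- setdiff(test_pool, train_pool)
  } else {
    train_pool <- test_pool <- names(groups)
  }

  rng <- .seeded_rng(seed)
  take <- function(pool, n_conf, exclude) {
    pool <- setdiff(pool, exclude)
    pool <- pool[rng$sample_perm(length(pool))]
    out_idx <- integer(0); used <- character(0)
    for (f in pool) {
      if (length(out_idx) >= n_conf) break
      out_idx <- c(out_idx, groups[[f]])
      used <- c(used, f)
    }
    if (length(out_idx) < n_conf) {
      stop("infeasible split: requested ", n_conf,
           " configurations but only ", length(out_idx),
           " available in ", length(pool), " eligible formula groups")
    }
    list(idx = out_idx[seq_len(n_conf)], used = used)
  }
  te <- take(test_pool, counts$test, character(0))
  # validation is sampled from the same formula groups as train (only the
  # train and test formula sets must be disjoint)
  trva <- take(train_pool, counts$train + counts$validation, te$used)
  perm <- trva$idx[rng$sample_perm(length(trva$idx))]
  tr_idx <- perm[seq_len(counts$train)]
  va_idx <- perm[counts$train + seq_len(counts$validation)]
  structure(list(train = ds[tr_idx], validation = ds[va_idx],
                 test = ds[te$idx]),
            class = "tb_split")
}

#' @export
print.tb_split <- function(x, ...) {
  cat(sprintf("<tb_split: train %d / validation %d / test %d configurations>\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

# Deterministic RNG helper that does not disturb the global RNG stream.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    sample_perm = function(n) if (n == 0) integer(0) else with_state(function() sample.int(n)),
    runif = function(n) with_state(function() runif(n)),
    rnorm = function(n, sd = 1) with_state(function() rnorm(n, sd = sd)),
    sample_int = function(n, size, replace = FALSE)
      with_state(function() sample.int(n, size, replace = replace))
  )
}

#' Pairwise distance distributions and suggested spline ranges
#'
#' For each unordered element pair present, collects all interatomic
#' distances in the dataset, bins them, and proposes spline ranges: the
#' electronic range runs from slightly below the shortest observed distance
#' (0.02 Angstrom margin) to the fixed 4.5 Angstrom long-range cutoff; the
#' repulsive range is truncated at the nearest-neighbor boundary, detected as
#' the first local minimum (after the first mode) of a kernel-smoothed
#' density with bandwidth 0.05 Angstrom.
#'
#' @param ds a non-empty \code{tb_dataset}
#' @param element_pairs optional list of length-2 atomic-number vectors;
#'   default: all unordered pairs of elements present
#' @param bin_width histogram bin width in Angstrom (default 0.05)
#' @param electronic_upper fixed electronic cutoff (4.5 Angstrom)
#' @param lower_margin margin below the minimum distance (0.02 Angstrom)
#' @return named list per pair: \code{histogram} (counts, breaks),
#'   \code{min_distance}, \code{suggested_electronic_range},
#'   \code{suggested_repulsive_range}, or \code{absent = TRUE}
#' @export
distance_histograms <- function(ds, element_pairs = NULL, bin_width = 0.05,
                                electronic_upper = 4.5, lower_margin = 0.02) {
  if (!length(ds)) stop("dataset is empty")
  zs <- sort(unique(unlist(lapply(ds, function(g) g$z))))
  if (is.null(element_pairs)) {
    element_pairs <- list()
    for (a in seq_along(zs)) for (b in a:length(zs))
      element_pairs[[length(element_pairs) + 1L]] <- c(zs[a], zs[b])
  }
  # gather distances per pair
  key <- function(p) paste(sort(p), collapse = "-")
  bag <- new.env()
  for (g in ds) {
    n <- length(g$z)
    if (n < 2L) next
    d <- as.matrix(stats::dist(g$xyz))
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      k <- key(c(g$z[i], g$z[j]))
      bag[[k]] <- c(bag[[k]], d[i, j])
    }
  }
  out <- list()
  for (p in element_pairs) {
    k <- key(p)
    dists <- bag[[k]]
    nm <- paste(element_symbol(sort(p)), collapse = "-")
    if (is.null(dists)) {
      out[[nm]] <- list(pair = sort(p), absent = TRUE)
      next
    }
    breaks <- seq(floor(min(dists) / bin_width) * bin_width,
                  ceiling(max(dists) / bin_width) * bin_width + bin_width,
                  by = bin_width)
    counts <- as.integer(table(cut(dists, breaks, include.lowest = TRUE)))
    mind <- min(dists)
    out[[nm]] <- list(
      pair = sort(p), absent = FALSE,
      histogram = list(counts = counts, breaks = breaks),
      min_distance = mind,
      suggested_electronic_range = c(mind - lower_margin, electronic_upper),
      suggested_repulsive_range = c(0, .repulsive_cutoff(dists))
    )
  }
  out
}

# First local minimum of a kernel-smoothed distance density after the first
# mode; falls back to the distance maximum when the density is unimodal.
.repulsive_cutoff <- function(dists, bw = 0.05) {
  if (length(dists) < 2L) return(max(dists) + 3 * bw)
  dens <- stats::density(dists, bw = bw, n = 1024)
  y <- dens$y
  n <- length(y)
  mode1 <- NULL
  for (i in 2:(n - 1)) {
    if (is.null(mode1) && y[i] > y[i - 1] && y[i] >= y[i + 1]) mode1 <- i
    else if (!is.null(mode1) && y[i] < y[i - 1] && y[i] <= y[i + 1]) {
      return(dens$x[i])
    }
  }
  max(dists) + 3 * bw
}
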