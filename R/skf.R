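#' Slater-Koster file (SKF) export and import
#'
#' Trained parameter sets are distributed in the classic (non-extended) SKF
#' format: one text file per ordered element pair with the H and S integral
#' tables resampled on a uniform bohr grid (20 columns in the standard
#' d/p/s channel order), on-site energies, Hubbard parameters and shell
#' occupancies on the homonuclear second line, and the repulsive potential
#' as the cubic-spline block (exponential short-range head, per-interval
#' cubic coefficients, fifth-order final segment).
#'
#' All quantities are in atomic units (bohr, Hartree) inside the files;
#' conversion from the Angstrom-based splines happens on the way out/in.
#' Table rows at or beyond a channel's cutoff are exactly zero. Below the
#' fitted range minus a small guard the tabulated values are clamped
#' (distances there never occur in valid geometries).
#'
#' @name skf
NULL

# classic 20-column channel order (H block, then S block)
.skf_cols <- c("dd_sigma", "dd_pi", "dd_delta", "pd_sigma", "pd_pi",
               "pp_sigma", "pp_pi", "sd_sigma", "sp_sigma", "ss_sigma")

.skf_eval_channel <- function(params, kind, zA, zB, channel, r_ang, guard = 0.05) {
  lo <- min(zA, zB); hi <- max(zA, zB)
  key <- if (channel == "sp_sigma") channel_key(kind, zA, zB, channel)
         else channel_key(kind, lo, hi, channel)
  sp <- params$electronic[[key]]
  if (is.null(sp)) stop("missing channel ", key, " for pair ",
                        element_symbol(zA), "-", element_symbol(zB))
  r_clamped <- pmax(r_ang, sp$r_low - guard)
  spline_eval(sp, r_clamped)
}

#' Write a parameter set as classic SKF files
#'
#' @param params a \code{tb_paramset}
#' @param directory output directory (created if needed)
#' @param grid_dist table grid spacing in bohr (default 0.02)
#' @return invisibly, the written file paths
#' @export
skf_write <- function(params, directory, grid_dist = 0.02) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  zs <- element_z(names(params$shells))
  max_cut <- max(vapply(params$electronic, function(s) s$r_cut, numeric(1)))
  n_grid <- ceiling((max_cut * BOHR_PER_ANG + 0.1) / grid_dist)
  r_bohr <- grid_dist * seq_len(n_grid)
  r_ang <- r_bohr * ANG_PER_BOHR
  fmt <- function(v) paste(sprintf("%.12e", v), collapse = "  ")
  paths <- character(0)
  for (za in zs) for (zb in zs) {
    sa <- element_symbol(za); sb <- element_symbol(zb)
    path <- file.path(directory, paste0(sa, "-", sb, ".skf"))
    lines <- c(sprintf("%.6f  %d", grid_dist, n_grid))
    if (za == zb) {
      on_p <- if (element_has_p(za)) onsite_of(params, za, "p") else 0
      on_s <- onsite_of(params, za, "s")
      u_p <- if (element_has_p(za)) hubbard_of(params, za, "p") else
        hubbard_of(params, za, "s")
      u_s <- hubbard_of(params, za, "s")
      f_p <- if (element_has_p(za)) shell_occupancy(za, "p") else 0
      f_s <- shell_occupancy(za, "s")
      lines <- c(lines, fmt(c(0, on_p, on_s, 0, 0, u_p, u_s, 0, f_p, f_s)))
    }
    lines <- c(lines, fmt(c(element_mass(za), rep(0, 8), 0, rep(0, 10))))
    tab <- matrix(0, n_grid, 20)
    has_pa <- element_has_p(za); has_pb <- element_has_p(zb)
    for (ki in 1:2) {
      kind <- c("H1", "S")[ki]
      off <- (ki - 1L) * 10L
      tab[, off + 10L] <- .skf_eval_channel(params, kind, za, zb, "ss_sigma", r_ang)
      if (has_pb)
        tab[, off + 9L] <- .skf_eval_channel(params, kind, za, zb, "sp_sigma", r_ang)
      if (has_pa && has_pb) {
        tab[, off + 6L] <- .skf_eval_channel(params, kind, za, zb, "pp_sigma", r_ang)
        tab[, off + 7L] <- .skf_eval_channel(params, kind, za, zb, "pp_pi", r_ang)
      }
    }
    lines <- c(lines, apply(tab, 1, fmt))
    # repulsive spline block
    rk <- channel_key("R", min(za, zb), max(za, zb), "rep")
    rsp <- params$repulsive[[rk]]
    if (!is.null(rsp)) lines <- c(lines, .skf_spline_block(rsp))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Repulsive B-spline -> classic cubic-spline block (atomic units).
.skf_spline_block <- function(rsp) {
  knots <- unique(rsp$knots_full) * BOHR_PER_ANG
  n_int <- length(knots) - 1L
  starts <- knots[-length(knots)]
  starts_ang <- starts * ANG_PER_BOHR
  derivs <- sapply(0:2, function(d)
    spline_eval(rsp, starts_ang, d) * ANG_PER_BOHR^d)
  if (n_int == 1L) derivs <- matrix(derivs, nrow = 1L)
  # third derivative of an order-3 spline is piecewise constant; recover it
  # exactly from the (piecewise linear) second derivative at two points of
  # each interval
  mids_ang <- (starts + diff(knots) / 2) * ANG_PER_BOHR
  f2_mid <- spline_eval(rsp, mids_ang, 2L) * ANG_PER_BOHR^2
  f3 <- (f2_mid - derivs[, 3]) / (diff(knots) / 2)
  coefs <- sweep(cbind(derivs, f3), 2, factorial(0:3), "/")
  f0 <- coefs[1, 1]
  f1 <- coefs[1, 2]
  if (f0 > 1e-12 && f1 < 0) {
    a1 <- -f1 / f0
    a2 <- log(f0) + a1 * starts[1]
    a3 <- 0
  } else {
    a1 <- a2 <- 0
    a3 <- f0 - 1   # exp(0) + a3 reproduces the value with zero slope
  }
  fmtn <- function(v) paste(sprintf("%.12e", v), collapse = "  ")
  lines <- c("Spline",
             sprintf("%d  %.12f", n_int, knots[length(knots)]),
             fmtn(c(a1, a2, a3)))
  for (k in seq_len(n_int)) {
    seg <- c(knots[k], knots[k + 1L], coefs[k, ])
    if (k == n_int) seg <- c(seg, 0, 0)   # fifth-order final segment
    lines <- c(lines, fmtn(seg))
  }
  lines
}

# ---------------------------------------------------------------------------

.skf_tokens <- function(line) {
  as.numeric(strsplit(trimws(line), "[\\s,]+", perl = TRUE)[[1]])
}

#' Read classic SKF files into a tabulated parameter container
#'
#' The returned object supports matrix assembly
#' (\code{\link{assemble_matrices}}) through natural-cubic interpolation of
#' the tables, and evaluation of the repulsive spline block.
#'
#' @param directory directory containing \code{X-Y.skf} files
#' @param elements element symbols to read (all ordered pairs required)
#' @return object of class \code{tb_skf}
#' @export
skf_read <- function(directory, elements) {
  zs <- element_z(elements)
  pairs <- list()
  onsite <- list()
  hubbard <- list()
  grid_ref <- NULL
  for (za in zs) for (zb in zs) {
    sa <- element_symbol(za); sb <- element_symbol(zb)
    path <- file.path(directory, paste0(sa, "-", sb, ".skf"))
    if (!file.exists(path))
      stop("missing SKF file for pair ", sa, "-", sb, ": ", path)
    lines <- readLines(path)
    hdr <- .skf_tokens(lines[1])
    grid_dist <- hdr[1]; n_grid <- as.integer(hdr[2])
    if (is.null(grid_ref)) grid_ref <- grid_dist
    else if (abs(grid_dist - grid_ref) > 1e-12)
      stop("inconsistent grid spacing across SKF files: ", grid_dist,
           " vs ", grid_ref)
    i <- 2L
    if (za == zb) {
      ons <- .skf_tokens(lines[i]); i <- i + 1L
      onsite[[sa]] <- list(p = ons[2], s = ons[3])
      hubbard[[sa]] <- list(p = ons[6], s = ons[7])
    } else {
      if (length(.skf_tokens(lines[i])) == 10L)
        stop("heteronuclear file ", path, " must not carry an on-site line")
    }
    i <- i + 1L  # mass/polynomial line
    if (length(lines) < i + n_grid - 1L)
      stop("truncated H/S table in ", path, ": expected ", n_grid, " rows")
    tab <- t(vapply(lines[i:(i + n_grid - 1L)], .skf_tokens, numeric(20)))
    rownames(tab) <- NULL
    if (anyNA(tab)) stop("malformed table row in ", path)
    i <- i + n_grid
    rep_block <- NULL
    spl_at <- which(trimws(lines) == "Spline")
    if (length(spl_at)) {
      j <- spl_at[1] + 1L
      nc <- .skf_tokens(lines[j])
      n_int <- as.integer(nc[1]); cutoff <- nc[2]
      expo <- .skf_tokens(lines[j + 1L])
      segs <- lapply((j + 2L):(j + 1L + n_int), function(kk) .skf_tokens(lines[kk]))
      rep_block <- list(n_int = n_int, cutoff = cutoff, expo = expo,
                        segments = segs)
    }
    pairs[[paste0(za, "-", zb)]] <- list(
      grid_dist = grid_dist, n_grid = n_grid,
      r_bohr = grid_dist * seq_len(n_grid), table = tab, rep = rep_block)
  }
  structure(list(elements = zs, pairs = pairs, onsite = onsite,
                 hubbard = hubbard, grid_dist = grid_ref,
                 .interp = new.env(parent = emptyenv())),
            class = "tb_skf")
}

#' @export
print.tb_skf <- function(x, ...) {
  cat(sprintf("<tb_skf: elements %s, %d pair tables, grid %.3f bohr>\n",
              paste(element_symbol(x$elements), collapse = ","),
              length(x$pairs), x$grid_dist))
  invisible(x)
}

.skf_col_index <- function(kind, channel) {
  base <- if (kind == "H1") 0L else 10L
  base + match(channel, .skf_cols)
}

#' @export
channel_value.tb_skf <- function(params, kind, zA, zB, channel, r, ...) {
  lo <- min(zA, zB); hi <- max(zA, zB)
  pk <- if (channel == "sp_sigma") paste0(zA, "-", zB) else paste0(lo, "-", hi)
  pr <- params$pairs[[pk]]
  if (is.null(pr)) stop("missing SKF pair table ", pk)
  ckey <- paste(pk, kind, channel, sep = ":")
  fn <- params$.interp[[ckey]]
  if (is.null(fn)) {
    col <- pr$table[, .skf_col_index(kind, channel)]
    fn <- stats::splinefun(pr$r_bohr, col, method = "natural")
    assign(ckey, fn, envir = params$.interp)
  }
  rb <- r * BOHR_PER_ANG
  out <- fn(pmin(pmax(rb, pr$r_bohr[1]), pr$r_bohr[pr$n_grid]))
  out[rb >= pr$r_bohr[pr$n_grid]] <- 0
  out
}

#' @export
onsite_of.tb_skf <- function(params, z, shell, ...) {
  params$onsite[[element_symbol(z)]][[shell]]
}
#' @export
hubbard_of.tb_skf <- function(params, z, shell, ...) {
  params$hubbard[[element_symbol(z)]][[shell]]
}
#' @export
.pair_r_low.tb_skf <- function(params, za, zb) NA_real_

#' Evaluate the repulsive spline block of an SKF pair
#'
#' @param skf a \code{tb_skf}
#' @param zA,zB atomic numbers
#' @param r_ang distances in Angstrom
#' @return repulsive energies in Hartree
#' @export
skf_repulsive_eval <- function(skf, zA, zB, r_ang) {
  pk <- paste0(min(zA, zB), "-", max(zA, zB))
  pr <- skf$pairs[[pk]]
  if (is.null(pr) || is.null(pr$rep))
    stop("no repulsive block for pair ", pk)
  rb <- r_ang * BOHR_PER_ANG
  blk <- pr$rep
  starts <- vapply(blk$segments, `[`, numeric(1), 1L)
  vapply(rb, function(x) {
    if (x >= blk$cutoff) return(0)
    if (x < starts[1]) {
      e <- blk$expo
      return(exp(-e[1] * x + e[2]) + e[3])
    }
    k <- findInterval(x, starts)
    seg <- blk$segments[[k]]
    cf <- seg[-(1:2)]
    dx <- x - seg[1]
    sum(cf * dx^(seq_along(cf) - 1L))
  }, numeric(1))
}
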