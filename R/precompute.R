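#' Precomputation of parameter-independent batch quantities
#'
#' Training evaluates the model thousands of times on a fixed set of
#' geometries. Everything that does not depend on trainable parameters is
#' computed once per molecule and cached: distances, direction cosines
#' (folded into sparse coefficient maps), orbital and shell bookkeeping, and
#' targets. Each \code{H1}/\code{S} matrix entry is an exactly linear
#' function of the flat parameter vector, represented as triplets
#' (entry, parameter, coefficient); rebuilding the matrices for any
#' coefficient values is a sparse matrix-vector product, so the cache stays
#' valid for every parameter update.
#'
#' @name precompute
NULL

# Cache for a single geometry. All indices 0-based (consumed by C++).
.precompute_mol <- function(g, ps, layout, method = NULL) {
  omap <- orbital_map(g)
  smap <- shell_map(g)
  norb <- nrow(omap)
  nel <- n_electrons(g)
  if (nel %% 2 != 0)
    stop("odd valence electron count in ", g$formula,
         ": only closed-shell systems are supported")
  natom <- length(g$z)

  eid <- matrix(0L, norb, norb)   # H1 entry registry (i <= j)
  h1_i <- integer(0); h1_j <- integer(0)
  h1_te <- list(); h1_tp <- list(); h1_tv <- list()
  s_i <- integer(0); s_j <- integer(0)
  s_te <- list(); s_tp <- list(); s_tv <- list()
  seid <- matrix(0L, norb, norb)

  get_h1_entry <- function(i, j) {
    lo <- min(i, j); hi <- max(i, j)
    if (eid[lo, hi] == 0L) {
      h1_i[length(h1_i) + 1L] <<- lo
      h1_j[length(h1_j) + 1L] <<- hi
      eid[lo, hi] <<- length(h1_i)
    }
    eid[lo, hi]
  }
  get_s_entry <- function(i, j) {
    lo <- min(i, j); hi <- max(i, j)
    if (seid[lo, hi] == 0L) {
      s_i[length(s_i) + 1L] <<- lo
      s_j[length(s_j) + 1L] <<- hi
      seid[lo, hi] <<- length(s_i)
    }
    seid[lo, hi]
  }

  chan_offsets <- stats::setNames(layout$channels$offset, layout$channels$key)

  # on-site energies: diagonal H1 entries, unit coefficient
  for (o in seq_len(norb)) {
    e <- get_h1_entry(o, o)
    lab <- paste0(element_symbol(omap$z[o]), ".", omap$shell[o])
    h1_te[[length(h1_te) + 1L]] <- e
    h1_tp[[length(h1_tp) + 1L]] <- as.integer(layout$onsite[[lab]]) - 1L
    h1_tv[[length(h1_tv) + 1L]] <- 1
  }

  add_channel <- function(kind, key, pairs_i, pairs_j, coeffs, r) {
    # pairs_i/j: global orbital indices; coeffs: geometric factors
    sp <- ps$electronic[[key]]
    if (is.null(sp)) stop("missing channel ", key)
    row <- drop(spline_free_design(sp, r))
    nz <- which(row != 0)
    if (!length(nz)) return(invisible())
    off <- chan_offsets[[key]]
    for (k in seq_along(pairs_i)) {
      if (coeffs[k] == 0) next
      if (kind == "H1") {
        e <- get_h1_entry(pairs_i[k], pairs_j[k])
        h1_te[[length(h1_te) + 1L]] <<- rep(e, length(nz))
        h1_tp[[length(h1_tp) + 1L]] <<- as.integer(off + nz - 1L)
        h1_tv[[length(h1_tv) + 1L]] <<- coeffs[k] * row[nz]
      } else {
        e <- get_s_entry(pairs_i[k], pairs_j[k])
        s_te[[length(s_te) + 1L]] <<- rep(e, length(nz))
        s_tp[[length(s_tp) + 1L]] <<- as.integer(off + nz - 1L)
        s_tv[[length(s_tv) + 1L]] <<- coeffs[k] * row[nz]
      }
    }
  }

  if (natom > 1L) {
    for (a in 1:(natom - 1L)) for (b in (a + 1L):natom) {
      dvec <- g$xyz[b, ] - g$xyz[a, ]
      r <- sqrt(sum(dvec^2))
      d <- dvec / r
      za <- g$z[a]; zb <- g$z[b]
      lo <- min(za, zb); hi <- max(za, zb)
      sa <- which(omap$atom == a & omap$m == "s")
      sb <- which(omap$atom == b & omap$m == "s")
      pa <- which(omap$atom == a & omap$shell == "p")  # x, y, z order
      pb <- which(omap$atom == b & omap$shell == "p")
      for (kind in c("H1", "S")) {
        add_channel(kind, channel_key(kind, lo, hi, "ss_sigma"), sa, sb, 1, r)
        if (length(pb))
          add_channel(kind, channel_key(kind, za, zb, "sp_sigma"),
                      rep(sa, 3), pb, d, r)
        if (length(pa))
          add_channel(kind, channel_key(kind, zb, za, "sp_sigma"),
                      pa, rep(sb, 3), -d, r)
        if (length(pa) && length(pb)) {
          dd <- outer(d, d)
          ii <- rep(pa, 3); jj <- rep(pb, each = 3)
          add_channel(kind, channel_key(kind, lo, hi, "pp_sigma"),
                      ii, jj, as.vector(dd), r)
          add_channel(kind, channel_key(kind, lo, hi, "pp_pi"),
                      ii, jj, as.vector(diag(3) - dd), r)
        }
      }
    }
  }

  tg <- if (is.null(method)) NULL else g$targets[[method]]
  Dat <- as.matrix(stats::dist(g$xyz)) * BOHR_PER_ANG
  hub_idx <- vapply(seq_len(nrow(smap)), function(i) {
    as.integer(layout$hubbard[[paste0(element_symbol(smap$z[i]), ".",
                                      smap$shell[i])]]) - 1L
  }, integer(1))

  list(
    norb = norb,
    nocc = as.integer(nel / 2),
    nheavy = as.numeric(sum(g$z != 1L)),
    natom = natom,
    xyz = g$xyz,
    formula = g$formula,
    orb_shell = as.integer(omap$shell_id - 1L),
    shell_atom = as.integer(smap$atom - 1L),
    shell_q0 = as.numeric(smap$occupancy),
    shell_hub = hub_idx,
    Rsh = Dat[smap$atom, smap$atom, drop = FALSE],
    h1_i = as.integer(h1_i - 1L), h1_j = as.integer(h1_j - 1L),
    h1_te = as.integer(unlist(h1_te) - 1L),
    h1_tp = as.integer(unlist(h1_tp)),
    h1_tv = as.numeric(unlist(h1_tv)),
    s_i = as.integer(s_i - 1L), s_j = as.integer(s_j - 1L),
    s_te = as.integer(unlist(s_te) - 1L),
    s_tp = as.integer(unlist(s_tp)),
    s_tv = as.numeric(unlist(s_tv)),
    t_energy = if (!is.null(tg$energy)) as.numeric(tg$energy) else NA_real_,
    t_dipole = if (!is.null(tg$dipole)) as.numeric(tg$dipole) else NULL,
    t_charges = if (!is.null(tg$charges)) as.numeric(tg$charges) else NULL
  )
}

#' Precompute the training cache for a set of geometries
#'
#' @param ds a \code{tb_dataset} (or list of \code{tb_geometry})
#' @param ps a \code{tb_paramset} defining channels and ranges
#' @param layout flat-vector layout from \code{\link{params_layout}}
#' @param method target method label whose targets are attached to the
#'   cache (NULL: no targets, e.g. for prediction-only use)
#' @return list of per-molecule caches (class \code{tb_cache})
#' @export
precompute_batch <- function(ds, ps, layout, method = NULL) {
  if (!length(ds)) stop("empty batch")
  structure(lapply(ds, .precompute_mol, ps = ps, layout = layout,
                   method = method),
            class = "tb_cache")
}

#' @export
print.tb_cache <- function(x, ...) {
  cat(sprintf("<tb_cache: %d molecules, %d parameters referenced>\n",
              length(x), max(vapply(x, function(m)
                max(c(m$h1_tp, m$s_tp, m$shell_hub, -1L)), integer(1))) + 1L))
  invisible(x)
}

#' Rebuild H1/S for one cached molecule at given parameters
#'
#' Cross-check utility: the result is identical (to machine precision) to
#' \code{\link{assemble_matrices}} on the original geometry.
#'
#' @param mol one element of a \code{tb_cache}
#' @param x flat parameter vector
#' @return list with \code{H1}, \code{S}
#' @export
cache_assemble <- function(mol, x) {
  cpp_assemble(mol, x)
}
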