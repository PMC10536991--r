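#' Orbital bookkeeping and Slater-Koster matrix assembly
#'
#' Orbitals are ordered per atom as s, p_x, p_y, p_z (hydrogen: s only).
#' Two-center blocks are built from the distance-dependent channel values by
#' the standard Slater-Koster geometric transformation for s/p orbitals;
#' on-site blocks are diagonal (orthogonal valence orbitals on one center),
#' carrying the trained on-site energies in \code{H1} and 1 in \code{S}.
#'
#' @name hamiltonian
NULL

#' Orbital map of a geometry
#'
#' @param geom a \code{tb_geometry}
#' @return data.frame with one row per orbital: \code{atom}, \code{z},
#'   \code{shell} ("s"/"p"), \code{m} ("s","x","y","z"), \code{shell_id}
#'   (1-based index over (atom, shell) pairs)
#' @export
orbital_map <- function(geom) {
  rows <- list()
  shell_id <- 0L
  for (a in seq_along(geom$z)) {
    z <- geom$z[a]
    shell_id <- shell_id + 1L
    rows[[length(rows) + 1L]] <- data.frame(atom = a, z = z, shell = "s",
                                            m = "s", shell_id = shell_id)
    if (element_has_p(z)) {
      shell_id <- shell_id + 1L
      for (m in c("x", "y", "z"))
        rows[[length(rows) + 1L]] <- data.frame(atom = a, z = z, shell = "p",
                                                m = m, shell_id = shell_id)
    }
  }
  do.call(rbind, rows)
}

# Shell table of a geometry: one row per (atom, shell).
shell_map <- function(geom) {
  rows <- list()
  for (a in seq_along(geom$z)) {
    z <- geom$z[a]
    for (sh in element_shells(z)) {
      rows[[length(rows) + 1L]] <- data.frame(
        atom = a, z = z, shell = sh, occupancy = shell_occupancy(z, sh))
    }
  }
  do.call(rbind, rows)
}

#' Two-center s/p block in the molecular frame
#'
#' Given the bond-frame channel values of an ordered atom pair (A, B) and
#' the unit direction vector from A to B, returns the orbital block in the
#' molecular Cartesian frame. Channel conventions as in \code{\link{sto}}:
#' \code{sp_ab} is s on A with p on B, \code{sp_ba} s on B with p on A, the
#' p-sigma orbitals pointing from A to B.
#'
#' @param channel_values list with entries \code{ss}, \code{sp_ab},
#'   \code{sp_ba}, \code{pp_sigma}, \code{pp_pi} (missing entries are treated
#'   as absent orbitals)
#' @param direction unit 3-vector from A to B
#' @param p_on_a,p_on_b do the atoms carry p shells?
#' @return numeric matrix (rows: orbitals of A; columns: orbitals of B)
#' @export
sk_pair_block <- function(channel_values, direction, p_on_a, p_on_b) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-8)
    stop("direction must be a unit vector")
  d <- direction
  na <- if (p_on_a) 4L else 1L
  nb <- if (p_on_b) 4L else 1L
  blk <- matrix(0, na, nb)
  blk[1, 1] <- channel_values$ss
  if (p_on_b) blk[1, 2:4] <- d * channel_values$sp_ab
  if (p_on_a) blk[2:4, 1] <- -d * channel_values$sp_ba
  if (p_on_a && p_on_b) {
    dd <- outer(d, d)
    blk[2:4, 2:4] <- dd * channel_values$pp_sigma +
      (diag(3) - dd) * channel_values$pp_pi
  }
  blk
}

# Generic channel evaluation: dispatches on the parameter container so the
# same assembly code serves spline parameter sets and tabulated SKF reads.
channel_value <- function(params, ...) UseMethod("channel_value")

#' @export
channel_value.tb_paramset <- function(params, kind, zA, zB, channel, r, ...) {
  k <- channel_key(kind, zA, zB, channel)
  sp <- params$electronic[[k]]
  if (is.null(sp)) stop("missing channel ", k)
  spline_eval(sp, r)
}

onsite_of <- function(params, ...) UseMethod("onsite_of")
hubbard_of <- function(params, ...) UseMethod("hubbard_of")

#' @export
onsite_of.tb_paramset <- function(params, z, shell, ...) {
  params$shells[[element_symbol(z)]][[shell]]$onsite
}
#' @export
hubbard_of.tb_paramset <- function(params, z, shell, ...) {
  params$shells[[element_symbol(z)]][[shell]]$hubbard
}

# Channel values (bond frame) for an ordered atom pair at distance r.
.pair_channel_values <- function(params, za, zb, kind, r) {
  lo <- min(za, zb); hi <- max(za, zb)
  vals <- list(ss = channel_value(params, kind, lo, hi, "ss_sigma", r))
  if (element_has_p(zb)) vals$sp_ab <- channel_value(params, kind, za, zb, "sp_sigma", r)
  if (element_has_p(za)) vals$sp_ba <- channel_value(params, kind, zb, za, "sp_sigma", r)
  if (element_has_p(za) && element_has_p(zb)) {
    vals$pp_sigma <- channel_value(params, kind, lo, hi, "pp_sigma", r)
    vals$pp_pi <- channel_value(params, kind, lo, hi, "pp_pi", r)
  }
  vals
}

#' Assemble molecular H1 and S matrices
#'
#' Builds the one-electron Hamiltonian \code{H1} (Hartree) and overlap
#' \code{S} from the channel splines by the Slater-Koster transformation.
#' Both matrices are exactly symmetric by construction; off-diagonal atom
#' blocks vanish for interatomic distances beyond the channel cutoffs.
#'
#' @param geom a \code{tb_geometry}
#' @param params a \code{tb_paramset} (or tabulated SKF parameters from
#'   \code{\link{skf_read}})
#' @param extrapolation_guard distances may undershoot the spline range by
#'   this margin (Angstrom) before a warning is raised
#' @return list with \code{H1}, \code{S}, \code{orbital_map} (class
#'   \code{tb_matrix_pair})
#' @export
assemble_matrices <- function(geom, params, extrapolation_guard = 0.05) {
  omap <- orbital_map(geom)
  n <- nrow(omap)
  H1 <- matrix(0, n, n)
  S <- diag(1, n)
  for (o in seq_len(n))
    H1[o, o] <- onsite_of(params, omap$z[o], omap$shell[o])
  undershoot <- 0L
  nat <- length(geom$z)
  if (nat > 1L) {
    for (a in 1:(nat - 1L)) for (b in (a + 1L):nat) {
      dvec <- geom$xyz[b, ] - geom$xyz[a, ]
      r <- sqrt(sum(dvec^2))
      za <- geom$z[a]; zb <- geom$z[b]
      rlo <- .pair_r_low(params, za, zb)
      if (is.finite(rlo) && r < rlo) {
        if (r < rlo - extrapolation_guard)
          stop(sprintf("distance %.3f A between atoms %d-%d is below the spline range (r_low %.3f A) by more than the %.2f A guard",
                       r, a, b, rlo, extrapolation_guard))
        undershoot <- undershoot + 1L
      }
      ia <- which(omap$atom == a); ib <- which(omap$atom == b)
      for (kind in c("H1", "S")) {
        vals <- .pair_channel_values(params, za, zb, kind, r)
        blk <- sk_pair_block(vals, dvec / r, element_has_p(za), element_has_p(zb))
        if (kind == "H1") {
          H1[ia, ib] <- blk; H1[ib, ia] <- t(blk)
        } else {
          S[ia, ib] <- blk; S[ib, ia] <- t(blk)
        }
      }
    }
  }
  if (undershoot > 0L)
    warning(undershoot, " pair distance(s) below the spline lower bound; first-piece extrapolation used")
  structure(list(H1 = H1, S = S, orbital_map = omap), class = "tb_matrix_pair")
}

.pair_r_low <- function(params, za, zb) UseMethod(".pair_r_low")
#' @export
.pair_r_low.tb_paramset <- function(params, za, zb) {
  k <- channel_key("S", min(za, zb), max(za, zb), "ss_sigma")
  sp <- params$electronic[[k]]
  if (is.null(sp)) NA_real_ else sp$r_low
}

#' Total number of valence electrons of a geometry
#' @param geom a \code{tb_geometry}
#' @return numeric count
#' @export
n_electrons <- function(geom) sum(valence_electrons(geom$z))
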