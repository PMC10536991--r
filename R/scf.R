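#' Self-consistent-charge solver
#'
#' Solves the self-consistent-charge tight-binding equations: the Coulomb
#' kernel couples Mulliken charge fluctuations back into the Fock operator,
#' which is rebuilt and re-diagonalized until the charge fluctuations reach a
#' fixed point. Closed-shell aufbau filling; the generalized eigenproblem is
#' handled by symmetric (Loewdin) orthogonalization.
#'
#' @name scf
NULL

#' SCF solver options
#'
#' @param tol convergence threshold on the maximum absolute change of any
#'   shell charge fluctuation (e), default 1e-7
#' @param max_iter maximum SCF iterations (default 60); non-convergence is
#'   flagged on the result, not thrown
#' @param mixing linear mixing fraction for charge updates (default 0.3)
#' @param anderson_depth history depth of Anderson acceleration (default 3)
#' @param anderson_start iteration at which Anderson acceleration begins
#'   (default 4, i.e. after three plain mixing steps)
#' @return list of options
#' @export
scf_options <- function(tol = 1e-7, max_iter = 60L, mixing = 0.3,
                        anderson_depth = 3L, anderson_start = 4L) {
  list(tol = tol, max_iter = as.integer(max_iter), mixing = mixing,
       anderson_depth = as.integer(anderson_depth),
       anderson_start = as.integer(anderson_start))
}

#' Shell-resolved Coulomb kernel matrix
#'
#' Builds the gamma matrix for all (atom, shell) pairs of a geometry from
#' the Hubbard parameters: the standard analytic kernel for exponentially
#' decaying s-like charge densities with per-shell decay tau = (16/5) U, so
#' the on-site diagonal equals the shell's Hubbard parameter and the
#' off-diagonal tends to 1/R (atomic units) at long range.
#'
#' @param geom a \code{tb_geometry}
#' @param params a \code{tb_paramset} (source of Hubbard parameters)
#' @return list with \code{gamma} (Hartree, shells x shells) and
#'   \code{shells} (the shell table)
#' @export
gamma_matrix <- function(geom, params) {
  sh <- shell_map(geom)
  ns <- nrow(sh)
  hub <- numeric(ns)
  for (i in seq_len(ns)) hub[i] <- hubbard_of(params, sh$z[i], sh$shell[i])
  if (any(hub <= 0)) stop("Hubbard parameters must be positive")
  D <- as.matrix(stats::dist(geom$xyz)) * BOHR_PER_ANG
  Rsh <- D[sh$atom, sh$atom, drop = FALSE]
  list(gamma = cpp_gamma_matrix(hub, Rsh), shells = sh)
}

#' Mulliken shell populations
#'
#' @param density_matrix symmetric density matrix over atomic orbitals
#' @param S overlap matrix
#' @param orbital_map orbital map (from \code{\link{orbital_map}} or a
#'   \code{tb_matrix_pair})
#' @return numeric vector of per-shell electron populations; the sum equals
#'   the trace of \code{P S} (total electron count)
#' @export
mulliken_populations <- function(density_matrix, S, orbital_map) {
  pop_orb <- rowSums(density_matrix * S)
  as.numeric(tapply(pop_orb, orbital_map$shell_id, sum))
}

#' Dipole moment from atomic point charges
#'
#' @param geom a \code{tb_geometry}
#' @param q_atom net atomic charges in e (positive = electron-deficient)
#' @return Cartesian dipole vector in e*Angstrom
#' @export
dipole_moment <- function(geom, q_atom) {
  stopifnot(length(q_atom) == length(geom$z))
  drop(crossprod(geom$xyz, q_atom))
}

#' Solve the SCC equations for assembled matrices
#'
#' @param matrix_pair a \code{tb_matrix_pair} from
#'   \code{\link{assemble_matrices}}
#' @param gamma result of \code{\link{gamma_matrix}} (or a bare matrix over
#'   the shells of the geometry)
#' @param n_electrons total number of valence electrons (must be even)
#' @param options \code{\link{scf_options}}
#' @return list (class \code{tb_scf_result}): \code{delta_q} per shell,
#'   \code{delta_q_atomic} aggregated per atom (electron excess),
#'   \code{density_matrix}, \code{mo_energies}, \code{electronic_energy}
#'   (band-structure + Coulomb, Hartree), \code{coulomb_energy},
#'   \code{populations}, \code{converged}, \code{n_iterations}
#' @export
scf_solve <- function(matrix_pair, gamma, n_electrons,
                      options = scf_options()) {
  if (n_electrons %% 2 != 0)
    stop("odd electron count: only closed-shell systems are supported")
  omap <- matrix_pair$orbital_map
  G <- if (is.list(gamma)) gamma$gamma else gamma
  shells <- if (is.list(gamma) && !is.null(gamma$shells)) gamma$shells else NULL
  if (is.null(shells)) {
    # reconstruct shell occupancies from the orbital map
    sid <- unique(omap$shell_id)
    q0 <- vapply(sid, function(s) {
      row <- omap[omap$shell_id == s, ][1, ]
      shell_occupancy(row$z, row$shell)
    }, numeric(1))
  } else {
    q0 <- shells$occupancy
  }
  res <- cpp_scf_raw(matrix_pair$H1, matrix_pair$S, G,
                     as.integer(omap$shell_id - 1L), q0,
                     as.integer(n_electrons / 2), options)
  dq <- drop(res$dq)
  atom_of_shell <- vapply(sort(unique(omap$shell_id)), function(s)
    omap$atom[omap$shell_id == s][1], numeric(1))
  dq_atomic <- as.numeric(tapply(dq, atom_of_shell, sum))
  structure(list(
    delta_q = dq,
    delta_q_atomic = dq_atomic,
    density_matrix = res$P,
    mo_energies = drop(res$mo_energies),
    populations = drop(res$populations),
    electronic_energy = res$e_band_structure + res$e_coulomb,
    band_energy = res$e_band_structure,
    coulomb_energy = res$e_coulomb,
    converged = res$converged,
    n_iterations = res$n_iterations
  ), class = "tb_scf_result")
}

#' @export
print.tb_scf_result <- function(x, ...) {
  cat(sprintf("<tb_scf_result: E_elec %.8f Ha, %s in %d iterations>\n",
              x$electronic_energy,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Pairwise repulsive energy of a geometry
#' @param geom a \code{tb_geometry}
#' @param params a \code{tb_paramset}
#' @return energy in Hartree
#' @export
repulsive_energy <- function(geom, params) {
  nat <- length(geom$z)
  if (nat < 2L) return(0)
  e <- 0
  for (a in 1:(nat - 1L)) for (b in (a + 1L):nat) {
    r <- sqrt(sum((geom$xyz[b, ] - geom$xyz[a, ])^2))
    k <- channel_key("R", min(geom$z[a], geom$z[b]),
                     max(geom$z[a], geom$z[b]), "rep")
    sp <- params$repulsive[[k]]
    if (is.null(sp)) stop("missing repulsive spline ", k)
    e <- e + spline_eval(sp, r)
  }
  e
}

#' Linear reference energy of a geometry
#'
#' E_ref = sum_Z N_Z C_Z + C_0, the per-element linear term that absorbs
#' isolated-atom energies so that energy comparisons act on atomization
#' energies.
#'
#' @param geom a \code{tb_geometry}
#' @param reference list(c_elements, c0)
#' @return energy in Hartree
#' @export
reference_energy_of <- function(geom, reference) {
  syms <- element_symbol(geom$z)
  e <- reference$c0
  for (s in names(reference$c_elements))
    e <- e + sum(syms == s) * reference$c_elements[[s]]
  as.numeric(e)
}

#' Full SCC calculation for one geometry
#'
#' Assembles matrices, solves the SCC equations, and reports all energy
#' components, atomic charges and the dipole.
#'
#' @param geom a \code{tb_geometry}
#' @param params a \code{tb_paramset}
#' @param options \code{\link{scf_options}}
#' @return \code{tb_scf_result} extended with \code{charges} (net atomic
#'   charges, e), \code{dipole} (e*Angstrom), \code{repulsive_energy},
#'   \code{reference_energy} and \code{total_energy} (Hartree)
#' @export
scf_compute <- function(geom, params, options = scf_options()) {
  mp <- assemble_matrices(geom, params)
  gm <- gamma_matrix(geom, params)
  res <- scf_solve(mp, gm, n_electrons(geom), options)
  res$charges <- -res$delta_q_atomic
  res$dipole <- dipole_moment(geom, res$charges)
  res$repulsive_energy <- repulsive_energy(geom, params)
  res$reference_energy <- reference_energy_of(geom, params$reference)
  res$total_energy <- res$electronic_energy + res$repulsive_energy +
    res$reference_energy
  res
}
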