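#' Physical constants and element tables
#'
#' Unit conventions used throughout: geometries and spline knots are in
#' Angstrom at the user-facing boundary, matrix elements and energies in
#' Hartree, charges in units of the elementary charge e, dipoles in e*Angstrom.
#' Coulomb kernels and Slater-Koster tables work in atomic units internally.
#'
#' @name units
#' @keywords internal
NULL

#' Bohr radius in Angstrom (1 Angstrom = 1.8897259886 bohr)
#' @export
ANG_PER_BOHR <- 1 / 1.8897259886

#' Conversion factor, bohr per Angstrom
#' @export
BOHR_PER_ANG <- 1.8897259886

#' Hartree in kcal/mol
#' @export
KCAL_PER_HA <- 627.509474

#' Hartree in eV
#' @export
EV_PER_HA <- 27.211386245988

# Supported elements and their properties. Valence-only minimal basis:
# H carries a single s shell, first-row elements carry s and p.
.element_table <- data.frame(
  symbol  = c("H", "C", "N", "O"),
  z       = c(1L, 6L, 7L, 8L),
  n_val   = c(1, 4, 5, 6),            # valence electrons
  has_p   = c(FALSE, TRUE, TRUE, TRUE),
  mass    = c(1.008, 12.011, 14.007, 15.999),
  stringsAsFactors = FALSE
)

#' Atomic number from element symbol
#' @param symbol character vector of element symbols
#' @return integer vector of atomic numbers
#' @export
element_z <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "),
         " (supported: ", paste(.element_table$symbol, collapse = ", "), ")")
  }
  .element_table$z[i]
}

#' Element symbol from atomic number
#' @param z integer vector of atomic numbers
#' @return character vector of symbols
#' @export
element_symbol <- function(z) {
  i <- match(z, .element_table$z)
  if (anyNA(i)) {
    stop("unsupported atomic number(s): ",
         paste(unique(z[is.na(i)]), collapse = ", "))
  }
  .element_table$symbol[i]
}

#' Number of valence electrons for an element
#' @param z atomic number vector
#' @return numeric vector of valence electron counts (H 1, C 4, N 5, O 6)
#' @export
valence_electrons <- function(z) {
  .element_table$n_val[match(z, .element_table$z)]
}

element_has_p <- function(z) {
  .element_table$has_p[match(z, .element_table$z)]
}

element_mass <- function(z) {
  .element_table$mass[match(z, .element_table$z)]
}

supported_z <- function() .element_table$z

# Shells carried by an element: "s" or c("s","p")
element_shells <- function(z) {
  if (element_has_p(z)) c("s", "p") else "s"
}

# Neutral reference occupancy of a valence shell (electrons).
# H: s^1; C: s^2 p^2; N: s^2 p^3; O: s^2 p^4.
shell_occupancy <- function(z, shell) {
  if (shell == "s") {
    if (z == 1L) 1 else 2
  } else {
    valence_electrons(z) - 2
  }
}

#' Empirical formula in Hill order
#'
#' Canonical element-count string: with carbon present, carbon first, then
#' hydrogen, then the remaining elements alphabetically; without carbon,
#' all elements alphabetically. Counts of one are omitted (e.g. "CH4",
#' "H2O").
#'
#' @param z integer vector of atomic numbers
#' @return single character string
#' @export
empirical_formula <- function(z) {
  sym <- element_symbol(z)
  cnt <- table(sym)
  nm <- names(cnt)
  if ("C" %in% nm) {
    ord <- c("C", intersect("H", nm), sort(setdiff(nm, c("C", "H"))))
  } else {
    ord <- sort(nm)
  }
  n <- as.integer(cnt[ord])
  paste0(ord, ifelse(n == 1L, "", n), collapse = "")
}
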