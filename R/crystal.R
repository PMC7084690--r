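# average (isotope-abundance-weighted) residue masses, Da (residue =
# amino acid minus one water); one water is added back per intact chain
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01528

#' Average mass of a peptide chain
#'
#' Sum of average residue masses plus one water for the free termini.
#'
#' @param sequence one-letter amino-acid string.
#' @return mass in Da.
#' @export
chain_mass <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, names(RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

#' Mature human CCL5 sequence and variants
#'
#' The 68-residue mature human CCL5 (RANTES) chain, optionally preceded by
#' the initiator methionine (M0) retained in bacterial expression, with
#' point substitutions applied by position.
#'
#' @param mutations named character vector of substitutions, names are
#'   residue positions in mature numbering (e.g. `c("12" = "A",
#'   "14" = "A")` for the 12AAA14 variant).
#' @param met0 prepend the initiator Met (default `TRUE`).
#' @return one-letter sequence string.
#' @examples
#' ccl5_sequence(c("12" = "A", "14" = "A"))
#' @export
ccl5_sequence <- function(mutations = NULL, met0 = TRUE) {
  seq68 <- "SPYSSDTTPCCFAYIARPLPRAHIKEYFYTSGKCSNPAVVFVTRKNRQVCANPEKKWVREYINSLEMS"
  aa <- strsplit(seq68, "")[[1]]
  stopifnot(length(aa) == 68)
  if (!is.null(mutations)) {
    pos <- as.integer(names(mutations))
    stopifnot(all(pos >= 1 & pos <= 68))
    aa[pos] <- toupper(mutations)
  }
  paste0(if (met0) "M" else "", paste(aa, collapse = ""))
}

#' Matthews coefficient and solvent content of a crystal
#'
#' Desk arithmetic relating cell, symmetry and chain mass:
#' V_M = V_cell / (Z * mass) with Z = (symmetry operators) * (chains per
#' asymmetric unit), and solvent fraction 1 - v_p / V_M with the protein
#' packing volume v_p = 1.230 cubic Angstrom per Dalton (the conventional
#' 0.74 cm^3/g partial specific volume).
#'
#' @param cell `c(a, b, c, alpha, beta, gamma)` in Angstrom / degrees.
#' @param space_group Hermann-Mauguin symbol (see [space_group_ops()]).
#' @param sequence one-letter chain sequence (modifications already
#'   applied), or a precomputed mass in Da.
#' @param z_per_asu chains per asymmetric unit (default 1).
#' @return list of class `crystal_content`: `matthews_vm` (cubic
#'   Angstrom/Da), `solvent_fraction`, `z_molecules`, `chain_mass_da`,
#'   `cell_volume_a3`.
#' @examples
#' crystal_content(c(48.3, 48.3, 60.4, 90, 90, 120), "P 31 2 1",
#'                 ccl5_sequence(c("12" = "A", "14" = "A")))
#' @export
crystal_content <- function(cell, space_group, sequence, z_per_asu = 1L) {
  ops <- space_group_ops(space_group)
  vol <- cell_volume(cell)
  mass <- if (is.numeric(sequence)) sequence else chain_mass(sequence)
  if (mass <= 0) stop("chain mass must be positive")
  z <- length(ops) * z_per_asu
  vm <- vol / (z * mass)
  if (vm <= 1.230)
    stop("impossible packing: V_M = ", signif(vm, 3),
         " <= 1.230 A^3/Da leaves no room for solvent")
  structure(list(matthews_vm = vm,
                 solvent_fraction = 1 - 1.230 / vm,
                 z_molecules = z,
                 chain_mass_da = mass,
                 cell_volume_a3 = vol),
            class = "crystal_content")
}

#' @export
print.crystal_content <- function(x, ...) {
  cat(sprintf(
    "crystal content: V_M = %.2f A^3/Da, solvent %.1f%%, Z = %d, chain %.0f Da\n",
    x$matthews_vm, 100 * x$solvent_fraction, x$z_molecules,
    x$chain_mass_da))
  invisible(x)
}
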