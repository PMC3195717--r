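#' @keywords internal
"_PACKAGE"

## Unit system: lengths in Angstrom, time in fs, mass in amu, energy in
## kcal/mol.  The integrator works in internal units (amu A^2 fs^-2); a
## single constant converts to/from kcal/mol.

# 1 kcal/mol expressed in amu A^2 fs^-2 (4184 J/mol / 1e7 J/mol)
.KCAL_PER_MOL_INTERNAL <- 4.184e-4

# Boltzmann constant, kcal/mol/K
.KB_KCAL <- 1.987204259e-3

# Boltzmann constant in internal units (amu A^2 fs^-2 per K)
.KB_INTERNAL <- .KB_KCAL * .KCAL_PER_MOL_INTERNAL

# Standard residue masses (amu), 3-letter codes; unknown codes fall back
# to a uniform 110 amu bead.
.RESIDUE_MASS <- c(
  ALA =  71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY =  57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO =  97.1167, SER =  87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL =  99.1326)

.DEFAULT_MASS <- 110

#' Look up coarse-grained bead masses for residue codes
#'
#' @param resnames character vector of three-letter residue codes.
#' @return numeric vector of masses in amu; unknown codes get 110 amu.
#' @keywords internal
residue_mass <- function(resnames) {
  m <- .RESIDUE_MASS[toupper(resnames)]
  m[is.na(m)] <- .DEFAULT_MASS
  unname(m)
}

# Classed condition helper so callers/tests can match on error class.
ed_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "enerdiss_error")))
}

ed_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) ed_stop(class, msg, ...)
  invisible(TRUE)
}
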