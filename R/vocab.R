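# Categorical feature vocabulary for molecular graphs.
#
# Node attributes: atom type (atomic number) and chirality tag.
# Edge attributes: bond type and bond direction.
# The last atom-type / bond-type category is reserved for the mask indicator.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Feature vocabulary for molecular graph featurization
#'
#' Defines the category counts of the four categorical attribute channels used
#' to featurize molecules: atom type (one category per atomic number, plus a
#' trailing mask token), chirality tag (unspecified / counter-clockwise /
#' clockwise / other), bond type (single / double / triple / aromatic, plus a
#' trailing mask token) and bond direction (none / end-up / end-down).
#' Indices are 1-based; the mask tokens are always the last category of their
#' channel.
#'
#' @param n_elements Number of atomic-number categories (default 118).
#' @return An object of class `feature_vocab`: a list with fields
#'   `atom_type_count`, `chirality_count`, `bond_type_count`,
#'   `bond_dir_count`, `mask_atom_index`, `mask_bond_index`.
#' @examples
#' v <- feature_vocab()
#' v$mask_atom_index == v$atom_type_count
#' @export
feature_vocab <- function(n_elements = 118L) {
  stopifnot(n_elements >= 1L)
  v <- list(
    atom_type_count = n_elements + 1L,   # + mask token
    chirality_count = 4L,
    bond_type_count = 5L,                # single/double/triple/aromatic + mask
    bond_dir_count  = 3L,                # none / end-up / end-down
    mask_atom_index = n_elements + 1L,
    mask_bond_index = 5L
  )
  class(v) <- "feature_vocab"
  v
}

.CHIRALITY_UNSPECIFIED <- 1L
.CHIRALITY_CCW <- 2L   # @
.CHIRALITY_CW  <- 3L   # @@
.CHIRALITY_OTHER <- 4L

.BOND_SINGLE <- 1L
.BOND_DOUBLE <- 2L
.BOND_TRIPLE <- 3L
.BOND_AROMATIC <- 4L

.BOND_DIR_NONE <- 1L

.atomic_number <- function(symbol) {
  z <- match(symbol, .ELEMENTS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  z
}
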