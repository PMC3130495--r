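#' Residue chemistry parameter set
#'
#' Loads the plain-text tables describing each standard residue's side-chain
#' atoms and bonds: element, partial charge (elementary-charge units), the
#' number of lone pairs counted for hydrogen-bond acceptance, a flag marking
#' hydrogens that donate hydrogen bonds, and bond lengths in Angstrom.  The
#' shipped tables use pH-7 protonation states (Lys+, Arg+, Asp-, Glu-, and the
#' neutral epsilon-tautomer of His) and include all side-chain hydrogens plus
#' the alpha-carbon root; the alpha-hydrogen is treated as backbone and
#' excluded, except for glycine whose side chain is its single hydrogen
#' substituent.  Proline's second bond to the backbone (through N) is present
#' so its graph closes a ring through the root.
#'
#' Pauling electronegativities are attached per element.  Any file with the
#' same columns can be substituted, making the derived index table fully
#' reproducible and swappable.
#'
#' @param atoms_file,bonds_file Paths to TSV files; defaults ship with the
#'   package.
#' @return An object of class `residue_chemistry`: a list with data frames
#'   `atoms` (residue, atom, element, charge, lone_pairs, donor_h,
#'   electronegativity) and `bonds` (residue, atom1, atom2, length).
#' @export
#' @examples
#' chem <- load_chemistry()
#' subset(chem$atoms, residue == "A")
load_chemistry <- function(atoms_file = system.file("extdata",
                                                    "residue_atoms.tsv",
                                                    package = "ugtregio"),
                           bonds_file = system.file("extdata",
                                                    "residue_bonds.tsv",
                                                    package = "ugtregio")) {
  atoms <- utils::read.delim(atoms_file, stringsAsFactors = FALSE)
  bonds <- utils::read.delim(bonds_file, stringsAsFactors = FALSE)
  needed_a <- c("residue", "atom", "element", "charge", "lone_pairs",
                "donor_h")
  needed_b <- c("residue", "atom1", "atom2", "length")
  if (!all(needed_a %in% names(atoms)))
    stop("atoms file must have columns: ", paste(needed_a, collapse = ", "))
  if (!all(needed_b %in% names(bonds)))
    stop("bonds file must have columns: ", paste(needed_b, collapse = ", "))
  en <- pauling_electronegativity()
  unknown <- setdiff(unique(atoms$element), names(en))
  if (length(unknown))
    stop("no electronegativity for element(s): ",
         paste(unknown, collapse = ", "))
  atoms$electronegativity <- unname(en[atoms$element])
  if (any(bonds$length <= 0)) stop("bond lengths must be positive")
  if (any(atoms$lone_pairs < 0)) stop("lone_pairs must be non-negative")
  bad_lp <- atoms$lone_pairs > 0 & !atoms$element %in% c("N", "O", "S")
  if (any(bad_lp))
    stop("lone pairs counted on non-N/O/S atom(s): ",
         paste(atoms$atom[bad_lp], collapse = ", "))
  structure(list(atoms = atoms, bonds = bonds), class = "residue_chemistry")
}

#' Pauling electronegativities for the elements found in amino acids
#' @return Named numeric vector.
#' @export
pauling_electronegativity <- function() {
  c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58)
}

#' The twenty standard one-letter residue codes
#' @return Character vector of length 20, alphabetical by code.
#' @export
standard_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}
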