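#' Bondi van der Waals radii (Angstrom)
#'
#' Default atomic radii used by the binding-residue labelling rule and the
#' Shrake-Rupley solvent-accessibility calculation. Covers the elements found
#' in protein and nucleic-acid polymers; user tables may override.
#'
#' @format Named numeric vector, element symbol -> radius in Angstrom.
#' @export
vdw_radii_bondi <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# Theoretical maximum accessible surface areas (A^2) per residue type
# (Tien et al. 2013, theoretical column), used to normalise SASA into RSA.
.max_asa <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

.standard_aa <- names(.max_asa)

# Non-standard residues folded onto their parent types before anything else
# sees them; unmapped hetero residues are dropped with a message.
.residue_aliases <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HSD = "HIS", HSE = "HIS",
  HSP = "HIS", CSO = "CYS", PTR = "TYR", SEP = "SER", TPO = "THR"
)

#' Nucleic-acid residue names recognised when selecting ligand atoms
#' @export
nucleic_residue_names <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))
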