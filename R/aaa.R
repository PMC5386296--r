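# Shared residue-name constants (loaded before the other source files).

#' @keywords internal
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # phosphoresidues keep their parent one-letter code; the phospho flag is
  # carried separately
  SEP = "S", TPO = "T", PTR = "Y"
)

#' @keywords internal
.phospho_resnames <- c(SEP = "S", TPO = "T", PTR = "Y")

#' @keywords internal
.aa1to3 <- c(stats::setNames(names(.aa3to1)[1:20], unname(.aa3to1[1:20])))
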