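# Amino-acid reference data: names, one/three-letter codes, and elemental
# formulas of the free (neutral, non-ionized) amino acids. Residue formulas
# are free amino acid minus one H2O (peptide condensation).

.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
          "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# element counts C,H,N,O,S of the free amino acids (neutral forms)
.AA_FORMULA <- matrix(c(
  # C   H  N  O  S
    3,  7, 1, 2, 0,  # Ala
    6, 14, 4, 2, 0,  # Arg
    4,  8, 2, 3, 0,  # Asn
    4,  7, 1, 4, 0,  # Asp
    3,  7, 1, 2, 1,  # Cys
    5, 10, 2, 3, 0,  # Gln
    5,  9, 1, 4, 0,  # Glu
    2,  5, 1, 2, 0,  # Gly
    6,  9, 3, 2, 0,  # His
    6, 13, 1, 2, 0,  # Ile
    6, 13, 1, 2, 0,  # Leu
    6, 14, 2, 2, 0,  # Lys
    5, 11, 1, 2, 1,  # Met
    9, 11, 1, 2, 0,  # Phe
    5,  9, 1, 2, 0,  # Pro
    3,  7, 1, 3, 0,  # Ser
    4,  9, 1, 3, 0,  # Thr
   11, 12, 2, 2, 0,  # Trp
    9, 11, 1, 3, 0,  # Tyr
    5, 11, 1, 2, 0   # Val
), nrow = 20, byrow = TRUE,
  dimnames = list(.AA3, c("C", "H", "N", "O", "S")))

.aa_formula <- function(aa3) {
  v <- .AA_FORMULA[aa3, ]
  elemental_formula(C = v["C"], H = v["H"], N = v["N"], O = v["O"], S = v["S"])
}

# residue (amino acid minus H2O) element matrix, charge column appended
.aa_residue_matrix <- function() {
  m <- .AA_FORMULA
  m[, "H"] <- m[, "H"] - 2
  m[, "O"] <- m[, "O"] - 1
  cbind(m, Z = 0)
}

#' Per-residue reference properties of the 20 amino acids
#'
#' Returns, for each standard amino acid, the average oxidation state of
#' carbon of its residue (identical to that of the free amino acid, since the
#' condensation water contributes neither carbon nor net oxidation-state
#' change) and the per-residue water and oxygen demand obtained by projecting
#' the residue formula onto the QEC basis (glutamine, glutamic acid,
#' cysteine, H2O, O2).
#'
#' @return A data frame with columns `aa` (three-letter code), `letter`,
#'   `C` (carbon count per residue), `Zc`, `nH2O`, `nO2`.
#' @export
amino_acid_properties <- function() {
  res <- .aa_residue_matrix()
  b <- basis_set("QEC")
  co <- t(apply(res, 1, function(v) {
    f <- elemental_formula(C = v["C"], H = v["H"], N = v["N"], O = v["O"],
                           S = v["S"], Z = v["Z"])
    project_onto_basis(f, b, length = 1L)$per_residue
  }))
  data.frame(
    aa = .AA3, letter = .AA1, C = unname(res[, "C"]),
    Zc = apply(res, 1, function(v)
      unname((-v["H"] + 3 * v["N"] + 2 * v["O"] + 2 * v["S"] + v["Z"]) / v["C"])),
    nH2O = unname(co[, "H2O"]), nO2 = unname(co[, "O2"]),
    row.names = NULL
  )
}
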