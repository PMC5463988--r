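# Independent oracles used across the suite. These re-derive expected values
# by brute force or enumeration and never call the code paths they check.

# exact two-sided Wilcoxon rank-sum p-value by enumeration of all rank
# assignments (tie-free samples only)
enumerate_wilcoxon_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x); n <- n1 + length(y)
  obs <- sum(rank(c(x, y))[seq_len(n1)])
  all_sums <- apply(utils::combn(n, n1), 2, sum)
  # two-sided: double the smaller tail (distribution is symmetric)
  mu <- n1 * (n + 1) / 2
  lo <- mean(all_sums <= obs); hi <- mean(all_sums >= obs)
  min(1, 2 * min(lo, hi))
}

# CLES by explicit double loop
enumerate_cles <- function(x, y) {
  wins <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) wins <- wins + 1
    else if (xi == yj) wins <- wins + 0.5
  }
  100 * wins / (length(x) * length(y))
}

# weighted rank difference straight from its definition
brute_wrd <- function(a_up, a_down) {
  r <- rank(c(a_up, a_down))
  n_up <- length(a_up); n_down <- length(a_down); n <- n_up + n_down
  2 * ((n_down / n) * sum(r[seq_len(n_up)]) -
       (n_up / n) * sum(r[n_up + seq_len(n_down)]))
}

# stoichiometric matrix of the QEC+ basis, typed by hand (rows = species,
# columns = C,H,N,O,S,charge), used as the independent projection oracle
QECP_MATRIX <- matrix(c(
  # C  H  N  O  S  Z
    3, 7, 1, 2, 1, 0,   # Cys
    5, 9, 1, 4, 0, 0,   # Glu
    5, 10, 2, 3, 0, 0,  # Gln
    0, 2, 0, 1, 0, 0,   # H2O
    0, 0, 0, 2, 0, 0,   # O2
    0, 1, 0, 0, 0, 1    # H+
), nrow = 6, byrow = TRUE,
  dimnames = list(c("Cys", "Glu", "Gln", "H2O", "O2", "H+"),
                  c("C", "H", "N", "O", "S", "Z")))

# independent linear solve for QEC+ projection coefficients
oracle_project_qecp <- function(target) {
  # target: named numeric C,H,N,O,S,Z
  solve(t(QECP_MATRIX), target[colnames(QECP_MATRIX)])
}

# random CHNOS formula guaranteed representable (it always is in QEC+);
# H kept >= 6 so protonation shifts of up to -5 stay physical
random_formula <- function() {
  elemental_formula(C = runif(1, 1, 60), H = runif(1, 6, 100),
                    N = runif(1, 0, 20), O = runif(1, 0, 30),
                    S = runif(1, 0, 5), Z = round(runif(1, -4, 4)))
}

# random amino-acid composition of given length
random_composition <- function(len = 50) {
  counts <- as.numeric(stats::rmultinom(1, len, rep(1 / 20, 20)))
  names(counts) <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                     "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                     "Thr", "Trp", "Tyr", "Val")
  aa_composition(counts)
}

# neutral random formula (for mass-bearing mixture pools)
random_formula_neutral <- function() {
  elemental_formula(C = runif(1, 1, 60), H = runif(1, 0, 100),
                    N = runif(1, 0, 20), O = runif(1, 0, 30),
                    S = runif(1, 0, 5))
}

# a formula with ZC shifted by d at unchanged carbon content and molar mass:
# adding d*c to the formal charge moves ZC by exactly d (charge is massless)
shift_protein <- function(f, d) {
  v <- unclass(f)
  elemental_formula(C = v["C"], H = v["H"], N = v["N"], O = v["O"],
                    S = v["S"], Z = v["Z"] + d * v["C"])
}

# composition table of homopolymer-like toy proteins from sequences
toy_aatable <- function(seqs, ids = names(seqs)) {
  rows <- lapply(seq_along(seqs), function(i) {
    comp <- seq_to_composition(seqs[[i]])
    data.frame(id = ids[i], organism = "toy", chains = 1,
               as.data.frame(t(as.numeric(unclass(comp)))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  names(tab)[4:23] <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                        "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                        "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
  tab
}

# a bare potential_diagram object with a prescribed field, for contour tests
fake_diagram <- function(x, y, W, name = "fake") {
  structure(list(x = x, y = y, wrd = W, name = name,
                 n_up = 1, n_down = 1, dropped = c(up = 0, down = 0)),
            class = "potential_diagram")
}
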