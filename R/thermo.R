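# Standard Gibbs energies, ionization, equilibrium constants, and chemical
# affinity of protein formation from basis species at fixed temperature and
# pressure (defaults: 310.15 K, 1 bar).

.RGAS <- 8.314462618  # J/(mol K)

.ln10RT <- function(T) log(10) * .RGAS * T

# ---- thermodynamic parameter table ---------------------------------------

#' Read a thermodynamic parameter table
#'
#' Delimited text (tab or comma) with columns
#' `species, kind, formula, G0_Jmol, source` where `kind` is one of
#' `basis`, `residue`, `terminus`. The table must contain every residue group
#' exactly once and a single terminus group.
#'
#' @param path File path.
#' @return Object of class `thermo_table`: the validated data frame with
#'   attributes `T` (K) and `P` (bar).
#' @export
read_thermo_table <- function(path) {
  lines <- readLines(path, n = 50L)
  first <- lines[!startsWith(lines, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("species", "kind", "formula", "G0_Jmol", "source")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("thermo table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(df$kind %in% c("basis", "residue", "terminus")))
    stop("thermo table kind must be basis, residue, or terminus")
  res <- df$species[df$kind == "residue"]
  if (!setequal(res, .AA3) || anyDuplicated(res))
    stop("thermo table must contain each of the 20 residue groups exactly once")
  if (sum(df$kind == "terminus") != 1L)
    stop("thermo table must contain exactly one terminus group")
  if (!all(is.finite(df$G0_Jmol))) stop("non-finite G0 in thermo table")
  structure(df, class = c("thermo_table", "data.frame"),
            T = 310.15, P = 1)
}

#' Default thermodynamic parameter table (310.15 K, 1 bar)
#'
#' Standard Gibbs energies of formation for the basis species (aqueous Cys,
#' Glu, Gln; liquid H2O; gaseous O2; aqueous H+ = 0 by convention), the 20
#' amino-acid residue groups of a polypeptide, and the chain-terminus group
#' (composition H2O). Values are compiled from published thermodynamic data
#' for aqueous amino acids; residue groups are amino acid minus H2O. See the
#' methods vignette for provenance and the approximations involved.
#'
#' @return A `thermo_table`.
#' @export
default_thermo_table <- function() {
  path <- system.file("extdata", "thermo_gibbs.tsv", package = "protchem")
  if (!nzchar(path)) stop("bundled thermo table not found")
  read_thermo_table(path)
}

.thermo_g0 <- function(table, species, kind = NULL) {
  sel <- table$species == species
  if (!is.null(kind)) sel <- sel & table$kind == kind
  g <- table$G0_Jmol[sel]
  if (length(g) != 1L)
    stop("thermo table lookup failed for species ", shQuote(species))
  g
}

# ---- ionization -----------------------------------------------------------

.DEFAULT_PKA <- c(Asp = 3.65, Glu = 4.25, His = 6.00, Cys = 8.30, Tyr = 10.07,
                  Lys = 10.53, Arg = 12.48, Nterm = 8.00, Cterm = 3.55)
# acid groups release a proton on deprotonation (charge -1 when deprotonated);
# base groups bind a proton (charge +1 when protonated)
.PKA_IS_ACID <- c(Asp = TRUE, Glu = TRUE, His = FALSE, Cys = TRUE, Tyr = TRUE,
                  Lys = FALSE, Arg = FALSE, Nterm = FALSE, Cterm = TRUE)

#' Define a protein ionization model
#'
#' A Henderson-Hasselbalch model over the ionizable side chains (Asp, Glu,
#' His, Cys, Tyr, Lys, Arg) and the chain termini, with configurable pKa
#' values at the reference temperature. Disabling the model reproduces the
#' non-ionized treatment exactly.
#'
#' @param pKa Named numeric vector of pKa values (names among Asp, Glu, His,
#'   Cys, Tyr, Lys, Arg, Nterm, Cterm); defaults are standard side-chain
#'   values.
#' @param enabled Logical; a disabled model yields zero charge everywhere.
#' @return Object of class `ionization_model`.
#' @export
ionization_model <- function(pKa = NULL, enabled = TRUE) {
  pk <- .DEFAULT_PKA
  if (!is.null(pKa)) {
    bad <- setdiff(names(pKa), names(pk))
    if (length(bad)) stop("unknown ionizable group(s): ",
                          paste(bad, collapse = ", "))
    pk[names(pKa)] <- pKa
  }
  if (!all(is.finite(pk))) stop("pKa values must be finite")
  structure(list(pKa = pk, acid = .PKA_IS_ACID, enabled = isTRUE(enabled)),
            class = "ionization_model")
}

# fraction ionized (deprotonated for acids, protonated for bases) at given pH
.alpha_ionized <- function(pKa, acid, pH) {
  if (acid) 1 / (1 + 10^(pKa - pH)) else 1 / (1 + 10^(pH - pKa))
}

#' Average protein charge from the ionization model
#'
#' Sums, over ionizable groups, the ionized fraction times the group charge
#' (acids contribute -1 when deprotonated, bases +1 when protonated). Chain
#' termini contribute once per chain. The total charge is continuous and
#' non-increasing in pH.
#'
#' @param comp An `aa_composition`.
#' @param pH Solution pH.
#' @param model An `ionization_model`; a disabled model gives zero charge.
#' @return List with `z` (total charge), `zbar` (per residue), and
#'   `alpha` (per-group ionized fractions).
#' @export
ionization_state <- function(comp, pH = 7, model = ionization_model()) {
  stopifnot(inherits(comp, "aa_composition"))
  L <- sum(comp)
  if (!model$enabled)
    return(list(z = 0, zbar = 0, alpha = setNames(numeric(0), character(0))))
  chains <- attr(comp, "chains")
  groups <- names(model$pKa)
  ngroup <- vapply(groups, function(g) {
    if (g %in% c("Nterm", "Cterm")) chains else unclass(comp)[[g]]
  }, numeric(1))
  alpha <- vapply(groups, function(g)
    .alpha_ionized(model$pKa[[g]], model$acid[[g]], pH), numeric(1))
  sign <- ifelse(model$acid[groups], -1, +1)
  z <- sum(ngroup * alpha * sign)
  list(z = z, zbar = z / L, alpha = alpha)
}

# ---- Gibbs energy, logK, affinity ----------------------------------------

# ionization Gibbs correction (J/mol): for each acid group, the deprotonation
# reaction HA = H+ + A- has dG0 = +ln(10) R T pKa, weighted by the
# deprotonated fraction; for each base, protonation has dG0 = -ln(10) R T pKa
# weighted by the protonated fraction.
.ionization_gibbs <- function(comp, pH, model, T) {
  if (!model$enabled) return(0)
  chains <- attr(comp, "chains")
  groups <- names(model$pKa)
  ngroup <- vapply(groups, function(g) {
    if (g %in% c("Nterm", "Cterm")) chains else unclass(comp)[[g]]
  }, numeric(1))
  alpha <- vapply(groups, function(g)
    .alpha_ionized(model$pKa[[g]], model$acid[[g]], pH), numeric(1))
  dG <- ifelse(model$acid[groups], 1, -1) * .ln10RT(T) * model$pKa[groups]
  sum(ngroup * alpha * dG)
}

#' Standard Gibbs energy per residue by group additivity
#'
#' Per-residue standard Gibbs energy of a protein: sum of residue-group
#' contributions, plus one terminus-group contribution per chain (if terminal
#' groups are included), plus the ionization correction at the given pH, all
#' divided by sequence length. With ionization disabled this is pure group
#' additivity on the non-ionized protein.
#'
#' @param comp An `aa_composition`.
#' @param table A `thermo_table`.
#' @param ionization An `ionization_model` (default disabled).
#' @param pH Solution pH (used only when ionization is enabled).
#' @param terminal Include the terminus group per chain (default TRUE).
#' @return Standard Gibbs energy per residue in J/mol.
#' @export
gibbs_per_residue <- function(comp, table = default_thermo_table(),
                              ionization = ionization_model(enabled = FALSE),
                              pH = 7, terminal = TRUE) {
  stopifnot(inherits(comp, "aa_composition"), inherits(table, "thermo_table"))
  T <- attr(table, "T")
  L <- sum(comp)
  gres <- vapply(.AA3, function(a) .thermo_g0(table, a, "residue"), numeric(1))
  G <- sum(unclass(comp) * gres)
  if (terminal) {
    gterm <- table$G0_Jmol[table$kind == "terminus"]
    G <- G + attr(comp, "chains") * gterm
  }
  G <- G + .ionization_gibbs(comp, pH, ionization, T)
  G / L
}

#' Per-residue equilibrium constant of the basis-formation reaction
#'
#' For the formation reaction of one residue-equivalent of (possibly ionized)
#' protein from the basis species, `logK = -dG0r / (ln(10) R T)` where `dG0r`
#' is the per-residue standard Gibbs energy of the protein minus the
#' basis-species contributions weighted by the per-residue projection
#' coefficients. With a proton in the basis, ionization changes only the
#' proton coefficient (equal to the average charge) and the ionization
#' energy; the other projection coefficients are those of the non-ionized
#' formula.
#'
#' @param comp An `aa_composition`.
#' @param basis A `basis_set` (default QEC+).
#' @param table A `thermo_table`.
#' @param ionization An `ionization_model`.
#' @param pH Solution pH.
#' @param terminal Include terminal groups (default TRUE).
#' @return `logK` per residue (dimensionless, decadic).
#' @export
logk_per_residue <- function(comp, basis = basis_set("QEC+"),
                             table = default_thermo_table(),
                             ionization = ionization_model(enabled = FALSE),
                             pH = 7, terminal = TRUE) {
  T <- attr(table, "T")
  L <- sum(comp)
  if (ionization$enabled && !basis$proton)
    stop("ionized proteins require a proton-bearing basis (QEC+)")
  f <- formula_from_composition(comp, terminal_water = terminal)
  pr <- project_onto_basis(f, basis, length = L)
  nbar <- pr$per_residue
  ion <- ionization_state(comp, pH, ionization)
  if (basis$proton) nbar[["H+"]] <- ion$zbar
  gprot <- gibbs_per_residue(comp, table, ionization, pH, terminal)
  gbasis <- vapply(basis$species, function(s) {
    if (s == "H+") 0 else .thermo_g0(table, s, "basis")
  }, numeric(1))
  dG0r <- gprot - sum(nbar * gbasis)
  -dG0r / .ln10RT(T)
}

# ---- conditions and affinity ---------------------------------------------

#' Thermodynamic conditions for affinity calculations
#'
#' Defaults follow mean human-plasma concentrations for the amino-acid basis
#' species (log activities -3.6 cysteine, -4.5 glutamic acid, -3.2
#' glutamine), unit activity of the protein residue (log a = 0), pH 7, and
#' 310.15 K.
#'
#' @param logfO2 Decadic log of oxygen fugacity.
#' @param logaH2O Decadic log of water activity.
#' @param pH Solution pH.
#' @param loga_basis Named log-activities of the amino-acid basis species.
#' @param loga_residue Log activity of the protein residue.
#' @param T Temperature in K.
#' @return Object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(logfO2 = -66, logaH2O = 0, pH = 7,
                              loga_basis = c(Cys = -3.6, Glu = -4.5, Gln = -3.2),
                              loga_residue = 0, T = 310.15) {
  structure(list(logfO2 = logfO2, logaH2O = logaH2O, pH = pH,
                 loga_basis = loga_basis, loga_residue = loga_residue, T = T),
            class = "thermo_conditions")
}

#' Per-residue chemical affinity of protein formation
#'
#' Evaluates, for the basis-species formation reaction of one
#' residue-equivalent of protein,
#' `A* = A/(ln(10) R T) = logK + sum(nbar_i log a_i) + nbar_O2 log fO2 +
#'  nbar_H2O log a_H2O - zbar pH - log a_residue`.
#' O2 enters through its gas-phase fugacity; H2O through its liquid-standard
#' state activity. The returned object retains every constituent term so the
#' sum can be audited.
#'
#' @param comp An `aa_composition`.
#' @param conditions A `thermo_conditions`.
#' @param basis A `basis_set` (default QEC+).
#' @param table A `thermo_table`.
#' @param ionization An `ionization_model`.
#' @param terminal Include terminal groups (default TRUE).
#' @return Object of class `affinity_value`: list with `astar`
#'   (dimensionless A/(2.303RT)), `terms` (named contributions), and the
#'   per-residue coefficients used.
#' @export
affinity_per_residue <- function(comp, conditions = thermo_conditions(),
                                 basis = basis_set("QEC+"),
                                 table = default_thermo_table(),
                                 ionization = ionization_model(enabled = FALSE),
                                 terminal = TRUE) {
  L <- sum(comp)
  f <- formula_from_composition(comp, terminal_water = terminal)
  pr <- project_onto_basis(f, basis, length = L)
  nbar <- pr$per_residue
  ion <- ionization_state(comp, conditions$pH, ionization)
  logK <- logk_per_residue(comp, basis, table, ionization, conditions$pH,
                           terminal)
  terms <- c(logK = logK)
  for (s in names(conditions$loga_basis)) {
    if (s %in% names(nbar))
      terms[[paste0("n_", s)]] <- nbar[[s]] * conditions$loga_basis[[s]]
  }
  terms[["n_H2O"]] <- nbar[["H2O"]] * conditions$logaH2O
  terms[["n_O2"]] <- nbar[["O2"]] * conditions$logfO2
  terms[["charge"]] <- -ion$zbar * conditions$pH
  terms[["residue"]] <- -conditions$loga_residue
  astar <- sum(terms)
  structure(list(astar = astar, terms = terms,
                 nbar = nbar, zbar = ion$zbar, logK = logK),
            class = "affinity_value")
}

#' @export
print.affinity_value <- function(x, ...) {
  cat("A/(2.303RT) per residue =", format(x$astar, digits = 8), "\n")
  invisible(x)
}

#' Define a rectangular grid over log fO2 and log aH2O
#'
#' @param logfO2 Length-2 range of log oxygen fugacity.
#' @param logaH2O Length-2 range of log water activity.
#' @param n Number of nodes per axis (length 1 or 2, at least 2).
#' @return Object of class `grid_spec` with strictly increasing axes `x`
#'   (log fO2) and `y` (log aH2O).
#' @export
grid_spec <- function(logfO2 = c(-72, -60), logaH2O = c(-4, 2), n = 129) {
  n <- rep(as.integer(n), length.out = 2)
  if (any(n < 2)) stop("grid needs at least 2 points per axis")
  if (diff(logfO2) <= 0 || diff(logaH2O) <= 0)
    stop("grid axis ranges must be strictly increasing")
  structure(list(x = seq(logfO2[1], logfO2[2], length.out = n[1]),
                 y = seq(logaH2O[1], logaH2O[2], length.out = n[2])),
            class = "grid_spec")
}

#' Affinity surfaces for a set of proteins over a condition grid
#'
#' Each protein's per-residue affinity is an affine function of log fO2 and
#' log aH2O with slopes equal to its per-residue O2 and H2O demand, so the
#' surface is evaluated from a per-protein intercept plus the two linear
#' terms.
#'
#' @param aatable Composition table of the proteins.
#' @param grid A `grid_spec`.
#' @param conditions A `thermo_conditions` supplying all non-grid variables.
#' @param basis,table,ionization,terminal As in [affinity_per_residue()].
#' @return List of class `affinity_grid` with `x`, `y`, `ids`, and `A`: an
#'   array of dimension (proteins, nx, ny) of A/(2.303RT) values.
#' @export
affinity_grid <- function(aatable, grid = grid_spec(),
                          conditions = thermo_conditions(),
                          basis = basis_set("QEC+"),
                          table = default_thermo_table(),
                          ionization = ionization_model(enabled = FALSE),
                          terminal = TRUE) {
  if (nrow(aatable) < 1) stop("empty protein set")
  base <- thermo_conditions(logfO2 = 0, logaH2O = 0, pH = conditions$pH,
                            loga_basis = conditions$loga_basis,
                            loga_residue = conditions$loga_residue,
                            T = conditions$T)
  nprot <- nrow(aatable)
  a0 <- numeric(nprot); sO2 <- numeric(nprot); sH2O <- numeric(nprot)
  for (i in seq_len(nprot)) {
    comp <- .row_to_composition(aatable[i, ])
    av <- affinity_per_residue(comp, base, basis, table, ionization, terminal)
    a0[i] <- av$astar
    sO2[i] <- av$nbar[["O2"]]
    sH2O[i] <- av$nbar[["H2O"]]
  }
  nx <- length(grid$x); ny <- length(grid$y)
  A <- array(0, dim = c(nprot, nx, ny))
  for (j in seq_len(nx)) {
    colpart <- a0 + sO2 * grid$x[j]
    for (k in seq_len(ny)) A[, j, k] <- colpart + sH2O * grid$y[k]
  }
  structure(list(x = grid$x, y = grid$y, ids = aatable$id, A = A,
                 nO2 = sO2, nH2O = sH2O, intercept = a0),
            class = "affinity_grid")
}
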