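# Lipid-protein redox mass balance: the lipid:protein weight ratio in cancer
# that conserves the carbon-weighted mean oxidation state of carbon, given a
# proteomic ZC shift.

#' Define a macromolecule pool
#'
#' @param label Pool name.
#' @param formula Elemental formula (object or string); may be fractional
#'   (an averaged formula).
#' @param mass Mass of the pool in grams (positive).
#' @return Object of class `macromolecule_pool`.
#' @export
macromolecule_pool <- function(label, formula, mass = 1) {
  f <- .as_formula(formula)
  if (unname(f["C"]) <= 0) stop("pool formula must contain carbon")
  if (!(is.numeric(mass) && mass > 0)) stop("pool mass must be positive")
  structure(list(label = label, formula = f, mass = mass),
            class = "macromolecule_pool")
}

#' Carbon-weighted mean oxidation state of a mixture
#'
#' Each pool contributes in proportion to its moles of carbon
#' (mass x mol C per gram); the result equals the ZC of the combined
#' elemental formula of all pools.
#'
#' @param pools List of `macromolecule_pool` objects.
#' @return Mixture-average ZC.
#' @export
mixture_zc <- function(pools) {
  stopifnot(length(pools) >= 1)
  molC <- vapply(pools, function(p) p$mass * carbon_per_gram(p$formula),
                 numeric(1))
  if (sum(molC) <= 0) stop("mixture contains no carbon")
  zcs <- vapply(pools, function(p) zc(p$formula), numeric(1))
  sum(molC * zcs) / sum(molC)
}

#' 1-palmitoyl-2,3-dioleoyl-glycerol, a representative triacylglycerol
#' @return An `elemental_formula` (C55H102O6).
#' @export
triacylglycerol_formula <- function() parse_formula("C55H102O6")

#' Average protein formula of the bundled representative human proteome
#'
#' Mean per-protein elemental formula computed from the synthetic
#' human-proteome-like mean amino-acid composition shipped with the package
#' (representative UniProt human amino-acid frequencies at a typical protein
#' length; a stand-in for a real reference-proteome average).
#'
#' @return An `elemental_formula` with fractional counts.
#' @export
mean_human_protein_formula <- function() {
  path <- system.file("extdata", "aa_human_synthetic.csv", package = "protchem")
  tab <- read_aa_table(path)
  formula_from_composition(.row_to_composition(tab[1, ]))
}

#' Define a lipid-protein redox scenario
#'
#' @param lipid_formula Elemental formula of the lipid pool (default the
#'   representative triacylglycerol C55H102O6).
#' @param protein_formula Average elemental formula of the normal-cell
#'   proteome (default from the bundled representative human composition).
#' @param lp_hypoxia Lipid:protein weight ratio in hypoxic normal cells
#'   (default 0.19; normal-cell baselines 0.15-0.16 may be substituted).
#' @param dzc_hypoxia,dzc_cancer Proteomic ZC shifts in hypoxia and cancer
#'   relative to normal cells (defaults -0.03 and +0.03).
#' @return Object of class `redox_scenario`.
#' @export
redox_scenario <- function(lipid_formula = triacylglycerol_formula(),
                           protein_formula = mean_human_protein_formula(),
                           lp_hypoxia = 0.19,
                           dzc_hypoxia = -0.03, dzc_cancer = 0.03) {
  if (lp_hypoxia <= 0) stop("lipid:protein ratio must be positive")
  if (abs(dzc_hypoxia) >= 1 || abs(dzc_cancer) >= 1)
    stop("|dZC| must be below 1")
  structure(list(lipid = .as_formula(lipid_formula),
                 protein = .as_formula(protein_formula),
                 lp_hypoxia = lp_hypoxia,
                 dzc_hypoxia = dzc_hypoxia, dzc_cancer = dzc_cancer),
            class = "redox_scenario")
}

#' Solve for the cancer lipid:protein ratio conserving mixture ZC
#'
#' With protein mass normalized to 1 g, finds the lipid mass `r` such that
#' the carbon-weighted mean ZC of (lipid at ratio `r`, protein at the cancer
#' ZC) equals that of (lipid at the hypoxic ratio, protein at the hypoxic
#' ZC). The balance is linear in `r` and solved in closed form; it is
#' singular when the lipid ZC equals the conserved mixture value. Raising the
#' cancer-protein ZC raises the required ratio (the reduced lipid pool must
#' grow to absorb the electrons released by protein oxidation).
#'
#' @param scenario A `redox_scenario`.
#' @return Object of class `redox_result`: `lp_cancer`, `percent_change`
#'   (relative to the hypoxic ratio), `mixture_zc` (the conserved value), and
#'   `electrons_per_g_protein` (mol e- released by the proteomic shift per
#'   gram protein).
#' @export
solve_lipid_protein_ratio <- function(scenario = redox_scenario()) {
  stopifnot(inherits(scenario, "redox_scenario"))
  a <- carbon_per_gram(scenario$lipid)      # mol C / g lipid
  b <- carbon_per_gram(scenario$protein)    # mol C / g protein
  zL <- zc(scenario$lipid)
  z0 <- zc(scenario$protein)
  zh <- z0 + scenario$dzc_hypoxia
  zcn <- z0 + scenario$dzc_cancer
  rh <- scenario$lp_hypoxia
  M <- (a * rh * zL + b * zh) / (a * rh + b)  # conserved mixture ZC
  if (abs(zL - M) < 1e-12)
    stop("degenerate scenario: lipid ZC equals the conserved mixture ZC, ",
         "no finite lipid:protein ratio exists")
  rc <- b * (M - zcn) / (a * (zL - M))
  if (rc <= 0)
    stop("no positive lipid:protein ratio solves the balance ",
         "(cancer-protein ZC beyond the representable range)")
  structure(list(lp_cancer = rc, lp_hypoxia = rh,
                 percent_change = 100 * (rc - rh) / rh,
                 mixture_zc = M,
                 electrons_per_g_protein = b * (zcn - zh)),
            class = "redox_result")
}

#' @export
print.redox_result <- function(x, ...) {
  cat("Lipid-protein redox balance\n")
  cat(sprintf("  conserved mixture ZC:        %.4f\n", x$mixture_zc))
  cat(sprintf("  L:P ratio, hypoxia:          %.3f\n", x$lp_hypoxia))
  cat(sprintf("  L:P ratio, cancer:           %.3f\n", x$lp_cancer))
  cat(sprintf("  change vs hypoxia:           %+.1f%%\n", x$percent_change))
  cat(sprintf("  electrons released per g protein: %.4f mol e-\n",
              x$electrons_per_g_protein))
  invisible(x)
}
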