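---
title: "Compositional and thermodynamic description of proteomic transformations"
author: "protchem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional and thermodynamic description of proteomic transformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protchem)
```

# The model

Differential protein expression is, among other things, a change in bulk
chemical composition. `protchem` describes that change with two per-protein
metrics and a thermodynamic potential built on them.

**Average oxidation state of carbon.** For a protein with non-ionized
formula $\mathrm{C}_c\mathrm{H}_h\mathrm{N}_n\mathrm{O}_o\mathrm{S}_s$,

$$Z_\mathrm{C} = \frac{-h + 3n + 2o + 2s + z}{c},$$

with $z = 0$ for the non-ionized form. Gaining or losing protons changes $h$
and $z$ equally, so $Z_\mathrm{C}$ is ionization-invariant; we therefore
always evaluate it on the non-ionized formula. $Z_\mathrm{C}$ of a protein
equals the carbon-weighted mean of its residues' $Z_\mathrm{C}$ (the
condensation water carries no carbon and a zero numerator contribution), an
identity the test suite checks to $10^{-12}$.

**Water demand per residue.** Hydration is quantified componentially, not
structurally: the protein's formula is projected onto a set of basis species
whose linear combination reproduces it exactly. With the QEC+ basis —
cysteine, glutamic acid, glutamine, H$_2$O, O$_2$, and H$^+$ — the formation
reaction of a protein is

$$n_\mathrm{Cys}\,\mathrm{Cys} + n_\mathrm{Glu}\,\mathrm{Glu} +
  n_\mathrm{Gln}\,\mathrm{Gln} + n_{\mathrm{H_2O}}\,\mathrm{H_2O} +
  n_{\mathrm{O_2}}\,\mathrm{O_2} + z\,\mathrm{H^+} \rightarrow
  \text{protein},$$

and the length-normalized coefficient $\bar n_{\mathrm{H_2O}}$ is the water
demand per residue. The projection is a linear solve over the element (and,
with a proton in the basis, charge) balance; it is exact to $10^{-9}$ per
element and the proton coefficient equals the protein's charge, so
ionization changes only the proton coefficient and all other coefficients
can be computed from the non-ionized formula. Any full-rank basis is
supported through the same code path; `QEC`, `QEC+` and `inorganic`
(CO$_2$, NH$_3$, H$_2$S, H$_2$O, O$_2$) are predefined. The QEC basis is the
default because across realistic proteomes it leaves $\bar n_{\mathrm{O_2}}$
strongly correlated with $Z_\mathrm{C}$ (an oxidation-state indicator) while
keeping $\bar n_{\mathrm{H_2O}}$ only weakly coupled to it — an inorganic
basis ties both to $Z_\mathrm{C}$, as `basis_correlation_report()` shows on
any generated proteome.

Worth noting: for poly-glutamine with the terminal water excluded the
reaction needs $n_\mathrm{Gln} = L$ and $n_{\mathrm{H_2O}} = -L$ (each
residue is glutamine *minus* water), so its water demand per residue is
$-1$, not $0$; typical real proteins sit around $-0.7$ to $-0.9$. The
terminal H$_2$O group adds exactly `chains/length` to
$\bar n_{\mathrm{H_2O}}$ and never moves $Z_\mathrm{C}$. Metrics are
computed with the terminal group included by default; a toggle excludes it.

# Group comparisons

For each differential-expression dataset (lists of up- and down-expressed
protein IDs), `compare_groups()` reports group means of $Z_\mathrm{C}$ and
$\bar n_{\mathrm{H_2O}}$, their differences (up minus down), two-sided
Wilcoxon rank-sum $p$-values, and the common language effect size (CLES):
the percentage of up/down pairings in which the up-expressed protein has the
larger value, with ties counted half. Half-credit for ties preserves
`cles(x, y) + cles(y, x) = 100`; ties are rare for these continuous metrics.
The Wilcoxon implementation enumerates exactly when both groups have at most
25 tie-free observations and otherwise uses the midrank normal approximation
with continuity correction; the two agree within 0.01 in the overlap regime
and the exact path's type-I error is at its nominal 5% in the suite's
1,000-replicate null simulation.

Datasets are cleaned on load: ID updates applied first, IDs reported with
both directions removed from both groups, within-group duplicates collapsed,
and every removal counted in a machine-readable log. Isoform-suffixed IDs
that miss the composition table fall back to their parent accession.

A comparison is *large* when $|\Delta| > 0.01$, *significant* when
$p < 0.05$, and *strong* when CLES $\le 40$ or $\ge 60$ (all configurable
via `classification_thresholds()`). The diagram-grouping predicate marks a
dataset for a metric's group when that metric's signed difference exceeds
the threshold while the other metric is neither significant nor strong; when
the two quietness criteria disagree we require both (the stricter reading),
which makes group membership conservative.

# Chemical affinity and potential diagrams

The per-residue affinity of the formation reaction at given conditions is

$$A^* = \frac{A}{2.303RT} = \log K + \bar n_\mathrm{Cys}\log a_\mathrm{Cys}
 + \bar n_\mathrm{Glu}\log a_\mathrm{Glu}
 + \bar n_\mathrm{Gln}\log a_\mathrm{Gln}
 + \bar n_{\mathrm{H_2O}}\log a_{\mathrm{H_2O}}
 + \bar n_{\mathrm{O_2}}\log f_{\mathrm{O_2}}
 - \bar z\,\mathrm{pH} - \log a_\mathrm{residue}.$$

O$_2$ enters as a gas-phase fugacity (its customary reference state), H$_2$O
as liquid-standard-state activity. Defaults follow mean human plasma:
$\log a_\mathrm{Cys} = -3.6$, $\log a_\mathrm{Glu} = -4.5$,
$\log a_\mathrm{Gln} = -3.2$; $\log a_\mathrm{residue} = 0$; pH 7;
$T = 310.15\,$K. $A^*$ is affine in
$(\log f_{\mathrm{O_2}}, \log a_{\mathrm{H_2O}})$ with slopes
$(\bar n_{\mathrm{O_2}}, \bar n_{\mathrm{H_2O}})$, which is how
`affinity_grid()` evaluates whole surfaces, and every `affinity_per_residue`
result retains its constituent terms so the sum can be audited to $10^{-9}$.
Changing $\log a_\mathrm{residue}$ shifts all proteins equally and can never
change a rank ordering.

**Standard Gibbs energies.** `logK` comes from group additivity over a
fixed-condition parameter table (310.15 K, 1 bar) shipped as
`inst/extdata/thermo_gibbs.tsv`: aqueous Cys/Glu/Gln, liquid H$_2$O
($-237.18$ kJ/mol), gaseous O$_2$ and aqueous H$^+$ (0 by convention), and
the 20 residue groups. The table is compiled from published standard Gibbs
energies of formation of aqueous amino acids at 25 °C; residue groups are
defined as amino acid minus H$_2$O (a condensation-energy-neutral
approximation) and the 25 °C values are used at the reference condition
without entropy correction (the methionine entry is an additivity estimate).
Both approximations contribute terms that are common to all residues or
cancel in differences between proteins — and it is only those differences
that determine weighted-rank fields and equipotential positions — so
absolute per-residue `logK` values are approximate while the diagrams'
geometry is not sensitive to them. Users with better data can drop in any
table matching the documented schema.

**Ionization.** The reference treatment is non-ionized proteins. An optional
Henderson–Hasselbalch model (side chains Asp 3.65, Glu 4.25, His 6.00,
Cys 8.30, Tyr 10.07, Lys 10.53, Arg 12.48; termini 8.00/3.55; all
configurable) supplies the average charge $\bar z$ and a Gibbs correction of
$\pm 2.303RT\,\mathrm{p}K_a$ per group weighted by its ionized fraction.
Disabling it reproduces the non-ionized model exactly. This is a desk-scale
surrogate for a full group-thermodynamics treatment; at pH 7 it lowers
equipotential lines by roughly one $\log a_{\mathrm{H_2O}}$ unit, the
expected qualitative magnitude, but its absolute placement should not be
over-read.

**Weighted rank difference.** At each node of a
$\log f_{\mathrm{O_2}} \times \log a_{\mathrm{H_2O}}$ grid the affinities of
all proteins in a dataset are ranked together (midranks for ties) and

$$\mathrm{WRD} = 2\left(\frac{n_\mathrm{down}}{n}\sum r_\mathrm{up}
 - \frac{n_\mathrm{up}}{n}\sum r_\mathrm{down}\right),$$

which is antisymmetric under swapping the groups, bounded by
$\pm n_\mathrm{up} n_\mathrm{down}$ with equality exactly at complete rank
separation, and invariant under any strictly increasing transform of the
affinities. The zero contour of the WRD field is the *equipotential line*:
conditions of rank-wise equal formation potential for the two groups.
Diagrams for related datasets are merged by node-wise arithmetic means, and
the member equipotential positions are summarized by median and quartiles.

**A property worth knowing.** Because WRD is a rank statistic, scaling the
compositional contrast between the groups scales every between-protein
affinity contrast without (to first order) changing its sign at any node.
The equipotential position therefore responds to the *direction* of a
compositional shift — oxidation-driven groups are read along
$\log f_{\mathrm{O_2}}$, hydration-driven groups along
$\log a_{\mathrm{H_2O}}$ — but is nearly invariant to the shift's
*magnitude*: in synthetic sweeps the median position stays anchored (about
$\log f_{\mathrm{O_2}} \approx -66.8$ with the bundled table for
oxidation-tilted groups) while larger imposed shifts mainly sharpen the
field and shrink the position's variance. Sweeps at 5–30 datasets per level
show magnitude-driven drift smaller than the between-dataset noise.

# Numerical choices

- Projection: QR solve over the element/charge matrix; residual tolerance
  $10^{-8}$ for representability, typical residuals $<10^{-12}$. A
  rank-deficient basis is an error naming the rank.
- Equipotential extraction: the scalar position is the mean coordinate of
  the exact marching-squares vertex set — nodes where the field is exactly
  zero plus linear-interpolation crossings on sign-changing grid edges.
  (`contourLines()` perturbs levels that coincide with node values, so it is
  used only for the plotted polylines.) An identically zero plateau yields
  its midpoint; a single-sign field reports "no crossing" rather than an
  error.
- Quartiles of member positions use the linear-interpolation convention
  (`stats::quantile` type 7).
- Default grid: $\log f_{\mathrm{O_2}} \in [-72, -60]$,
  $\log a_{\mathrm{H_2O}} \in [-4, 2]$, 129 × 129 nodes, configurable; this
  window brackets where realistic proteome comparisons cross zero under the
  default conditions.
- Energy units are J/mol with $R = 8.314462618$ J/(mol K); decadic logs
  throughout.
- Nonstandard residue codes (B, J, Z, X, U, O) are dropped with a logged
  count, not imputed.

# The synthetic-data generator

`generate_synthetic_experiment()` emulates an up/down proteomics comparison:
per-group amino-acid frequencies are exponential tilts of a representative
human-proteome baseline,
$f_i \propto \mathrm{base}_i\,e^{\beta Z_{\mathrm{C},i} + \gamma \bar n_{\mathrm{H_2O},i}}$,
protein lengths are log-normal (median 375 residues, a human-like scale),
residue counts are multinomial, and all randomness derives from one seed.
Because $Z_\mathrm{C}$ and $\bar n_{\mathrm{H_2O}}$ are correlated across
amino acids, the presets solve jointly for $(\beta, \gamma)$ so that the
frequency-level shift hits the target on the focal metric and zero on the
other: `hypoxia` imposes $\Delta Z_\mathrm{C} = -0.03$, `cancer` $+0.03$,
`hyperosmotic` $\Delta\bar n_{\mathrm{H_2O}} = -0.02$, magnitudes typical of
the corresponding laboratory comparisons; group sizes default to 100/100.

What the generator does *not* emulate: real proteomes have correlated,
protein-family-structured composition variation (multinomial sampling
understates between-protein variance), study-specific ID noise, organism
mixtures, and length–composition dependence. Passing recovery tests
therefore demonstrates that the statistical machinery detects imposed
compositional shifts of realistic size at realistic sample sizes — not that
any particular biological dataset will behave likewise.

The bundled `aa_human_synthetic.csv` is a synthetic mean human-proteome
composition assembled from representative amino-acid frequencies; it stands
in for a reference-proteome average in the redox default scenario and is
labelled accordingly.

# The lipid–protein redox balance

Assuming (i) the carbon-weighted mean oxidation state of the lipid+protein
pool is the same in cancer cells as in hypoxic normal cells and (ii) only
the molecule counts change, `solve_lipid_protein_ratio()` finds the cancer
lipid:protein weight ratio in closed form from a linear balance: with
protein mass 1 g, lipid carbon density $a$, protein carbon density $b$,
lipid $Z_\mathrm{C}^L$, and protein $Z_\mathrm{C}$ shifted by $-0.03$
(hypoxia) and $+0.03$ (cancer) around the proteome mean, conserve the
mixture $Z_\mathrm{C}$ attained at the hypoxic ratio 0.19. The default
lipid is the representative triacylglycerol C$_{55}$H$_{102}$O$_6$
($Z_\mathrm{C} = -90/55 \approx -1.64$). With the bundled mean protein
composition the solution is a ratio of about 0.226, a rise of about 19%
over the hypoxic ratio, releasing $\approx 0.0027$ mol e$^-$ per gram of
protein; normal-cell baselines 0.15 and 0.16 are accepted as alternative
scenario presets. Raising the cancer-protein $Z_\mathrm{C}$ strictly raises
the required ratio; the case where the lipid $Z_\mathrm{C}$ equals the
conserved mixture value is singular and reported as such.

# Problem sizes and limitations

The test suite runs at desk scale by design: 1,000-formula projection
sweeps, 1,000-replicate null simulations, 500-instance WRD bound checks,
100-seed recovery runs at 100/100 proteins, and 65 × 65 grids for
oracle-equivalence checks (the package default for production diagrams is
129 × 129). The full synthetic pipeline — simulate, compare, classify,
diagram, merge — completes in well under five minutes on one CPU.

Known limitations: fixed temperature and pressure (no equations of state or
activity-coefficient models, no O$_2$ solubility conversion); the ionization
surrogate above; approximate absolute `logK` values from the compiled Gibbs
table; no post-translational modifications; compositions only — no
structure, abundance weighting, or functional annotation. Reproducing the
published multi-study summaries additionally requires the original per-study
up/down ID lists and compositions, which are not redistributable here; the
reproduction test blocks document the expected file layout under
`inst/extdata/reproduction/`.
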