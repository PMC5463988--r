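# Amino-acid compositions, protein formulas, and stoichiometric projection
# onto basis species.

#' Create an amino-acid composition
#'
#' @param counts Named numeric vector of residue counts; names may be
#'   three-letter (`Ala`) or one-letter (`A`) codes. Counts may be fractional
#'   (averaged compositions) but must be non-negative.
#' @param chains Number of polypeptide chains (positive integer, default 1).
#' @return Object of class `aa_composition`: a length-20 numeric vector in
#'   fixed three-letter-code order with attribute `chains`.
#' @export
aa_composition <- function(counts, chains = 1) {
  if (is.null(names(counts))) stop("counts must be named by amino acid")
  nm <- names(counts)
  idx <- match(nm, .AA3)
  idx1 <- match(nm, .AA1)
  idx[is.na(idx)] <- idx1[is.na(idx)]
  if (anyNA(idx)) stop("unknown amino acid code(s): ",
                       paste(nm[is.na(idx)], collapse = ", "))
  x <- setNames(numeric(20), .AA3)
  for (i in seq_along(counts)) x[idx[i]] <- x[idx[i]] + counts[i]
  if (any(x < 0)) stop("residue counts must be non-negative")
  if (sum(x) < 1) stop("composition must contain at least one residue")
  if (!(is.numeric(chains) && length(chains) == 1L && chains >= 1))
    stop("chains must be a positive integer")
  structure(x, chains = as.numeric(chains), class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  cat("Amino acid composition:", sum(x), "residues,",
      attr(x, "chains"), "chain(s)\n")
  print(unclass(x)[unclass(x) > 0])
  invisible(x)
}

#' Count residues in an amino-acid sequence
#'
#' Sanitizes the sequence (uppercases, strips whitespace and `*`), then counts
#' standard one-letter codes. Nonstandard codes (B, J, Z, X, U, O and anything
#' else) are dropped; the number dropped is recorded in the `dropped`
#' attribute and reported with a warning.
#'
#' @param sequence Character string of one-letter codes.
#' @param chains Number of polypeptide chains.
#' @return An `aa_composition` with attribute `dropped`.
#' @export
seq_to_composition <- function(sequence, chains = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- gsub("[\\s*]", "", toupper(sequence), perl = TRUE)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  ok <- chars %in% .AA1
  dropped <- sum(!ok)
  if (dropped > 0)
    warning(sprintf("dropped %d nonstandard residue code(s)", dropped))
  if (!any(ok)) stop("sequence contains no standard residues")
  counts <- table(factor(chars[ok], levels = .AA1))
  comp <- aa_composition(setNames(as.numeric(counts), .AA3), chains = chains)
  attr(comp, "dropped") <- dropped
  comp
}

#' Elemental formula of a protein from its composition
#'
#' The polypeptide formula is the sum of residue formulas plus, by default,
#' one H2O per chain for the terminal groups. The formula is that of the
#' fully non-ionized protein (charge 0).
#'
#' @param comp An `aa_composition`.
#' @param terminal_water Include one H2O per chain (default TRUE)? Terminal
#'   water has no effect on ZC but shifts the per-residue water demand by
#'   `chains/length`.
#' @return An `elemental_formula`.
#' @export
formula_from_composition <- function(comp, terminal_water = TRUE) {
  stopifnot(inherits(comp, "aa_composition"))
  if (sum(comp) < 1) stop("zero-length composition")
  res <- .aa_residue_matrix()
  tot <- drop(crossprod(res, unclass(comp)))
  f <- elemental_formula(C = tot["C"], H = tot["H"], N = tot["N"],
                         O = tot["O"], S = tot["S"])
  if (terminal_water)
    f <- f + elemental_formula(H = 2 * attr(comp, "chains"),
                               O = attr(comp, "chains"))
  f
}

#' Elemental formula of a protein from its sequence
#'
#' @inheritParams seq_to_composition
#' @param terminal_water Include one H2O per chain (default TRUE)?
#' @return An `elemental_formula` (non-ionized, charge 0).
#' @examples
#' format_formula(formula_from_sequence("GG"))  # "C4H8N2O3"
#' @export
formula_from_sequence <- function(sequence, chains = 1, terminal_water = TRUE) {
  formula_from_composition(seq_to_composition(sequence, chains),
                           terminal_water = terminal_water)
}

# ---- basis sets -----------------------------------------------------------

.BASIS_PRESETS <- list(
  "QEC" = list(
    species = c("Cys", "Glu", "Gln", "H2O", "O2"),
    formulas = c("C3H7NO2S", "C5H9NO4", "C5H10N2O3", "H2O", "O2"),
    proton = FALSE),
  "QEC+" = list(
    species = c("Cys", "Glu", "Gln", "H2O", "O2", "H+"),
    formulas = c("C3H7NO2S", "C5H9NO4", "C5H10N2O3", "H2O", "O2", "H+1"),
    proton = TRUE),
  "inorganic" = list(
    species = c("CO2", "NH3", "H2S", "H2O", "O2"),
    formulas = c("CO2", "NH3", "H2S", "H2O", "O2"),
    proton = FALSE)
)

#' Define a set of basis species
#'
#' A basis set is an ordered list of chemical species whose formulas can be
#' linearly combined to represent any protein composition. Available presets:
#' `"QEC"` (cysteine, glutamic acid, glutamine, H2O, O2), `"QEC+"` (QEC plus
#' the proton, supporting ionized formulas) and `"inorganic"` (CO2, NH3, H2S,
#' H2O, O2). A user-defined basis is given as a named character vector of
#' formulas.
#'
#' @param x Preset name or named character vector of formulas.
#' @return Object of class `basis_set` with elements `species`, `matrix`
#'   (species x C,H,N,O,S,Z stoichiometric matrix) and `proton` flag.
#' @export
basis_set <- function(x = "QEC") {
  if (is.character(x) && length(x) == 1L && x %in% names(.BASIS_PRESETS)) {
    p <- .BASIS_PRESETS[[x]]
    formulas <- setNames(p$formulas, p$species)
    proton <- p$proton
  } else if (is.character(x) && !is.null(names(x))) {
    formulas <- x
    proton <- any(vapply(x, function(f) {
      v <- unclass(parse_formula(f))
      abs(v["Z"]) > 0 && v["H"] > 0 && v["C"] == 0
    }, logical(1)))
  } else stop("basis must be a preset name or a named character vector")
  m <- t(vapply(formulas, function(f) unclass(parse_formula(f)),
                numeric(6)))
  rownames(m) <- names(formulas)
  # active columns: elements actually representable plus charge if proton basis
  structure(list(species = names(formulas), matrix = m, proton = proton,
                 name = if (is.character(x) && length(x) == 1L) x else "custom"),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat("Basis set", shQuote(x$name), "with species:",
      paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

# columns of the element/charge matrix used to balance a given basis
.basis_columns <- function(basis) {
  if (basis$proton) c("C", "H", "N", "O", "S", "Z") else c("C", "H", "N", "O", "S")
}

#' Project a formula onto basis species
#'
#' Solves the element (and, for proton-bearing bases, charge) balance so that
#' a linear combination of the basis-species formulas reproduces the target
#' formula exactly. For the QEC+ basis the proton coefficient equals the
#' formula's charge. Per-residue coefficients are the totals divided by
#' `length`.
#'
#' @param formula An `elemental_formula` (or formula string).
#' @param basis A `basis_set`.
#' @param length Sequence length used for per-residue normalization.
#' @return Object of class `basis_coefficients`: list with `coefficients`
#'   (named by basis species), `per_residue`, `length`, and the maximum
#'   element-balance `residual`.
#' @export
project_onto_basis <- function(formula, basis = basis_set("QEC"), length = 1L) {
  f <- .as_formula(formula)
  stopifnot(inherits(basis, "basis_set"), length >= 1)
  cols <- .basis_columns(basis)
  A <- t(basis$matrix[, cols, drop = FALSE])   # elements x species
  if (nrow(A) < ncol(A)) stop("basis has more species than balanced components")
  qa <- qr(A)
  if (qa$rank < ncol(A))
    stop("singular basis: stoichiometric matrix has rank ", qa$rank,
         " for ", ncol(A), " species; projection is not unique")
  b <- unclass(f)[cols]
  x <- qr.coef(qa, b)
  if (anyNA(x)) stop("projection failed")
  resid <- A %*% x - b
  # components not in `cols` (e.g. charge for a neutral basis) must balance too
  allres <- t(basis$matrix) %*% x - unclass(f)
  if (max(abs(allres)) > 1e-8)
    stop("formula cannot be represented in this basis (residual ",
         format(max(abs(allres))), ")")
  coef <- setNames(as.numeric(x), basis$species)
  structure(list(coefficients = coef, per_residue = coef / length,
                 length = length, residual = max(abs(resid)),
                 basis = basis$name),
            class = "basis_coefficients")
}

#' @export
print.basis_coefficients <- function(x, ...) {
  cat("Projection onto", shQuote(x$basis), "basis (length ", x$length, "):\n",
      sep = "")
  print(round(x$coefficients, 6))
  if (x$length != 1) {
    cat("per residue:\n")
    print(round(x$per_residue, 6))
  }
  invisible(x)
}

# ---- composition tables ---------------------------------------------------

.AA_TABLE_COLS <- c("id", "organism", "chains", .AA3)

#' Read an amino-acid composition table
#'
#' Delimited text with columns `id, organism, chains, Ala, ..., Val` (fixed
#' order, tab- or comma-separated).
#'
#' @param path File path.
#' @return A data frame in the fixed column order.
#' @export
read_aa_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.AA_TABLE_COLS, names(df))
  if (length(missing))
    stop("composition table lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[, .AA_TABLE_COLS]
  if (anyDuplicated(df$id)) stop("duplicate protein ids in composition table")
  df
}

#' Write an amino-acid composition table
#'
#' Emits exactly the canonical dialect: tab-separated with columns
#' `id, organism, chains, Ala, ..., Val`.
#'
#' @param df Data frame as returned by [read_aa_table()] or
#'   [generate_synthetic_proteome()].
#' @param path Output file path.
#' @export
write_aa_table <- function(df, path) {
  missing <- setdiff(.AA_TABLE_COLS, names(df))
  if (length(missing))
    stop("composition table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.table(df[, .AA_TABLE_COLS], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file into a composition table
#'
#' Reads plain or gzip FASTA via Biostrings. UniProt-style headers
#' (`sp|ACCESSION|NAME ...` or `tr|ACCESSION|NAME ...`) have the accession
#' extracted; otherwise the first whitespace-delimited token is used.
#'
#' @param path FASTA file path.
#' @param organism Organism label stored in the table.
#' @return Composition table (data frame) with one row per record.
#' @export
read_fasta_composition <- function(path, organism = "unknown") {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  headers <- names(seqs)
  ids <- vapply(headers, function(h) {
    tok <- strsplit(h, "\\s+")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  rows <- lapply(as.character(seqs), function(s) {
    comp <- suppressWarnings(seq_to_composition(s))
    as.numeric(unclass(comp))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- .AA3
  df <- data.frame(id = ids, organism = organism, chains = 1,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(m))
}

# composition table row -> aa_composition
.row_to_composition <- function(row) {
  counts <- as.numeric(row[.AA3])
  aa_composition(setNames(counts, .AA3),
                 chains = if ("chains" %in% names(row)) as.numeric(row[["chains"]]) else 1)
}

#' Compositional metrics for a collection of proteins
#'
#' Computes, for each protein in a composition table, the sequence length,
#' the average oxidation state of carbon (on the non-ionized formula) and the
#' per-residue water and oxygen demand from projection onto the chosen basis.
#'
#' @param aatable Composition table (data frame with `id, organism, chains`
#'   and the 20 amino-acid columns).
#' @param basis A `basis_set` (default QEC).
#' @param terminal_water Include terminal H2O groups (default TRUE)? ZC is
#'   unaffected either way.
#' @return Data frame with columns `id, organism, length, Zc, nH2O, nO2`.
#' @export
compute_metrics <- function(aatable, basis = basis_set("QEC"),
                            terminal_water = TRUE) {
  stopifnot(is.data.frame(aatable), nrow(aatable) >= 1)
  res <- .aa_residue_matrix()
  cols <- .basis_columns(basis)
  A <- t(basis$matrix[, cols, drop = FALSE])
  Ainv <- solve(qr(A), diag(nrow(A)))   # species x elements pseudo-solve
  counts <- as.matrix(aatable[, .AA3])
  storage.mode(counts) <- "double"
  chains <- if ("chains" %in% names(aatable)) as.numeric(aatable$chains) else rep(1, nrow(aatable))
  len <- rowSums(counts)
  if (any(len < 1)) stop("composition with zero length at row ",
                         which(len < 1)[1])
  elem <- counts %*% res[, c("C", "H", "N", "O", "S")]
  if (terminal_water) {
    elem[, "H"] <- elem[, "H"] + 2 * chains
    elem[, "O"] <- elem[, "O"] + chains
  }
  Zc <- (-elem[, "H"] + 3 * elem[, "N"] + 2 * elem[, "O"] + 2 * elem[, "S"]) /
    elem[, "C"]
  bmat <- cbind(elem, Z = 0)[, cols, drop = FALSE] %*% t(Ainv)  # n x species
  colnames(bmat) <- basis$species
  nH2O <- bmat[, "H2O"] / len
  nO2 <- bmat[, "O2"] / len
  data.frame(id = aatable$id,
             organism = if ("organism" %in% names(aatable)) aatable$organism else NA,
             length = len, Zc = unname(Zc), nH2O = unname(nH2O),
             nO2 = unname(nO2), stringsAsFactors = FALSE)
}

#' Compare bases by correlation of projected metrics with ZC
#'
#' For each basis, reports the correlation across proteins of the per-residue
#' oxygen demand and water demand with the (basis-independent) average
#' oxidation state of carbon. Under the QEC basis `nO2` is strongly
#' positively correlated with ZC while `nH2O` is only weakly related; an
#' inorganic basis couples both metrics to ZC, which is the motivation for
#' QEC.
#'
#' @param aatable Composition table with at least 3 proteins.
#' @param bases List of `basis_set` objects (or preset names).
#' @param method Correlation method passed to [stats::cor()].
#' @return Data frame with columns `basis, cor_nO2_Zc, cor_nH2O_Zc`;
#'   correlations are `NA` when a metric is degenerate (constant).
#' @export
basis_correlation_report <- function(aatable,
                                     bases = list("QEC", "inorganic"),
                                     method = "pearson") {
  if (nrow(aatable) < 3) stop("need at least 3 proteins")
  rows <- lapply(bases, function(b) {
    if (is.character(b)) b <- basis_set(b)
    met <- compute_metrics(aatable, basis = b)
    safe_cor <- function(x, y) {
      if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14) return(NA_real_)
      stats::cor(x, y, method = method)
    }
    data.frame(basis = b$name,
               cor_nO2_Zc = safe_cor(met$nO2, met$Zc),
               cor_nH2O_Zc = safe_cor(met$nH2O, met$Zc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
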