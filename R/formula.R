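# Elemental formulas over C, H, N, O, S plus formal charge.
# Counts may be fractional so that averaged (mean-proteome) formulas are
# first-class citizens everywhere.

.ELEMENTS <- c("C", "H", "N", "O", "S", "Z")

# IUPAC conventional atomic weights (g/mol)
.ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

#' Create an elemental formula
#'
#' An `elemental_formula` is a named numeric vector of element counts
#' (C, H, N, O, S) plus a formal charge `Z`. Counts may be non-integer, which
#' supports averaged formulas such as the mean protein of a proteome.
#'
#' @param C,H,N,O,S Element counts (non-negative, finite).
#' @param Z Formal charge (may be negative).
#' @return An object of class `elemental_formula`.
#' @examples
#' glutamine <- elemental_formula(C = 5, H = 10, N = 2, O = 3)
#' zc(glutamine)  # 0.4
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, S = 0, Z = 0) {
  x <- c(C = unname(C), H = unname(H), N = unname(N), O = unname(O),
         S = unname(S), Z = unname(Z))
  if (!all(is.finite(x))) stop("elemental formula entries must be finite")
  if (any(x[c("C", "H", "N", "O", "S")] < -1e-9))
    stop("element counts must be non-negative")
  structure(x, class = "elemental_formula")
}

.as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_formula(x))
  if (is.numeric(x)) {
    v <- setNames(numeric(6), .ELEMENTS)
    nm <- names(x)
    if (is.null(nm) || !all(nm %in% .ELEMENTS))
      stop("numeric formula must be named with elements C,H,N,O,S,Z")
    v[nm] <- x
    return(do.call(elemental_formula, as.list(v)))
  }
  stop("cannot interpret object as an elemental formula")
}

#' Parse a chemical formula string
#'
#' Understands formulas over C, H, N, O and S with optional (possibly
#' fractional) counts and an optional trailing charge written as `+2`, `-1`,
#' `+` or `-`, e.g. `"C5H10N2O3"`, `"C2H4NO2-1"`, `"H+"`.
#'
#' @param x A single formula string.
#' @return An `elemental_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s", "", x)
  charge <- 0
  m <- regmatches(s, regexpr("[+-][0-9]*$", s))
  if (length(m) == 1L && nzchar(m)) {
    sign <- if (substr(m, 1, 1) == "+") 1 else -1
    num <- substring(m, 2)
    charge <- sign * (if (nzchar(num)) as.numeric(num) else 1)
    s <- substr(s, 1, nchar(s) - nchar(m))
  }
  counts <- setNames(numeric(5), c("C", "H", "N", "O", "S"))
  pat <- "([CHNOS])([0-9]*\\.?[0-9]*)"
  pos <- gregexpr(pat, s)[[1]]
  if (pos[1] == -1 || sum(attr(pos, "match.length")) != nchar(s))
    stop("cannot parse formula: ", x)
  for (tok in regmatches(s, gregexpr(pat, s))[[1]]) {
    el <- substr(tok, 1, 1)
    num <- substring(tok, 2)
    counts[el] <- counts[el] + (if (nzchar(num)) as.numeric(num) else 1)
  }
  elemental_formula(C = counts["C"], H = counts["H"], N = counts["N"],
                    O = counts["O"], S = counts["S"], Z = charge)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Format an elemental formula as a string
#' @param x An `elemental_formula`.
#' @return A single character string such as `"C5H10N2O3"`.
#' @export
format_formula <- function(x) {
  x <- .as_formula(x)
  parts <- character(0)
  for (el in c("C", "H", "N", "O", "S")) {
    v <- unname(x[el])
    if (abs(v) > 1e-12) {
      num <- if (abs(v - 1) < 1e-12) "" else format(v, digits = 10)
      parts <- c(parts, paste0(el, num))
    }
  }
  z <- unname(x["Z"])
  zs <- if (abs(z) > 1e-12) sprintf("%+g", z) else ""
  paste0(paste(parts, collapse = ""), zs)
}

#' @export
Ops.elemental_formula <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    a <- unclass(.as_formula(e1)); b <- unclass(.as_formula(e2))
    out <- get(.Generic)(a, b)
  } else if (.Generic == "*") {
    if (inherits(e1, "elemental_formula")) {
      out <- unclass(e1) * as.numeric(e2)
    } else out <- as.numeric(e1) * unclass(e2)
  } else stop("operation ", .Generic, " not defined for elemental formulas")
  structure(out, class = "elemental_formula")
}

#' Average oxidation state of carbon
#'
#' For a formula \eqn{C_c H_h N_n O_o S_s^z} the average oxidation state of
#' carbon is \eqn{Z_C = (-h + 3n + 2o + 2s + z)/c}. Ionization (adding k to
#' both H count and charge) leaves the value unchanged, so proteins are
#' conventionally evaluated in their fully non-ionized form.
#'
#' @param x An `elemental_formula`, formula string, or named numeric vector.
#' @return The average oxidation state of carbon (dimensionless).
#' @examples
#' zc("C5H10N2O3")   # glutamine, 0.4
#' zc("C3H7NO2S")    # cysteine, 2/3
#' @export
zc <- function(x) {
  f <- .as_formula(x)
  if (unname(f["C"]) <= 0) stop("ZC requires a formula with carbon (c > 0)")
  unname((-f["H"] + 3 * f["N"] + 2 * f["O"] + 2 * f["S"] + f["Z"]) / f["C"])
}

#' Molar mass of a formula
#' @param x An `elemental_formula` or formula string.
#' @return Molar mass in g/mol (charge ignored; electron mass neglected).
#' @export
molar_mass <- function(x) {
  f <- .as_formula(x)
  sum(unclass(f)[names(.ATOMIC_WEIGHTS)] * .ATOMIC_WEIGHTS)
}

#' Moles of carbon per gram
#'
#' An intensive quantity: scaling the formula by any factor leaves it
#' unchanged. Used by the lipid-protein redox balance.
#'
#' @param x An `elemental_formula` or formula string.
#' @return mol C per gram of substance.
#' @export
carbon_per_gram <- function(x) {
  f <- .as_formula(x)
  m <- molar_mass(f)
  if (m <= 0) stop("formula has zero mass")
  unname(f["C"]) / m
}
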