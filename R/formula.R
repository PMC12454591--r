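# Elemental formula arithmetic and monoisotopic mass computation.
#
# All masses are monoisotopic (most abundant isotope), in Da. Ion m/z values
# use the electron-corrected proton mass, singly protonated positive mode.

# Monoisotopic masses of the most abundant isotope (CODATA/IUPAC).
.element_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Se = 79.9165213
)

# Electron-corrected proton mass (Da); used only by ion m/z operations.
.proton_mass <- 1.00727646688

.new_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    syms <- names(counts)
    # Hill order: C, then H (when C present), then alphabetical
    if ("C" %in% syms) {
      rest <- sort(setdiff(syms, c("C", "H")))
      ord <- c("C", intersect("H", syms), rest)
    } else {
      ord <- sort(syms)
    }
    counts <- counts[ord]
  }
  structure(as.integer(counts), names = names(counts),
            class = "elemental_formula")
}

#' Parse an elemental formula in Hill notation
#'
#' @param text A single string such as `"C5H5N5O"`. Element symbols must be
#'   known (C, H, N, O, S, P, Cl, F, Br, I, Na, K, Se); a missing count means 1.
#' @return An `elemental_formula`: a named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' monoisotopic_mass(parse_formula("C5H8O3"))  # deoxyribose neutral loss
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text))
    stop("malformed formula: '", text, "'")
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(cnts == "", "1", cnts)
  cnts <- suppressWarnings(as.integer(cnts))
  if (anyNA(cnts)) stop("malformed count in formula: '", text, "'")
  unknown <- setdiff(syms, names(.element_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- vapply(split(cnts, syms), sum, integer(1))
  .new_formula(counts)
}

#' Format an elemental formula in Hill notation
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(f))` equals `f`.
#'
#' @param f An `elemental_formula`.
#' @return A single string; the empty formula formats as `""`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  if (!length(f)) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (",
      sprintf("%.4f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

.as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) x else parse_formula(x)
}

#' Add or subtract elemental formulas
#'
#' Element-wise composition arithmetic. Subtraction that would drive any
#' element count negative is an error (impossible chemistry).
#'
#' @param a,b `elemental_formula` objects or formula strings.
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  counts <- vapply(syms, function(s) {
    sum(a[s], b[s], na.rm = TRUE)
  }, numeric(1))
  .new_formula(counts)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  syms <- union(names(a), names(b))
  counts <- vapply(syms, function(s) {
    av <- if (s %in% names(a)) a[[s]] else 0L
    bv <- if (s %in% names(b)) b[[s]] else 0L
    av - bv
  }, numeric(1))
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop("subtraction yields negative count for element(s): ",
         paste(bad, collapse = ", "))
  }
  .new_formula(counts)
}

#' @export
`+.elemental_formula` <- function(e1, e2) formula_add(e1, e2)

#' @export
`-.elemental_formula` <- function(e1, e2) formula_subtract(e1, e2)

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(format_formula(.as_formula(e1)), format_formula(.as_formula(e2)))
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-element counts times the mass of the most abundant isotope.
#'
#' @param f An `elemental_formula` or formula string.
#' @return Mass in Da; `0` for the empty formula.
#' @examples
#' monoisotopic_mass("C5H8O3")  # 116.0473, the deoxyribose neutral loss
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0)
  sum(unclass(f) * .element_masses[names(f)])
}

#' m/z of the singly protonated ion [M+H]+
#'
#' @param f An `elemental_formula` or formula string of the neutral molecule.
#' @return m/z in Da: monoisotopic mass plus the electron-corrected proton
#'   mass (1.00727646688 Da). Rounding is left to presentation.
#' @examples
#' protonated_mz("C5H5N5O")  # guanine, 152.0567
#' @export
protonated_mz <- function(f) {
  monoisotopic_mass(f) + .proton_mass
}

#' Relative mass error in parts per million
#'
#' @param observed,expected m/z or mass values in Da.
#' @return Signed ppm error `(observed - expected) / expected * 1e6`.
#' @export
ppm_error <- function(observed, expected) {
  (observed - expected) / expected * 1e6
}
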