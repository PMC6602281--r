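# Monoisotopic mass tables and molecular-formula arithmetic.
# Every downstream m/z in the package flows through these few functions,
# so the element table is the single source of truth.

# IUPAC/CODATA monoisotopic masses, Da
.ELEMENT_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.99491461956,
  S = 31.97207100
)

#' Mass constants used throughout the package
#'
#' Monoisotopic element masses (Da) for C, H, N, O, S, together with the
#' proton, water and ammonia masses. All mass arithmetic in the package is
#' monoisotopic; average masses are deliberately not supported.
#'
#' @return Named list with elements `elements` (named numeric vector),
#'   `proton`, `water`, `ammonia` (Da).
#' @examples
#' mass_constants()$proton
#' @export
mass_constants <- function() {
  list(
    elements = .ELEMENT_MASS,
    proton  = 1.00727646688,
    water   = 2 * .ELEMENT_MASS[["H"]] + .ELEMENT_MASS[["O"]],
    ammonia = .ELEMENT_MASS[["N"]] + 3 * .ELEMENT_MASS[["H"]]
  )
}

.new_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    counts <- counts[order(names(counts))]
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = "molecular_formula")
}

#' Parse a molecular formula string
#'
#' Accepts formulas written as element symbols each followed by an optional
#' positive count, e.g. `"C24H43N7O8"` or `"H2O"`. Only elements present in
#' the package mass table (C, H, N, O, S) are allowed. The empty string is
#' the empty (zero-mass) formula.
#'
#' @param text Formula string.
#' @return A `molecular_formula`: a named integer vector of element counts.
#' @examples
#' parse_formula("C24H43N7O8")
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(.new_formula(integer(0)))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed formula string: ", sQuote(text), call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  els <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  unknown <- setdiff(els, names(.ELEMENT_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(cnt < 1L)) stop("element counts must be positive", call. = FALSE)
  counts <- tapply(cnt, els, sum)
  .new_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' @export
format.molecular_formula <- function(x, ...) {
  if (!length(x)) return("")
  els <- names(x)
  # Hill order: C then H then the rest alphabetically (when C is present)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  n <- unclass(x)[ord]
  paste0(ord, ifelse(n == 1L, "", n), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular formula> ", format(x),
      sprintf("  (%.5f Da)\n", monoisotopic_mass(x)), sep = "")
  invisible(x)
}

#' @export
as.character.molecular_formula <- function(x, ...) format(x)

#' Add and subtract molecular formulas
#'
#' Formula arithmetic is element-wise; subtraction that would drive any
#' element count negative is an error (there is no such molecule).
#'
#' @param e1,e2 `molecular_formula` objects (or formula strings).
#' @return A `molecular_formula`.
#' @examples
#' parse_formula("C6H12N2O") + parse_formula("O")   # Lys -> Hyl residue
#' @export
Ops.molecular_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==", "!=")) {
    stop("operation ", sQuote(.Generic), " not defined for formulas",
         call. = FALSE)
  }
  f1 <- if (is.character(e1)) parse_formula(e1) else e1
  f2 <- if (is.character(e2)) parse_formula(e2) else e2
  els <- union(names(f1), names(f2))
  a <- stats::setNames(integer(length(els)), els)
  b <- a
  a[names(f1)] <- unclass(f1)
  b[names(f2)] <- unclass(f2)
  if (.Generic == "==") return(all(a == b))
  if (.Generic == "!=") return(!all(a == b))
  out <- if (.Generic == "+") a + b else a - b
  if (any(out < 0L)) {
    stop("formula subtraction yields negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "), call. = FALSE)
  }
  .new_formula(out)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param f A `molecular_formula` or a formula string.
#' @return Mass in Da (numeric scalar).
#' @examples
#' monoisotopic_mass("C12H25N3O4")  # reduced LNL free cross-link
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molecular_formula"))
  if (!length(f)) return(0)
  sum(.ELEMENT_MASS[names(f)] * unclass(f))
}

#' m/z of a protonated ion
#'
#' The package models protonation only (\[M+zH\]z+), the adduct convention
#' of positive-mode peptide and cross-link analysis.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z (numeric).
#' @examples
#' mz(monoisotopic_mass("C12H25N3O4"), 1)  # 276.19
#' @export
mz <- function(mass, charge = 1L) {
  stopifnot(is.numeric(mass), is.numeric(charge))
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (mass + charge * mass_constants()$proton) / charge
}

#' Round half away from zero at a fixed number of decimals
#'
#' Printed m/z and percentage tables in this field round half-up
#' (558.3246 prints as 558.32, 0.125 as 0.13), unlike [round()]'s
#' round-half-even. Used wherever package output is compared with printed
#' values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
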