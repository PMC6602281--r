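# Residue table: the 20 standard amino-acid residues (chain form, no water)
# plus the collagen-specific states: 4-hydroxyproline, hydroxylysine and its
# two O-glycoforms, the lysyl-oxidase aldehydes, and pyroglutamate.

.pkg_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "collagenQ")
  if (!nzchar(path)) {
    # devtools::load_all() / source-tree fallback
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("resource not found: ", file, call. = FALSE)
  path
}

#' Residue mass table
#'
#' Reads the shipped residue resource (code, name, formula) and returns it
#' with parsed formulas and monoisotopic residue masses. The table contains
#' the 20 standard residues plus `Hyp`, `Hyl`, `G-Hyl`, `GG-Hyl`, `Lys-ald`
#' (allysine), `Hyl-ald` (hydroxyallysine) and `pyro-Glu`. Users may pass
#' their own CSV with the same columns to extend it.
#'
#' @param path Optional path to a user residue CSV (columns
#'   `code,name,formula`).
#' @return A data.frame with columns `code`, `name`, `formula` (string) and
#'   `mass` (Da), one row per residue code.
#' @examples
#' rt <- residue_table()
#' rt[rt$code %in% c("K", "Hyl", "GG-Hyl"), ]
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.pkg_cache$residues)) return(.pkg_cache$residues)
  file <- if (is.null(path)) .extdata("residues.csv") else path
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "name", "formula") %in% names(tab)))
  if (anyDuplicated(tab$code)) stop("duplicate residue codes", call. = FALSE)
  tab$mass <- vapply(tab$formula, function(f) monoisotopic_mass(parse_formula(f)),
                     numeric(1), USE.NAMES = FALSE)
  if (is.null(path)) .pkg_cache$residues <- tab
  tab
}

.residue_formula <- function(code, table = residue_table()) {
  i <- match(code, table$code)
  if (anyNA(i)) {
    stop("unknown residue code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  lapply(table$formula[i], parse_formula)
}

.residue_mass <- function(code, table = residue_table()) {
  i <- match(code, table$code)
  if (anyNA(i)) {
    stop("unknown residue code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  table$mass[i]
}

# Free amino-acid form (residue + water); used for cross-link assembly.
.free_acid_formula <- function(code, table = residue_table()) {
  alias <- c(Lys = "K", His = "H", Gly = "G")
  code <- ifelse(code %in% names(alias), alias[code], code)
  lapply(.residue_formula(code, table), function(f) f + parse_formula("H2O"))
}
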