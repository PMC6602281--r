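# Marker-peptide site definitions and modification-variant enumeration.
#
# A "site" is one cross-linking / glycosylation lysine of type I collagen,
# carried by a marker peptide. Helical sites admit {Lys, Hyl, G-Hyl, GG-Hyl};
# telopeptidyl sites admit {Lys, Lys-ald, Hyl}. Two-lysine peptides (the
# helical cross-linking site pair) enumerate joint classes; positional
# isomers of equal mass collapse into a single occupancy class, because EIC
# areas cannot tell them apart.

.STATE_ORDER <- c("Lys", "Lys-ald", "Hyl", "G-Hyl", "GG-Hyl")
.STATE_RESIDUE <- c("Lys" = "K", "Lys-ald" = "Lys-ald", "Hyl" = "Hyl",
                    "G-Hyl" = "G-Hyl", "GG-Hyl" = "GG-Hyl")

.split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Marker-peptide site definitions
#'
#' Reads the shipped site resource. Each row defines one modifiable lysine
#' site: collagen chain, site label (helical residue number, or N/C-suffixed
#' telopeptide position), marker peptide sequence, whether the peptide starts
#' with pyroglutamate, the 1-based positions of the modifiable lysines, the
#' allowed modification states at those positions, and the positions of
#' prolines fixed as 4-hydroxyproline. The `sequence_source` column flags
#' which sequences are literature-printed and which are representative
#' collagen-like stand-ins used by the synthetic generator.
#'
#' @param path Optional path to a user site CSV with the same columns.
#' @return A data.frame, one row per site.
#' @examples
#' site_table()[, c("chain", "label", "sequence")]
#' @export
site_table <- function(path = NULL) {
  file <- if (is.null(path)) .extdata("sites.csv") else path
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Fetch one site definition
#'
#' @param label Site label, e.g. `"Lys-87"`.
#' @param chain Collagen chain, e.g. `"alpha1(I)"`; required when the label
#'   occurs on more than one chain.
#' @param sites Site table, default [site_table()].
#' @return A list of class `site_definition` with parsed fields.
#' @examples
#' site_definition("Lys-87", "alpha1(I)")
#' @export
site_definition <- function(label, chain = NULL, sites = site_table()) {
  hit <- sites$label == label & (is.null(chain) | sites$chain == chain)
  if (sum(hit) == 0L) stop("no such site: ", label, call. = FALSE)
  if (sum(hit) > 1L) stop("site label ", sQuote(label),
                          " is ambiguous; give `chain`", call. = FALSE)
  row <- sites[hit, , drop = FALSE]
  pos <- as.integer(.split_field(as.character(row$mod_positions)))
  states <- .split_field(row$allowed_states)
  bad <- setdiff(states, .STATE_ORDER)
  if (length(bad)) stop("unknown modification state(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  seq_chars <- strsplit(row$sequence, "")[[1]]
  if (any(seq_chars[pos] != "K")) {
    stop("modifiable positions must carry Lys in the base sequence",
         call. = FALSE)
  }
  structure(list(
    chain = row$chain,
    label = row$label,
    sequence = row$sequence,
    pyro_glu = isTRUE(as.logical(row$pyro_glu)),
    mod_positions = pos,
    allowed_states = states,
    hyp_positions = as.integer(.split_field(as.character(row$hyp_positions))),
    sequence_source = row$sequence_source
  ), class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("<site> ", x$chain, " ", x$label, "  ", x$sequence,
      if (x$pyro_glu) " (pyro-Glu)", "\n",
      "  modifiable position(s): ", paste(x$mod_positions, collapse = ", "),
      "; states: ", paste(x$allowed_states, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a (modified) marker peptide
#'
#' Mass = sum of residue masses + water, minus ammonia when the N-terminal
#' glutamine is cyclised to pyroglutamate. Modifiable lysines are replaced by
#' the residue form of the given states; fixed hydroxyproline positions are
#' replaced by `Hyp`.
#'
#' @param site A `site_definition`.
#' @param states Character vector of modification states, one per modifiable
#'   position (subset of the site's allowed states).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' s <- site_definition("Lys-87", "alpha1(I)")
#' peptide_mass(s, "Hyl") - peptide_mass(s, "Lys")  # +15.99491
#' @export
peptide_mass <- function(site, states) {
  stopifnot(inherits(site, "site_definition"))
  if (length(states) != length(site$mod_positions)) {
    stop("need one state per modifiable position", call. = FALSE)
  }
  bad <- setdiff(states, site$allowed_states)
  if (length(bad)) {
    stop("state not allowed at this site: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  codes <- strsplit(site$sequence, "")[[1]]
  if (length(site$hyp_positions)) codes[site$hyp_positions] <- "Hyp"
  codes[site$mod_positions] <- .STATE_RESIDUE[states]
  if (site$pyro_glu) codes[1] <- "pyro-Glu"
  mc <- mass_constants()
  sum(.residue_mass(codes)) + mc$water
}

#' Enumerate mass-distinct occupancy classes of a site
#'
#' Forms every combination of allowed states over the site's modifiable
#' positions, computes each neutral mass, and collapses combinations that
#' are permutations of one another (isobaric positional isomers) into one
#' occupancy class. Classes are returned in order of increasing mass. The
#' aldehyde state keeps its own mass-level class but reports into the `Lys`
#' occupancy class (`report_label`), matching how telopeptidyl aldehydes are
#' tallied.
#'
#' @param site A `site_definition`.
#' @return A data.frame with columns `class` (label such as `"Hyl"` or
#'   `"Lys + Hyl"`), `report_label`, `neutral_mass` (Da), and `states`
#'   (list column of state vectors).
#' @examples
#' enumerate_variants(site_definition("Lys-918/930", "alpha1(I)"))
#' @export
enumerate_variants <- function(site) {
  stopifnot(inherits(site, "site_definition"))
  npos <- length(site$mod_positions)
  combos <- expand.grid(rep(list(site$allowed_states), npos),
                        stringsAsFactors = FALSE)
  # canonical multiset label, ordered by the field's naming convention
  lab <- apply(combos, 1L, function(s) {
    paste(s[order(match(s, .STATE_ORDER))], collapse = " + ")
  })
  keep <- !duplicated(lab)
  combos <- combos[keep, , drop = FALSE]
  lab <- lab[keep]
  mass <- vapply(seq_len(nrow(combos)),
                 function(i) peptide_mass(site, unlist(combos[i, ])),
                 numeric(1))
  # permutation-equivalent combos already collapsed by label; classes that
  # are isobaric *across* labels remain distinct queries and are flagged
  # downstream by build_eic_queries()
  report <- vapply(strsplit(lab, " \\+ "), function(s) {
    s[s == "Lys-ald"] <- "Lys"
    paste(s[order(match(s, .STATE_ORDER))], collapse = " + ")
  }, character(1))
  o <- order(mass)
  out <- data.frame(class = lab[o], report_label = report[o],
                    neutral_mass = mass[o], stringsAsFactors = FALSE)
  out$states <- lapply(seq_len(nrow(combos)), function(i) unlist(combos[o[i], ],
                                                                 use.names = FALSE))
  out
}

#' Build EIC queries for a site
#'
#' One query per (occupancy class, charge): the theoretical m/z of the
#' protonated class at that charge, with an absolute extraction tolerance
#' (default ±0.02 m/z). Queries whose windows would overlap at the same
#' charge (|Δm/z| < 2 × tolerance) are flagged `ambiguous`.
#'
#' @param site A `site_definition`.
#' @param charges Integer vector of charge states (default 2).
#' @param tolerance Absolute m/z half-window (default 0.02).
#' @return A data.frame with columns `site`, `chain`, `class`,
#'   `report_label`, `charge`, `mz`, `tolerance`, `ambiguous`.
#' @examples
#' build_eic_queries(site_definition("Lys-87", "alpha1(I)"), charges = 2)
#' @export
build_eic_queries <- function(site, charges = 2L, tolerance = 0.02) {
  stopifnot(tolerance > 0, all(charges >= 1))
  cls <- enumerate_variants(site)
  out <- do.call(rbind, lapply(charges, function(z) {
    data.frame(site = site$label, chain = site$chain, class = cls$class,
               report_label = cls$report_label, charge = as.integer(z),
               mz = mz(cls$neutral_mass, z), tolerance = tolerance,
               stringsAsFactors = FALSE)
  }))
  out$ambiguous <- FALSE
  for (z in unique(out$charge)) {
    i <- which(out$charge == z)
    d <- abs(outer(out$mz[i], out$mz[i], "-"))
    diag(d) <- Inf
    out$ambiguous[i] <- apply(d < 2 * tolerance, 1L, any)
  }
  rownames(out) <- NULL
  out
}
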