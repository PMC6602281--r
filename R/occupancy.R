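# Site occupancy, glycoform profiles, collagen typing and extractability.
#
# All of these are ratio quantities: EIC areas (or isotope-dilution amounts)
# normalised within a sample, so they are invariant to global intensity
# scale. Percentages sum to 100 exactly before any rounding.

#' Site occupancy from per-class EIC areas
#'
#' Fractional abundance of each occupancy class at one site in one sample:
#' `100 * area / sum(areas)`. Aldehyde-class areas are expected to be pooled
#' into the `Lys` class upstream (see [site_class_areas()]); any names of the
#' form `"Lys-ald"` passed here are pooled too.
#'
#' @param areas Named numeric vector of per-class areas (names are class
#'   labels such as `Lys`, `Hyl`, `G-Hyl`, `GG-Hyl`, or joint labels).
#' @return A named numeric vector of percentages summing to 100, of class
#'   `site_occupancy`. All-zero input is an error (`"site not detected"`).
#' @examples
#' site_occupancy(c(Lys = 0.2, Hyl = 1.8, "G-Hyl" = 3.5, "GG-Hyl" = 94.5) * 7)
#' @export
site_occupancy <- function(areas) {
  stopifnot(is.numeric(areas), !is.null(names(areas)))
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  nm <- names(areas)
  nm[nm == "Lys-ald"] <- "Lys"
  if (anyDuplicated(nm)) areas <- tapply(areas, nm, sum)[unique(nm)]
  else names(areas) <- nm
  tot <- sum(areas)
  if (tot == 0) stop("site not detected: all class areas are zero",
                     call. = FALSE)
  structure(100 * areas / tot, class = "site_occupancy")
}

#' Glycoform profile among hydroxylated forms
#'
#' Renormalises the three hydroxylated classes of a site occupancy
#' (`Hyl + G-Hyl + GG-Hyl = 100%`), discarding the unmodified `Lys` share.
#'
#' @param occupancy A `site_occupancy` (or named percentage vector)
#'   containing at least one of `Hyl`, `G-Hyl`, `GG-Hyl` with positive value.
#' @return Named numeric vector (`Hyl`, `G-Hyl`, `GG-Hyl` present in input)
#'   summing to 100, of class `glycoform_profile`.
#' @examples
#' glycoform_profile(c(Lys = 0.2, Hyl = 1.8, "G-Hyl" = 3.5, "GG-Hyl" = 94.5))
#' @export
glycoform_profile <- function(occupancy) {
  keep <- intersect(c("Hyl", "G-Hyl", "GG-Hyl"), names(occupancy))
  x <- unclass(occupancy)[keep]
  if (!length(x) || sum(x) <= 0) {
    stop("site is fully unmodified: no hydroxylated forms to profile",
         call. = FALSE)
  }
  structure(100 * x / sum(x), class = "glycoform_profile")
}

#' Collagen type ratio by stable-isotope dilution
#'
#' Each marker peptide contributes an absolute amount estimate
#' `light_area / heavy_area * standard_amount`; per-type amounts are the
#' mean over that type's markers, and the type percentages are taken over
#' types I + III. Markers with a missing or zero heavy channel are excluded
#' (it is an error if a type loses all its markers).
#'
#' @param markers A data.frame with columns `marker_id`, `collagen_type`
#'   (`"I"`/`"III"`), `light_area`, `heavy_area`, `standard_amount`.
#' @return A list of class `collagen_quant`: `per_marker` (data.frame with
#'   an `amount` column), `amounts` (named, per type), `percent` (named,
#'   summing to 100).
#' @export
collagen_type_ratio <- function(markers) {
  need <- c("marker_id", "collagen_type", "light_area", "heavy_area",
            "standard_amount")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("marker table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok <- is.finite(markers$heavy_area) & markers$heavy_area > 0
  excluded <- markers$marker_id[!ok]
  m <- markers[ok, , drop = FALSE]
  if (!nrow(m)) stop("all markers excluded: no usable heavy channel",
                     call. = FALSE)
  m$amount <- m$light_area / m$heavy_area * m$standard_amount
  amounts <- tapply(m$amount, m$collagen_type, mean)
  types <- names(amounts)
  if (!all(c("I", "III") %in% types)) {
    stop("need at least one usable marker per collagen type (I and III)",
         call. = FALSE)
  }
  pct <- 100 * amounts / sum(amounts)
  structure(list(per_marker = m, excluded = excluded,
                 amounts = amounts, percent = pct),
            class = "collagen_quant")
}

#' @export
print.collagen_quant <- function(x, ...) {
  cat("<collagen typing>\n")
  for (t in names(x$percent)) {
    cat(sprintf("  type %-4s %6.1f %%  (amount %.4g)\n",
                t, x$percent[[t]], x$amounts[[t]]))
  }
  invisible(x)
}

#' Collagen extractability fractions
#'
#' Percentage of total collagen recovered in each sequential-extraction
#' fraction (acid-soluble, pepsin-soluble, residual), from per-fraction
#' amounts measured by 4-hydroxyproline isotope dilution.
#'
#' @param amounts Named non-negative numeric vector of per-fraction amounts
#'   (any consistent unit); must sum to a positive value.
#' @return Named percentages summing to 100.
#' @examples
#' extractability(c(acid = 14.2, pepsin = 70.8, residual = 15.0))
#' @export
extractability <- function(amounts) {
  stopifnot(is.numeric(amounts))
  if (any(amounts < 0)) stop("fraction amounts must be non-negative",
                             call. = FALSE)
  tot <- sum(amounts)
  if (tot == 0) stop("all fraction amounts are zero", call. = FALSE)
  100 * amounts / tot
}

#' Collagen moles from a 4-hydroxyproline amount
#'
#' Converts moles of 4-Hyp measured in a hydrolysate into moles of collagen
#' triple-helical molecules using a fixed Hyp residue count per molecule.
#'
#' @param hyp_mol Moles of 4-Hyp.
#' @param hyp_per_molecule Hyp residues per collagen molecule (default 300).
#' @return Moles of collagen.
#' @export
collagen_moles <- function(hyp_mol, hyp_per_molecule = 300) {
  stopifnot(hyp_mol >= 0, hyp_per_molecule > 0)
  hyp_mol / hyp_per_molecule
}
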