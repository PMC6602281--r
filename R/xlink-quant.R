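# Cross-link quantification from radiolabelled cation-exchange HPLC traces.
#
# Reduced cross-links carry tritium from borohydride reduction; integrated
# counts in a species' elution window convert to moles via the label's
# specific activity, then to mol per mol collagen via the 4-Hyp-derived
# collagen amount. The tetrafunctional HHMD/d-HHMD carry two reduced bonds
# per molecule, so their counts are divided by the label count (default 2).

#' Elution window table for cross-link species
#'
#' Per-species elution windows (fraction units) for the acid- and
#' base-hydrolysis runs. Windows are method-specific; the shipped table is
#' the one used by the synthetic generator, and users supply their own for
#' real traces.
#'
#' @param path Optional path to a user window CSV
#'   (`mode,species,start,end`).
#' @return A data.frame, one row per (mode, species).
#' @export
crosslink_windows <- function(path = NULL) {
  file <- if (is.null(path)) .extdata("crosslink_windows.csv") else path
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Calibration for cross-link quantification
#'
#' @param specific_activity Counts per minute per mole of reduced bond.
#' @param efficiency Counting efficiency (default 1: counts already
#'   corrected).
#' @param collagen_mol Moles of collagen in the hydrolysate (e.g. from
#'   [collagen_moles()]).
#' @param labels_per_molecule Named integer vector of reduced (labelled)
#'   bonds per molecule; species not named default to 1.
#' @return A list of class `quant_calibration`.
#' @export
quant_calibration <- function(specific_activity, efficiency = 1,
                              collagen_mol,
                              labels_per_molecule = c(HHMD = 2, "d-HHMD" = 2)) {
  stopifnot(specific_activity > 0, efficiency > 0, collagen_mol > 0,
            all(labels_per_molecule >= 1))
  structure(list(specific_activity = specific_activity,
                 efficiency = efficiency, collagen_mol = collagen_mol,
                 labels_per_molecule = labels_per_molecule),
            class = "quant_calibration")
}

.labels_for <- function(cal, species) {
  lp <- cal$labels_per_molecule
  ifelse(species %in% names(lp), unname(lp[species]), 1)
}

#' Quantify cross-link levels from an HPLC trace
#'
#' Sums radioactivity counts within each species' elution window, converts
#' to moles (`counts / (specific_activity * efficiency * labels)`), and
#' normalises by the collagen amount to give mol per mol collagen.
#'
#' @param trace A data.frame with columns `fraction` (strictly increasing)
#'   and `cpm` (non-negative counts), plus optionally `mode`.
#' @param windows Window table for the trace's hydrolysis mode (columns
#'   `species`, `start`, `end`); windows must not overlap.
#' @param cal A `quant_calibration`.
#' @return A named numeric vector of levels (mol/mol collagen), one per
#'   window species, of class `crosslink_levels` with attribute `mode`.
#' @export
quantify_crosslinks <- function(trace, windows, cal) {
  stopifnot(inherits(cal, "quant_calibration"))
  need <- c("fraction", "cpm")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("trace lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(trace$cpm < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.unsorted(trace$fraction, strictly = TRUE)) {
    stop("fraction indices must be strictly increasing", call. = FALSE)
  }
  w <- windows[order(windows$start), , drop = FALSE]
  if (any(utils::head(w$end, -1) >= utils::tail(w$start, -1))) {
    stop("elution windows overlap", call. = FALSE)
  }
  lev <- vapply(seq_len(nrow(w)), function(i) {
    counts <- sum(trace$cpm[trace$fraction >= w$start[i] &
                            trace$fraction <= w$end[i]])
    moles <- counts / (cal$specific_activity * cal$efficiency *
                       .labels_for(cal, w$species[i]))
    moles / cal$collagen_mol
  }, numeric(1))
  structure(stats::setNames(lev, w$species), class = "crosslink_levels",
            mode = if ("mode" %in% names(trace)) trace$mode[1] else NA_character_)
}

#' Total aldehyde content from cross-link levels
#'
#' Sum of immature cross-links counting the tetrafunctional species twice:
#' `HLNL + LNL + 2*HHMD + 2*d-HHMD` (each tetrafunctional molecule consumes
#' two telopeptidyl aldehydes). Missing species count as zero.
#'
#' @param levels Named numeric vector of levels (mol/mol collagen).
#' @return Total aldehyde, mol per mol collagen.
#' @examples
#' total_aldehyde(c(HLNL = 0.53, LNL = 0, HHMD = 0.72, "d-HHMD" = 0))
#' @export
total_aldehyde <- function(levels) {
  g <- function(s) if (s %in% names(levels)) unname(levels[s]) else 0
  g("HLNL") + g("LNL") + 2 * g("HHMD") + 2 * g("d-HHMD")
}

#' Glycoform fractions of HLNL (base hydrolysis)
#'
#' Base hydrolysis preserves the O-glycosides, splitting HLNL into its
#' glucosylgalactosyl-, galactosyl- and non-glycosylated forms. Returns each
#' as a percentage of their sum (`GG-HLNL + G-HLNL + HLNL = 100%`).
#'
#' @param levels Named numeric vector containing `GG-HLNL`, `G-HLNL`,
#'   `HLNL` (the free form), e.g. a base-mode [quantify_crosslinks()] result.
#' @return Named percentages summing to 100.
#' @examples
#' hlnl_glyco_fractions(c("GG-HLNL" = 0.18, "G-HLNL" = 0.10, HLNL = 0.25))
#' @export
hlnl_glyco_fractions <- function(levels) {
  keep <- c("GG-HLNL", "G-HLNL", "HLNL")
  miss <- setdiff(keep, names(levels))
  if (length(miss)) stop("levels lack: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- unclass(levels)[keep]
  if (any(x < 0)) stop("levels must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all HLNL forms are zero", call. = FALSE)
  100 * x / sum(x)
}
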