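# Assembly of lysyl-oxidase-derived collagen cross-links.
#
# The immature reducible cross-links are condensation products of the
# telopeptidyl lysine aldehyde (allysine) with helical Lys/Hyl (bifunctional
# LNL/HLNL) or, via the aldol condensation product (ACP) of two allysines,
# with helical His and Lys/Hyl (tetrafunctional d-HHMD/HHMD). A species is
# specified by its component free amino acids, the number of condensation
# water losses, the number of H2 added on borohydride reduction, and an
# optional O-glycan on the Hyl component.

#' Cross-link assembly recipes
#'
#' Reads the shipped recipe resource (name, semicolon-separated component
#' free amino acids, water losses, reductions, glycan formula). Editable:
#' pass a CSV with the same columns to add species.
#'
#' @param path Optional path to a user recipe CSV.
#' @return A data.frame, one row per species.
#' @examples
#' crosslink_recipes()
#' @export
crosslink_recipes <- function(path = NULL) {
  file <- if (is.null(path)) .extdata("crosslink_recipes.csv") else path
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Assemble a cross-link species
#'
#' Builds the molecular formula of a cross-link from its recipe:
#' `formula = sum(component free amino acids) - n_water * H2O + n_h2 * H2
#' + glycan`. Built-in recipes: `LNL` (allysine + Lys), `HLNL`
#' (allysine + Hyl), `G-HLNL`/`GG-HLNL` (HLNL + hexose / dihexose), `HHMD`
#' (2 allysine + His + Hyl, two water losses), `d-HHMD` (Lys in place of
#' Hyl), `ACP` and the unreduced `dehydro-` precursors.
#'
#' @param name Recipe name, or `NULL` when `components` is given directly.
#' @param components Character vector of component free amino acids
#'   (`Lys`, `Hyl`, `His`, `Lys-ald`); overrides the recipe table.
#' @param n_water Number of condensation water losses.
#' @param n_h2 Number of H2 added by reduction (0 for dehydro species).
#' @param glycan Glycan formula string (e.g. `"C6H10O5"`), or `""`.
#' @param recipes Recipe table, default [crosslink_recipes()].
#' @return A list of class `crosslink_species` with fields `name`,
#'   `components`, `n_water`, `n_h2`, `glycan`, `formula`
#'   (`molecular_formula`), `neutral_mass` and `mz1` (\[M+H\]+).
#' @examples
#' assemble_crosslink("HHMD")    # C24H43N7O9, [M+H]+ 574.32
#' assemble_crosslink("d-HHMD")  # C24H43N7O8, [M+H]+ 558.32
#' @export
assemble_crosslink <- function(name = NULL, components = NULL, n_water = 0L,
                               n_h2 = 0L, glycan = "",
                               recipes = crosslink_recipes()) {
  if (!is.null(name) && is.null(components)) {
    i <- match(name, recipes$name)
    if (is.na(i)) stop("unknown cross-link recipe: ", sQuote(name),
                       call. = FALSE)
    components <- .split_field(recipes$components[i])
    n_water <- recipes$n_water[i]
    n_h2 <- recipes$n_h2[i]
    glycan <- if (is.na(recipes$glycan[i])) "" else recipes$glycan[i]
  }
  if (is.null(components) || !length(components)) {
    stop("a recipe name or a component list is required", call. = FALSE)
  }
  stopifnot(n_water >= 0, n_h2 >= 0)
  f <- Reduce(`+`, .free_acid_formula(components))
  for (k in seq_len(n_water)) f <- f - parse_formula("H2O")
  for (k in seq_len(n_h2)) f <- f + parse_formula("H2")
  if (nzchar(glycan)) f <- f + parse_formula(glycan)
  m <- monoisotopic_mass(f)
  structure(list(
    name = if (is.null(name)) format(f) else name,
    components = components, n_water = as.integer(n_water),
    n_h2 = as.integer(n_h2), glycan = glycan,
    formula = f, neutral_mass = m, mz1 = mz(m, 1L)
  ), class = "crosslink_species")
}

#' @export
print.crosslink_species <- function(x, ...) {
  cat(sprintf("<cross-link> %s  %s  M %.5f Da  [M+H]+ %.4f\n",
              x$name, format(x$formula), x$neutral_mass, x$mz1))
  invisible(x)
}

#' Theoretical m/z table for all recipe species
#'
#' @param charges Integer charge states (default 1:3).
#' @param recipes Recipe table.
#' @return A data.frame `name`, `formula`, `neutral_mass`, then one `mz_z<k>`
#'   column per charge.
#' @export
crosslink_mz_table <- function(charges = 1:3, recipes = crosslink_recipes()) {
  sp <- lapply(recipes$name, assemble_crosslink, recipes = recipes)
  out <- data.frame(
    name = recipes$name,
    formula = vapply(sp, function(s) format(s$formula), character(1)),
    neutral_mass = vapply(sp, `[[`, numeric(1), "neutral_mass"),
    stringsAsFactors = FALSE
  )
  for (z in charges) out[[paste0("mz_z", z)]] <- mz(out$neutral_mass, z)
  out
}

#' Enumerate MS/MS fragments of a cross-link species
#'
#' Generates singly protonated fragment candidates from (i) combined neutral
#' losses drawn with repetition from the loss grammar (default NH3, H2O,
#' HCOOH; at most `max_losses` combined), applied to the precursor, and (ii)
#' release of one intact component amino acid, yielding both the protonated
#' free amino acid (single H transfer to the charged fragment — this places
#' free His from HHMD/d-HHMD at m/z 156.08) and its complementary fragment.
#' Fragments are deduplicated by formula and sorted by m/z; every fragment
#' m/z is at most the precursor \[M+H\]+.
#'
#' @param species A `crosslink_species`.
#' @param losses Character vector of neutral-loss formulas.
#' @param max_losses Maximum number of combined neutral losses (default 3).
#' @return A data.frame `label`, `formula`, `mz` (z = 1).
#' @examples
#' fr <- enumerate_fragments(assemble_crosslink("HHMD"))
#' fr[abs(fr$mz - 156.08) < 0.02, ]
#' @export
enumerate_fragments <- function(species,
                                losses = c("NH3", "H2O", "HCOOH"),
                                max_losses = 3L) {
  stopifnot(inherits(species, "crosslink_species"))
  prec <- species$formula
  frags <- list(list(label = "precursor", formula = prec))
  # neutral-loss multisets of size 1..max_losses
  if (length(losses) && max_losses >= 1L) {
    for (n in seq_len(max_losses)) {
      idx <- expand.grid(rep(list(seq_along(losses)), n))
      idx <- idx[!duplicated(t(apply(idx, 1L, sort))), , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        sel <- sort(unlist(idx[r, ], use.names = FALSE))
        f <- prec
        ok <- TRUE
        for (j in sel) {
          f <- tryCatch(f - parse_formula(losses[j]), error = function(e) NULL)
          if (is.null(f)) { ok <- FALSE; break }
        }
        if (ok) {
          frags[[length(frags) + 1L]] <- list(
            label = paste0("-", paste(losses[sel], collapse = "-")),
            formula = f)
        }
      }
    }
  }
  # component-release cleavages
  for (comp in unique(species$components)) {
    cf <- .free_acid_formula(comp)[[1]]
    frags[[length(frags) + 1L]] <- list(label = paste0("released ", comp),
                                        formula = cf)
    rest <- tryCatch(prec - cf + parse_formula("H2O"),
                     error = function(e) NULL)
    if (!is.null(rest)) {
      frags[[length(frags) + 1L]] <- list(label = paste0("minus ", comp),
                                          formula = rest)
    }
  }
  key <- vapply(frags, function(f) format(f$formula), character(1))
  frags <- frags[!duplicated(key)]
  out <- data.frame(
    label = vapply(frags, `[[`, character(1), "label"),
    formula = vapply(frags, function(f) format(f$formula), character(1)),
    mz = vapply(frags, function(f) mz(monoisotopic_mass(f$formula), 1L),
                numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[out$mz <= species$mz1 + 1e-9, ]
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  out
}

#' Assign an observed precursor/fragment spectrum to a cross-link species
#'
#' A candidate matches when its \[M+H\]+ lies within `tolerance` of the
#' observed precursor m/z. Among precursor matches the species with the most
#' theoretical fragments within `tolerance` of observed fragment peaks wins;
#' an exact tie is reported `ambiguous`, and no precursor match is
#' `unassigned`.
#'
#' @param precursor_mz Observed precursor m/z (z = 1 convention).
#' @param fragment_mz Numeric vector of observed fragment m/z values.
#' @param candidates List of `crosslink_species`.
#' @param tolerance Absolute m/z tolerance (default 0.02, as for MS1).
#' @return A list of class `species_assignment`: `decision`
#'   (`assigned`/`ambiguous`/`unassigned`), `species` (name or `NA`),
#'   `n_matched`, and a `matches` data.frame for the winning candidate.
#' @examples
#' cands <- lapply(c("HHMD", "d-HHMD"), assemble_crosslink)
#' assign_species(558.32, c(159.12, 403.27, 156.08), cands)
#' @export
assign_species <- function(precursor_mz, fragment_mz, candidates,
                           tolerance = 0.02) {
  stopifnot(tolerance > 0)
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  hits <- Filter(function(s) abs(s$mz1 - precursor_mz) <= tolerance, candidates)
  if (!length(hits)) {
    return(structure(list(decision = "unassigned", species = NA_character_,
                          n_matched = 0L, matches = NULL),
                     class = "species_assignment"))
  }
  score_one <- function(s) {
    theo <- enumerate_fragments(s)
    m <- lapply(fragment_mz, function(fm) {
      d <- abs(theo$mz - fm)
      j <- which.min(d)
      if (d[j] <= tolerance) {
        data.frame(observed = fm, theoretical = theo$mz[j],
                   label = theo$label[j], delta = theo$mz[j] - fm)
      } else NULL
    })
    do.call(rbind, m)
  }
  matched <- lapply(hits, score_one)
  n <- vapply(matched, function(m) if (is.null(m)) 0L else nrow(m), integer(0L + 1L))
  best <- which(n == max(n))
  if (length(best) > 1L) {
    return(structure(list(
      decision = "ambiguous",
      species = vapply(hits[best], `[[`, character(1), "name"),
      n_matched = max(n), matches = NULL), class = "species_assignment"))
  }
  structure(list(decision = "assigned", species = hits[[best]]$name,
                 n_matched = n[best], matches = matched[[best]]),
            class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  cat("<assignment> ", x$decision,
      if (!all(is.na(x$species))) paste0(": ", paste(x$species, collapse = " / ")),
      sprintf("  (%d fragment match%s)\n", x$n_matched,
              if (x$n_matched == 1L) "" else "es"), sep = "")
  invisible(x)
}
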