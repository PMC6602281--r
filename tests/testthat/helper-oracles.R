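# Independent oracles for the mass-chemistry tests. These recompute masses
# from a locally defined element table with plain arithmetic (no package
# formula machinery), so a defect in the package's parser or arithmetic
# cannot hide in the expectation.

ORACLE_ELEMENTS <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                     O = 15.99491461956, S = 31.97207100)
ORACLE_PROTON <- 1.00727646688

# mass of a formula given as a named count vector
oracle_mass <- function(counts) {
  sum(ORACLE_ELEMENTS[names(counts)] * counts)
}

# brute-force fragment m/z enumeration on element-count vectors: all
# neutral-loss multisets up to `max_losses` over {NH3, H2O, HCOOH} that keep
# every element count non-negative, plus component release fragments
# (released free acid, and precursor minus component plus water)
oracle_fragment_mz <- function(precursor_counts, component_counts,
                               max_losses = 3) {
  full <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  pad <- function(x) { v <- full; v[names(x)] <- x; v }
  prec <- pad(precursor_counts)
  nh3 <- pad(c(N = 1, H = 3)); h2o <- pad(c(H = 2, O = 1))
  hcooh <- pad(c(C = 1, H = 2, O = 2))
  counts <- list(prec)
  for (n1 in 0:max_losses) for (n2 in 0:max_losses) for (n3 in 0:max_losses) {
    if (n1 + n2 + n3 > max_losses || n1 + n2 + n3 == 0) next
    f <- prec - n1 * nh3 - n2 * h2o - n3 * hcooh
    if (all(f >= 0)) counts[[length(counts) + 1]] <- f
  }
  for (cm in component_counts) {
    cmp <- pad(cm)
    counts[[length(counts) + 1]] <- cmp
    rest <- prec - cmp
    if (all(rest >= 0)) counts[[length(counts) + 1]] <- rest + h2o
  }
  mzs <- vapply(counts, function(f) sum(ORACLE_ELEMENTS * f[names(ORACLE_ELEMENTS)]),
                numeric(1)) + ORACLE_PROTON
  cap <- sum(ORACLE_ELEMENTS * prec[names(ORACLE_ELEMENTS)]) + ORACLE_PROTON
  sort(unique(round(mzs[mzs <= cap + 1e-9], 6)))
}

# free amino-acid compositions and monoisotopic masses used by the oracles
ORACLE_FREE_ACID_COUNTS <- list(
  Lys = c(C = 6, H = 14, N = 2, O = 2),
  Hyl = c(C = 6, H = 14, N = 2, O = 3),
  His = c(C = 6, H = 9, N = 3, O = 2),
  `Lys-ald` = c(C = 6, H = 11, N = 1, O = 3)
)
ORACLE_FREE_ACID <- vapply(ORACLE_FREE_ACID_COUNTS, oracle_mass, numeric(1))

# random molecular formula generator for round-trip property tests
random_formula_string <- function() {
  els <- sample(c("C", "H", "N", "O", "S"), sample(1:5, 1))
  paste0(els, sample(1:40, length(els), replace = TRUE), collapse = "")
}
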