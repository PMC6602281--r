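# Cross-link assembly, fragment enumeration, and spectrum assignment.

test_that("built-in recipes reproduce the reference formulas and m/z", {
  cases <- list(
    list(name = "LNL",    formula = "C12H25N3O4", mz2 = 276.19),
    list(name = "HLNL",   formula = "C12H25N3O5", mz2 = 292.19),
    list(name = "HHMD",   formula = "C24H43N7O9", mz2 = 574.32),
    list(name = "d-HHMD", formula = "C24H43N7O8", mz2 = 558.32)
  )
  for (cs in cases) {
    sp <- assemble_crosslink(cs$name)
    expect_equal(format(sp$formula), cs$formula, info = cs$name)
    expect_equal(round_half_up(sp$mz1, 2), cs$mz2, info = cs$name)
  }
  expect_error(assemble_crosslink("pyridinoline"), "unknown")
})

test_that("assembly conserves mass and hydroxyl deltas", {
  water <- oracle_mass(c(H = 2, O = 1))
  h2 <- oracle_mass(c(H = 2))
  lnl <- assemble_crosslink("LNL")
  expect_equal(lnl$neutral_mass,
               ORACLE_FREE_ACID[["Lys-ald"]] + ORACLE_FREE_ACID[["Lys"]] -
                 water + h2,
               tolerance = 1e-9)
  hhmd <- assemble_crosslink("HHMD")
  expect_equal(hhmd$neutral_mass,
               2 * ORACLE_FREE_ACID[["Lys-ald"]] + ORACLE_FREE_ACID[["His"]] +
                 ORACLE_FREE_ACID[["Hyl"]] - 2 * water + h2,
               tolerance = 1e-9)
  # Hyl -> Lys substitution removes exactly one oxygen
  expect_equal(assemble_crosslink("HLNL")$neutral_mass - lnl$neutral_mass,
               15.99491462, tolerance = 1e-8)
  expect_equal(hhmd$neutral_mass - assemble_crosslink("d-HHMD")$neutral_mass,
               15.99491462, tolerance = 1e-8)
  # glycoforms add hexose units
  expect_equal(assemble_crosslink("GG-HLNL")$neutral_mass -
                 assemble_crosslink("HLNL")$neutral_mass,
               324.1056468, tolerance = 1e-6)
  # dehydro precursor lacks the reduction H2
  expect_equal(lnl$neutral_mass -
                 assemble_crosslink("dehydro-LNL")$neutral_mass,
               h2, tolerance = 1e-9)
})

test_that("fragment enumeration equals the exhaustive-subset oracle", {
  for (nm in c("LNL", "HLNL", "HHMD", "d-HHMD")) {
    sp <- assemble_crosslink(nm)
    got <- sort(unique(round(enumerate_fragments(sp)$mz, 6)))
    want <- oracle_fragment_mz(unclass(sp$formula),
                               ORACLE_FREE_ACID_COUNTS[unique(sp$components)])
    expect_equal(got, want, tolerance = 1e-9, info = nm)
  }
})

test_that("fragments include released His at 156.08 and obey the precursor cap", {
  for (nm in c("HHMD", "d-HHMD")) {
    fr <- enumerate_fragments(assemble_crosslink(nm))
    expect_true(any(abs(fr$mz - 156.0768) < 0.001), info = nm)
    expect_true(all(fr$mz <= assemble_crosslink(nm)$mz1 + 1e-9), info = nm)
  }
  # zero allowed losses leaves just the precursor and release fragments
  sp <- assemble_crosslink("LNL")
  fr0 <- enumerate_fragments(sp, losses = character(0))
  expect_true(any(abs(fr0$mz - sp$mz1) < 1e-9))
})

test_that("species assignment distinguishes HHMD from d-HHMD", {
  cands <- lapply(c("HHMD", "d-HHMD"), assemble_crosslink)
  # reference spectrum of the deoxy species: precursor 558.32 with its
  # Lys-marker fragments
  a <- assign_species(558.32, c(159.12, 403.27, 156.08), cands)
  expect_equal(a$decision, "assigned")
  expect_equal(a$species, "d-HHMD")
  # far-off precursor
  expect_equal(assign_species(999.9, 156.08, cands)$decision, "unassigned")
  # constructed tie: identical candidates, equal support
  tie <- assign_species(558.32, 156.08,
                        lapply(c("d-HHMD", "d-HHMD"), assemble_crosslink))
  expect_equal(tie$decision, "ambiguous")
  expect_error(assign_species(558.32, 156.08, list()), "empty")
})
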