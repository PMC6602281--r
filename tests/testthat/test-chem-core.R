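# Molecular-formula parsing, arithmetic and m/z computation.

test_that("formula parsing matches hand-built counts and round-trips", {
  f <- parse_formula("C24H43N7O8")
  expect_equal(unclass(f)[c("C", "H", "N", "O")],
               c(C = 24L, H = 43L, N = 7L, O = 8L))
  expect_equal(format(parse_formula("H2O")), "H2O")
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  # empty formula is the identity
  expect_length(parse_formula(""), 0)
  expect_identical(monoisotopic_mass(parse_formula("")), 0)
  # repeated element symbols accumulate
  expect_true(parse_formula("CH3CH3") == parse_formula("C2H6"))
  # round-trip parse(format(f)) == f on random formulas
  set.seed(42)
  for (i in 1:25) {
    s <- random_formula_string()
    f <- parse_formula(s)
    expect_true(parse_formula(format(f)) == f)
  }
})

test_that("malformed and unknown-element formulas are rejected", {
  expect_error(parse_formula("Xx3"), "unknown element")
  expect_error(parse_formula("C2H5!"), "malformed")
  expect_error(parse_formula("c2h5"), "malformed")
})

test_that("mass is linear in counts and arithmetic is exact", {
  a <- parse_formula("C6H12N2O")
  b <- parse_formula("C5H7NO3")
  expect_equal(monoisotopic_mass(a + b),
               monoisotopic_mass(a) + monoisotopic_mass(b),
               tolerance = 1e-9)
  expect_true((a + b) - b == a)
  # commutativity/associativity
  cc <- parse_formula("SO2")
  expect_true((a + b) + cc == a + (b + cc))
  expect_true(a + b == b + a)
  # subtraction below zero is an error
  expect_error(parse_formula("H2O") - parse_formula("H3N"), "negative")
  # one O adds exactly 15.99491 Da
  expect_equal(monoisotopic_mass(a + parse_formula("O")) - monoisotopic_mass(a),
               15.99491461956, tolerance = 1e-9)
})

test_that("residue table reproduces reference residue masses and deltas", {
  rt <- residue_table()
  gly <- rt$mass[rt$code == "G"]
  expect_equal(gly, oracle_mass(c(C = 2, H = 3, N = 1, O = 1)),
               tolerance = 1e-9)
  expect_equal(gly, 57.02146, tolerance = 1e-5)
  m <- function(code) rt$mass[rt$code == code]
  # Hyl = Lys + O; glycoforms add hexose units; allysine = Lys - NH3 + O
  expect_equal(m("Hyl") - m("K"), 15.99491462, tolerance = 1e-8)
  expect_equal(m("G-Hyl") - m("Hyl"), 162.0528234, tolerance = 1e-6)
  expect_equal(m("GG-Hyl") - m("Hyl"), 324.1056468, tolerance = 1e-6)
  expect_equal(m("Lys-ald") - m("K"), -1.03163448, tolerance = 1e-8)
  expect_equal(m("pyro-Glu") - m("Q"), -17.02654910, tolerance = 1e-8)
  expect_equal(m("Hyp") - m("P"), 15.99491462, tolerance = 1e-8)
})

test_that("protonated m/z follows the [M+zH]z+ convention", {
  expect_equal(mz(275.1845, 1), 276.1918, tolerance = 1e-4)
  expect_equal(mz(0, 1), 1.00728, tolerance = 1e-5)
  expect_equal(mz(557.3173, 1), 558.3246, tolerance = 1e-4)
  m <- monoisotopic_mass("C12H25N3O4")
  expect_equal(m, 275.18451, tolerance = 1e-5)
  expect_equal(mz(m, 2), (m + 2 * ORACLE_PROTON) / 2, tolerance = 1e-9)
  expect_error(mz(100, 0), "positive integer")
})

test_that("round_half_up rounds halves away from zero at printed precision", {
  expect_equal(round_half_up(558.3246, 2), 558.32)
  expect_equal(round_half_up(292.18669, 2), 292.19)
  expect_equal(round_half_up(0.125, 2), 0.13)   # round() would give 0.12
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(94.689, 1), 94.7)
})
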