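# Cross-link quantification from HPLC traces, total aldehyde, glycoforms.

test_that("window counts convert to mol/mol with the label-count correction", {
  cal <- quant_calibration(specific_activity = 1e12, collagen_mol = 2e-9)
  lev <- c(HLNL = 0.53, LNL = 0, HHMD = 0.72, "d-HHMD" = 0)
  tr <- simulate_hplc_trace(lev, "acid", cal, seed = 3)
  w <- crosslink_windows()
  got <- quantify_crosslinks(tr, w[w$mode == "acid", ], cal)
  expect_equal(unclass(got)[names(lev)], lev, tolerance = 1e-9)
  # all-zero counts give all-zero levels
  tr0 <- tr; tr0$cpm <- 0
  expect_true(all(quantify_crosslinks(tr0, w[w$mode == "acid", ], cal) == 0))
  # doubling counts and collagen together leaves levels unchanged
  cal2 <- quant_calibration(1e12, collagen_mol = 4e-9)
  tr2 <- tr; tr2$cpm <- tr$cpm * 2
  expect_equal(unclass(quantify_crosslinks(tr2, w[w$mode == "acid", ], cal2)),
               unclass(got), tolerance = 1e-12)
  # the tetrafunctional species carry two labels: halving the correction
  # doubles the apparent level
  cal1 <- quant_calibration(1e12, collagen_mol = 2e-9,
                            labels_per_molecule = c(HHMD = 1, "d-HHMD" = 1))
  got1 <- quantify_crosslinks(tr, w[w$mode == "acid", ], cal1)
  expect_equal(got1[["HHMD"]], 2 * got[["HHMD"]], tolerance = 1e-9)
  expect_error(quantify_crosslinks(tr, data.frame(
    species = c("a", "b"), start = c(1, 3), end = c(5, 8)), cal), "overlap")
})

test_that("total aldehyde doubles the tetrafunctional cross-links", {
  expect_equal(total_aldehyde(c(HLNL = 0.53, LNL = 0, HHMD = 0.72,
                                "d-HHMD" = 0)), 1.97)
  expect_equal(total_aldehyde(c(HLNL = 0, LNL = 0, HHMD = 0, "d-HHMD" = 0)), 0)
  # linearity: mean of per-sample totals equals total of per-sample means
  set.seed(11)
  cohort <- replicate(8, abs(rnorm(4, c(0.5, 0.1, 0.7, 0.2), 0.05)))
  rownames(cohort) <- c("HLNL", "LNL", "HHMD", "d-HHMD")
  per_sample <- apply(cohort, 2, function(v) total_aldehyde(v))
  expect_equal(mean(per_sample), total_aldehyde(rowMeans(cohort)),
               tolerance = 1e-12)
})

test_that("HLNL glycoform fractions normalise to 100 and are scale-invariant", {
  fr <- hlnl_glyco_fractions(c("GG-HLNL" = 0.18, "G-HLNL" = 0.10,
                               HLNL = 0.25))
  expect_equal(unname(round_half_up(fr, 1)), c(34.0, 18.9, 47.2))
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_equal(unname(hlnl_glyco_fractions(c("GG-HLNL" = 0.3, "G-HLNL" = 0,
                                             HLNL = 0))), c(100, 0, 0))
  expect_equal(hlnl_glyco_fractions(c("GG-HLNL" = 0.18, "G-HLNL" = 0.10,
                                      HLNL = 0.25) * 5), fr)
  expect_error(hlnl_glyco_fractions(c("GG-HLNL" = 0, "G-HLNL" = 0, HLNL = 0)),
               "zero")
})

test_that("acid-mode total HLNL equals the base-mode glycoform sum", {
  cal <- quant_calibration(1e12, collagen_mol = 2e-9)
  base_lev <- c("GG-HLNL" = 0.18, "G-HLNL" = 0.10, HLNL = 0.25, HHMD = 0.72)
  acid_lev <- c(HLNL = sum(base_lev[c("GG-HLNL", "G-HLNL", "HLNL")]),
                LNL = 0, HHMD = 0.72, "d-HHMD" = 0)
  w <- crosslink_windows()
  qa <- quantify_crosslinks(simulate_hplc_trace(acid_lev, "acid", cal),
                            w[w$mode == "acid", ], cal)
  qb <- quantify_crosslinks(simulate_hplc_trace(base_lev, "base", cal),
                            w[w$mode == "base", ], cal)
  expect_equal(qa[["HLNL"]],
               sum(qb[c("GG-HLNL", "G-HLNL", "HLNL")]), tolerance = 1e-9)
  expect_equal(qa[["HHMD"]], qb[["HHMD"]], tolerance = 1e-9)
})
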