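# Site occupancy, glycoform renormalisation, collagen typing, extractability.

test_that("occupancy percentages are scale-invariant and sum to 100", {
  ref <- c(Lys = 0.2, Hyl = 1.8, "G-Hyl" = 3.5, "GG-Hyl" = 94.5)
  for (k in c(1, 0.37, 1e6)) {
    occ <- site_occupancy(ref * k)
    expect_equal(sum(occ), 100, tolerance = 1e-9)
    expect_equal(as.numeric(occ), unname(ref), tolerance = 1e-12)
  }
  expect_equal(as.numeric(site_occupancy(c(Lys = 0, Hyl = 0, "G-Hyl" = 0,
                                           "GG-Hyl" = 7))),
               c(0, 0, 0, 100))
  # property: random areas, sum always exactly 100
  set.seed(7)
  for (i in 1:20) {
    a <- setNames(runif(4), c("Lys", "Hyl", "G-Hyl", "GG-Hyl"))
    expect_equal(sum(site_occupancy(a)), 100, tolerance = 1e-9)
  }
  expect_error(site_occupancy(c(Lys = 0, Hyl = 0)), "not detected")
})

test_that("aldehyde areas pool into the Lys occupancy class", {
  occ <- site_occupancy(c(Lys = 30, "Lys-ald" = 20, Hyl = 50))
  expect_equal(as.numeric(occ[c("Lys", "Hyl")]), c(50, 50))
})

test_that("glycoform profile renormalises hydroxylated forms to 100", {
  # reference columns whose occupancy rows sum exactly to 100
  gp87 <- glycoform_profile(c(Lys = 0.2, Hyl = 1.8, "G-Hyl" = 3.5,
                              "GG-Hyl" = 94.5))
  expect_equal(round_half_up(gp87[["GG-Hyl"]], 1), 94.7)
  gp603 <- glycoform_profile(c(Lys = 13.9, Hyl = 84.7, "G-Hyl" = 0.9,
                               "GG-Hyl" = 0.5))
  expect_equal(round_half_up(gp603[["Hyl"]], 1), 98.4)
  expect_equal(sum(gp87), 100, tolerance = 1e-9)
  gp <- glycoform_profile(c(Lys = 50, Hyl = 50, "G-Hyl" = 0, "GG-Hyl" = 0))
  expect_equal(gp[["Hyl"]], 100)
  expect_error(glycoform_profile(c(Lys = 100, Hyl = 0, "G-Hyl" = 0,
                                   "GG-Hyl" = 0)), "unmodified")
})

test_that("collagen typing averages isotope-dilution marker estimates", {
  mk <- data.frame(marker_id = paste0("m", 1:4),
                   collagen_type = c("I", "I", "III", "III"),
                   light_area = c(1, 1, 1, 1), heavy_area = 1,
                   standard_amount = 1)
  q <- collagen_type_ratio(mk)
  expect_equal(unname(q$percent["III"]), 50)
  # set composition is recovered from proportional light areas
  mk$light_area <- c(85.8, 85.8, 14.2, 14.2)
  expect_equal(unname(collagen_type_ratio(mk)$percent["III"]), 14.2,
               tolerance = 1e-9)
  # an excluded marker (dead heavy channel) drops out of the mean
  mk2 <- mk
  mk2$light_area[2] <- 1e6
  mk2$heavy_area[2] <- 0
  q2 <- collagen_type_ratio(mk2)
  expect_equal(q2$excluded, "m2")
  expect_equal(unname(q2$percent["III"]), 14.2, tolerance = 1e-9)
  mk3 <- mk[mk$collagen_type == "I", ]
  expect_error(collagen_type_ratio(mk3), "per collagen type")
})

test_that("extractability fractions normalise and are scale-invariant", {
  x <- extractability(c(acid = 14.2, pepsin = 70.8, residual = 15.0))
  expect_equal(unname(x), c(14.2, 70.8, 15.0), tolerance = 1e-9)
  expect_equal(sum(x), 100)
  expect_equal(unname(extractability(c(0, 42, 0))), c(0, 100, 0))
  expect_equal(extractability(c(a = 1, b = 2, c = 3) * 17),
               extractability(c(a = 1, b = 2, c = 3)))
  expect_error(extractability(c(0, 0)), "zero")
})

test_that("collagen moles follow the Hyp-per-molecule convention", {
  expect_equal(collagen_moles(600e-9), 2e-9)
  expect_equal(collagen_moles(600e-9, hyp_per_molecule = 100), 6e-9)
})
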