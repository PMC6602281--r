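# Synthetic generators: determinism, ground-truth sidecars, degenerate cases.

test_that("generators are pure functions of their seed", {
  s <- site_definition("Lys-87", "alpha1(I)")
  c1 <- simulate_chromatogram(s, genotype = "KO", sample = 2, noise = TRUE,
                              seed = 99)
  c2 <- simulate_chromatogram(s, genotype = "KO", sample = 2, noise = TRUE,
                              seed = 99)
  expect_identical(c1, c2)
  c3 <- simulate_chromatogram(s, genotype = "KO", sample = 2, noise = TRUE,
                              seed = 100)
  expect_false(identical(c1$intensity, c3$intensity))

  cal <- quant_calibration(1e12, collagen_mol = 2e-9)
  t1 <- simulate_hplc_trace(c(HLNL = 0.5), "acid", cal, poisson = TRUE,
                            seed = 7)
  t2 <- simulate_hplc_trace(c(HLNL = 0.5), "acid", cal, poisson = TRUE,
                            seed = 7)
  expect_identical(t1, t2)

  f1 <- simulate_force_curves(1e4, n_curves = 2, rel_noise = 0.05, seed = 3)
  f2 <- simulate_force_curves(1e4, n_curves = 2, rel_noise = 0.05, seed = 3)
  expect_identical(f1, f2)
  # generators restore the caller RNG state
  set.seed(1); before <- .Random.seed
  invisible(simulate_force_curves(1e4, rel_noise = 0.05, seed = 12))
  expect_identical(.Random.seed, before)
})

test_that("ground truth travels with the fixture", {
  s <- site_definition("Lys-87", "alpha1(I)")
  occ <- c(Lys = 80.8, Hyl = 3.7, "G-Hyl" = 0.8, "GG-Hyl" = 14.7)
  ch <- simulate_chromatogram(s, occupancy = occ, noise = FALSE)
  expect_equal(attr(ch, "truth")$occupancy, occ)
  expect_equal(sum(attr(ch, "truth")$areas), 1e6, tolerance = 1e-9)
  cv <- simulate_force_curves(5e3, seed = 2)
  expect_equal(attr(cv, "truth")$E, 5e3)
})

test_that("degenerate requests yield empty outputs", {
  s <- site_definition("Lys-87", "alpha1(I)")
  ch <- simulate_chromatogram(s, occupancy = c(Lys = 0, Hyl = 0,
                                               "G-Hyl" = 0, "GG-Hyl" = 0),
                              noise = FALSE)
  expect_equal(nrow(ch), 0L)
  expect_length(simulate_force_curves(1e4, n_curves = 0), 0)
  cal <- quant_calibration(1e12, collagen_mol = 2e-9)
  tr <- simulate_hplc_trace(c(HLNL = 0.5, HHMD = 0), "acid", cal)
  w <- crosslink_windows(); w <- w[w$mode == "acid", ]
  inwin <- tr$fraction >= w$start[w$species == "HHMD"] &
    tr$fraction <= w$end[w$species == "HHMD"]
  expect_true(all(tr$cpm[inwin] == 0))
})

test_that("noiseless occupancy set-points survive the full EIC pipeline", {
  spec <- cohort_spec()
  for (g in c("WT", "KO")) {
    s <- site_definition("Lys-87", "alpha1(I)")
    ch <- simulate_chromatogram(s, spec = spec, genotype = g, noise = FALSE)
    a <- site_class_areas(ch, s)
    occ <- site_occupancy(setNames(a$area, a$report_label))
    want <- collagenQ:::.occupancy_setpoint(spec, s, g)
    expect_equal(as.numeric(occ), unname(want), tolerance = 1e-6)
  }
  # the two-lysine site with joint classes round-trips too
  s2 <- site_definition("Lys-918/930", "alpha1(I)")
  ch2 <- simulate_chromatogram(s2, spec = spec, genotype = "KO",
                               noise = FALSE)
  a2 <- site_class_areas(ch2, s2)
  occ2 <- site_occupancy(setNames(a2$area, a2$report_label))
  expect_equal(as.numeric(occ2), c(66.4, 26.6, 7.0), tolerance = 1e-6)
})

test_that("heavy internal-standard channel co-elutes and integrates", {
  s <- site_definition("Lys-87", "alpha1(I)")
  ch <- simulate_chromatogram(s, occupancy = c(Lys = 25, Hyl = 25,
                                               "G-Hyl" = 25, "GG-Hyl" = 25),
                              noise = FALSE, heavy_shift_da = 6.02013,
                              heavy_area = 4e5)
  a <- site_class_areas(ch, s, heavy_shift_da = 6.02013)
  # auto integration truncates identical tail fractions on every peak, so
  # areas agree to ~0.5% absolute and the light/heavy ratio is exact
  expect_equal(a$heavy_area, rep(1e5, 4), tolerance = 5e-3)
  expect_equal(a$area, rep(2.5e5, 4), tolerance = 5e-3)
  expect_equal(a$area / a$heavy_area, rep(2.5, 4), tolerance = 1e-9)
})
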