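# Seed-deterministic synthetic generators for every instrument stream the
# pipeline consumes: MS1 chromatograms of marker peptides, radiolabelled
# HPLC cross-link traces, and AFM force curves. Each generator attaches its
# ground truth as the `truth` attribute so recovery tests never re-derive
# truth from the fixture itself.

#' Default cohort set-points
#'
#' Reference per-genotype set-points shipped with the package: occupancy
#' vectors per site (murine skin type I collagen, WT/Het/KO), cross-link
#' levels in mol/mol collagen for acid- and base-hydrolysis runs, and
#' regional indentation moduli (kPa, mean and SE). These are the default
#' effect sizes of [cohort_spec()].
#'
#' @return A data.frame (long format for occupancy; wide per-genotype
#'   columns).
#' @export
default_occupancy <- function() {
  utils::read.csv(.extdata("default_occupancy.csv"), stringsAsFactors = FALSE)
}

#' @rdname default_occupancy
#' @export
default_crosslink_levels <- function() {
  utils::read.csv(.extdata("default_crosslink_levels.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname default_occupancy
#' @export
default_moduli <- function() {
  utils::read.csv(.extdata("default_moduli.csv"), stringsAsFactors = FALSE)
}

#' Collagen-type marker peptides
#'
#' Marker peptide resource for stable-isotope-dilution collagen typing (two
#' peptides per chain; sequences are representative stand-ins).
#'
#' @param path Optional user CSV.
#' @return A data.frame, one row per marker.
#' @export
collagen_markers <- function(path = NULL) {
  file <- if (is.null(path)) .extdata("collagen_markers.csv") else path
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Cohort specification for the synthetic generators
#'
#' Bundles genotype labels, per-genotype sample sizes (3 for MS occupancy
#' and AFM, 10 for cross-links, matching the study design the defaults
#' emulate), the set-point tables, and the noise model.
#'
#' @param genotypes Genotype labels.
#' @param n_ms,n_xlink,n_afm Samples per genotype for each assay.
#' @param occupancy,xlink_levels,moduli Set-point tables (defaults shipped).
#' @param noise List: `area_cv` multiplicative log-normal intensity CV,
#'   `mz_jitter` maximum absolute m/z jitter, `poisson_counts` logical,
#'   `force_rel` relative force noise SD.
#' @param seed Base RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(genotypes = c("WT", "Het", "KO"),
                        n_ms = 3L, n_xlink = 10L, n_afm = 3L,
                        occupancy = default_occupancy(),
                        xlink_levels = default_crosslink_levels(),
                        moduli = default_moduli(),
                        noise = list(area_cv = 0.05, mz_jitter = 0.005,
                                     poisson_counts = TRUE, force_rel = 0.05),
                        seed = 1L) {
  stopifnot(n_ms >= 1, n_xlink >= 1, n_afm >= 1)
  structure(list(genotypes = genotypes, n_ms = n_ms, n_xlink = n_xlink,
                 n_afm = n_afm, occupancy = occupancy,
                 xlink_levels = xlink_levels, moduli = moduli,
                 noise = noise, seed = seed),
            class = "cohort_spec")
}

.occupancy_setpoint <- function(spec, site, genotype) {
  occ <- spec$occupancy
  sel <- occ[occ$site == site$label & occ$chain == site$chain, , drop = FALSE]
  if (!nrow(sel)) stop("no occupancy set-point for site ", site$label,
                       call. = FALSE)
  stats::setNames(sel[[paste0(genotype, "_mean")]], sel$class)
}

.occupancy_sd <- function(spec, site, genotype) {
  occ <- spec$occupancy
  sel <- occ[occ$site == site$label & occ$chain == site$chain, , drop = FALSE]
  stats::setNames(sel[[paste0(genotype, "_sd")]], sel$class)
}

#' Draw a per-sample occupancy vector
#'
#' Truncated-normal draw per class around the set-point means with the
#' per-class SDs, renormalised to sum to 100. (A Dirichlet draw calibrated
#' to the same means is available via `method = "dirichlet"`.)
#'
#' @param mean Named percentage vector (sums to 100).
#' @param sd Named SD vector (same names).
#' @param method `"truncnorm"` (default) or `"dirichlet"`.
#' @return Named percentage vector summing to 100.
#' @export
draw_occupancy <- function(mean, sd, method = c("truncnorm", "dirichlet")) {
  method <- match.arg(method)
  if (method == "truncnorm") {
    x <- vapply(seq_along(mean), function(i) {
      .rtruncnorm_pos(1, mean[i], sd[i])
    }, numeric(1))
  } else {
    conc <- pmax(mean, 1e-3)  # concentration proportional to the mean
    g <- stats::rgamma(length(mean), shape = conc / 2, rate = 1)
    x <- g
  }
  if (sum(x) == 0) x <- mean
  stats::setNames(100 * x / sum(x), names(mean))
}

#' Simulate an MS1 chromatogram of one marker-peptide site
#'
#' Places one Gaussian elution peak per occupancy class at its theoretical
#' m/z (per queried charge), with peak areas proportional to the supplied
#' occupancy vector. Optional multiplicative log-normal area noise, m/z
#' jitter, and a co-eluting heavy internal-standard channel shifted by
#' `heavy_shift_da` on the neutral mass. Fully determined by `seed`.
#'
#' @param site A `site_definition`.
#' @param occupancy Named percentage vector over the site's class labels
#'   (defaults drawn from `spec` when `NULL`).
#' @param spec A `cohort_spec` (used for set-points/noise defaults).
#' @param genotype,sample Genotype label and sample index (select the
#'   set-point and decorrelate seeds).
#' @param charges Charge states simulated/queried (default 2).
#' @param total_area Total light-channel area across classes.
#' @param noise Enable the spec's noise model (default `FALSE`).
#' @param heavy_shift_da Neutral-mass shift of the heavy channel, or `NULL`
#'   for no internal standard.
#' @param heavy_area Total heavy-channel area (split evenly across classes).
#' @param rt_center,rt_sd,rt_step Elution geometry in seconds.
#' @param seed RNG seed (default derived from `spec$seed`, genotype, sample).
#' @return A `chromatogram` data.frame with attribute `truth` (the occupancy
#'   vector used, plus per-class areas).
#' @export
simulate_chromatogram <- function(site, occupancy = NULL,
                                  spec = cohort_spec(),
                                  genotype = "WT", sample = 1L,
                                  charges = 2L, total_area = 1e6,
                                  noise = FALSE, heavy_shift_da = NULL,
                                  heavy_area = total_area,
                                  rt_center = 300, rt_sd = 10, rt_step = 2,
                                  seed = NULL) {
  if (is.null(seed)) {
    seed <- (spec$seed * 1009L + match(genotype, spec$genotypes) * 101L +
               sample) %% .Machine$integer.max
  }
  with_seed(seed, {
    cls <- enumerate_variants(site)
    if (is.null(occupancy)) {
      mu <- .occupancy_setpoint(spec, site, genotype)
      if (noise) {
        occupancy <- draw_occupancy(mu, .occupancy_sd(spec, site, genotype))
      } else occupancy <- mu
    }
    miss <- setdiff(names(occupancy), cls$class)
    if (length(miss)) stop("occupancy classes not defined for site: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    rt <- seq(rt_center - 15 * rt_sd, rt_center + 15 * rt_sd +
                40 * (nrow(cls) - 1), by = rt_step)
    rows <- list()
    areas <- numeric(nrow(cls))
    for (i in seq_len(nrow(cls))) {
      frac <- if (cls$class[i] %in% names(occupancy)) {
        occupancy[[cls$class[i]]] / 100
      } else 0
      a <- total_area * frac
      if (noise && a > 0) {
        a <- a * stats::rlnorm(1, -spec$noise$area_cv^2 / 2, spec$noise$area_cv)
      }
      areas[i] <- a
      center <- rt_center + 40 * (i - 1)  # grid-aligned: 40 = 20 * rt_step
      shape <- stats::dnorm(rt, center, rt_sd)
      for (z in charges) {
        target <- mz(cls$neutral_mass[i], z)
        if (a > 0) {
          jit <- if (noise) stats::runif(length(rt), -spec$noise$mz_jitter,
                                         spec$noise$mz_jitter) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste0(genotype, "_", sample),
            rt_s = rt, mz = target + jit, intensity = a * shape)
        }
        if (!is.null(heavy_shift_da) && heavy_area > 0) {
          ha <- heavy_area / nrow(cls)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste0(genotype, "_", sample),
            rt_s = rt, mz = target + heavy_shift_da / z,
            intensity = ha * shape)
        }
      }
    }
    if (!length(rows)) {
      out <- data.frame(sample_id = character(0), rt_s = numeric(0),
                        mz = numeric(0), intensity = numeric(0))
    } else {
      out <- do.call(rbind, rows)
    }
    out <- as_chromatogram(out)
    attr(out, "truth") <- list(occupancy = occupancy,
                               areas = stats::setNames(areas, cls$class),
                               seed = seed)
    out
  })
}

#' Simulate light/heavy marker-peptide EIC data for collagen typing
#'
#' Generates one chromatogram carrying a light and a heavy (internal
#' standard) peak per marker peptide: light areas proportional to the
#' per-type collagen amounts, heavy areas equal to the standard amount.
#'
#' @param type_amounts Named amounts per collagen type (e.g.
#'   `c(I = 85.8, III = 14.2)`).
#' @param standard_amount Heavy standard amount per marker.
#' @param markers Marker table, default [collagen_markers()].
#' @param heavy_shift_da Neutral heavy-label mass shift (default 6.02013,
#'   six 13C).
#' @param noise Multiplicative log-normal CV on light areas (0 = noiseless).
#' @param seed RNG seed.
#' @return A list: `chromatogram`, and `markers` (the marker table with
#'   query m/z columns appended); attribute `truth` holds the set-points.
#' @export
simulate_marker_peptides <- function(type_amounts, standard_amount = 1,
                                     markers = collagen_markers(),
                                     heavy_shift_da = 6.02013,
                                     noise = 0, seed = 1L) {
  with_seed(seed, {
    rt <- seq(100, 500, by = 2)
    rows <- list()
    markers$light_mz <- NA_real_
    markers$heavy_mz <- NA_real_
    for (i in seq_len(nrow(markers))) {
      codes <- strsplit(markers$sequence[i], "")[[1]]
      m0 <- sum(.residue_mass(codes)) + mass_constants()$water
      z <- markers$charge[i]
      lmz <- mz(m0, z); hmz <- mz(m0 + heavy_shift_da, z)
      markers$light_mz[i] <- lmz; markers$heavy_mz[i] <- hmz
      amt <- type_amounts[[markers$collagen_type[i]]]
      la <- amt * if (noise > 0) stats::rlnorm(1, -noise^2 / 2, noise) else 1
      center <- 150 + 50 * (i - 1)
      shape <- stats::dnorm(rt, center, 8)
      rows[[length(rows) + 1L]] <- data.frame(sample_id = "typing", rt_s = rt,
                                              mz = lmz, intensity = la * shape)
      rows[[length(rows) + 1L]] <- data.frame(sample_id = "typing", rt_s = rt,
                                              mz = hmz,
                                              intensity = standard_amount * shape)
    }
    chrom <- as_chromatogram(do.call(rbind, rows))
    out <- list(chromatogram = chrom, markers = markers)
    attr(out, "truth") <- list(type_amounts = type_amounts,
                               percent = 100 * type_amounts / sum(type_amounts),
                               standard_amount = standard_amount, seed = seed)
    out
  })
}

#' Quantify collagen type from a simulated or real marker chromatogram
#'
#' Integrates the light and heavy EIC of each marker and runs
#' [collagen_type_ratio()].
#'
#' @param chrom A `chromatogram`.
#' @param markers Marker table with `light_mz`/`heavy_mz` columns (as
#'   returned by [simulate_marker_peptides()]).
#' @param standard_amount Heavy standard amount per marker.
#' @param tolerance EIC half-window.
#' @return A `collagen_quant`.
#' @export
quantify_collagen_type <- function(chrom, markers, standard_amount = 1,
                                   tolerance = 0.02) {
  tab <- data.frame(
    marker_id = markers$marker_id,
    collagen_type = markers$collagen_type,
    light_area = vapply(markers$light_mz, function(m)
      integrate_peak(extract_eic(chrom, m, tolerance)), numeric(1)),
    heavy_area = vapply(markers$heavy_mz, function(m)
      integrate_peak(extract_eic(chrom, m, tolerance)), numeric(1)),
    standard_amount = standard_amount,
    stringsAsFactors = FALSE
  )
  collagen_type_ratio(tab)
}

#' Simulate a radiolabelled HPLC cross-link trace
#'
#' One Gaussian count peak per species, centred in its elution window, with
#' integrated counts = level × collagen mol × specific activity ×
#' efficiency × labels per molecule. Discrete peak weights are normalised
#' within the window so the window sum reproduces the set counts exactly in
#' the noiseless case; optional Poisson count noise.
#'
#' @param levels Named species levels (mol/mol collagen).
#' @param mode `"acid"` or `"base"` (selects windows).
#' @param cal A `quant_calibration`.
#' @param windows Window table, default the shipped one filtered by `mode`.
#' @param fractions Fraction grid (default 1:40).
#' @param poisson Add Poisson count noise.
#' @param seed RNG seed.
#' @return A data.frame (`sample_id`, `fraction`, `signal`, `cpm`, `mode`)
#'   with attribute `truth` (the levels and calibration used).
#' @export
simulate_hplc_trace <- function(levels, mode = c("acid", "base"), cal,
                                windows = NULL, fractions = 1:40,
                                poisson = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cal, "quant_calibration"))
  if (is.null(windows)) {
    w <- crosslink_windows()
    windows <- w[w$mode == mode, c("species", "start", "end")]
  }
  with_seed(seed, {
    cpm <- numeric(length(fractions))
    for (i in seq_len(nrow(windows))) {
      sp <- windows$species[i]
      lev <- if (sp %in% names(levels)) levels[[sp]] else 0
      if (lev <= 0) next
      total <- lev * cal$collagen_mol * cal$specific_activity *
        cal$efficiency * .labels_for(cal, sp)
      inwin <- fractions >= windows$start[i] & fractions <= windows$end[i]
      center <- (windows$start[i] + windows$end[i]) / 2
      wgt <- stats::dnorm(fractions[inwin], center,
                          (windows$end[i] - windows$start[i]) / 6)
      cpm[inwin] <- cpm[inwin] + total * wgt / sum(wgt)
    }
    if (poisson) cpm <- stats::rpois(length(cpm), cpm)
    out <- data.frame(sample_id = "trace", fraction = fractions,
                      signal = cpm / max(c(cpm, 1)), cpm = cpm, mode = mode)
    attr(out, "truth") <- list(levels = levels, mode = mode, seed = seed)
    out
  })
}

#' Simulate AFM force-indentation curves
#'
#' Forward thin-layer Hertz curves at a given modulus, with optional
#' multiplicative force noise.
#'
#' @param E Indentation modulus, Pa.
#' @param n_curves Number of replicate curves.
#' @param R,h,nu,bonded Geometry, as in [hertz_force()].
#' @param max_depth Maximum indentation depth, m.
#' @param n_points Points per curve.
#' @param rel_noise Relative force noise SD (0 = noiseless).
#' @param seed RNG seed.
#' @return A list of data.frames (`depth`, `force`) with attribute `truth`.
#' @export
simulate_force_curves <- function(E, n_curves = 1L, R = 5e-6, h = 40e-6,
                                  nu = 0.45, bonded = TRUE,
                                  max_depth = 1e-6, n_points = 100L,
                                  rel_noise = 0, seed = 1L) {
  stopifnot(E > 0, n_curves >= 0)
  with_seed(seed, {
    curves <- vector("list", n_curves)
    d <- seq(0, max_depth, length.out = n_points)
    for (k in seq_len(n_curves)) {
      f <- hertz_force(E, d, R, h, nu, bonded)
      if (rel_noise > 0) f <- f * (1 + stats::rnorm(n_points, 0, rel_noise))
      curves[[k]] <- data.frame(depth = d, force = f)
    }
    attr(curves, "truth") <- list(E = E, R = R, h = h, nu = nu,
                                  bonded = bonded, seed = seed)
    curves
  })
}
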