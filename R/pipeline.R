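# End-to-end orchestration over a synthetic (or user-supplied) cohort, and
# the group-summary statistics used by every report table.

#' Group summary with pairwise Welch tests
#'
#' Per-genotype mean, dispersion (SD or SE) and n for one metric, plus
#' pairwise two-sided Welch t-tests of each non-reference group against the
#' reference (and of the reference pairings requested). Significance tiers
#' follow the conventional 0.05 / 0.01 / 0.001 / 0.0001 thresholds.
#'
#' @param values Numeric vector of per-sample values.
#' @param group Factor/character of group labels, parallel to `values`.
#' @param dispersion `"sd"` or `"se"`.
#' @param comparisons List of 2-vectors of group labels to test (default:
#'   every other group against the last-listed group, mirroring WT-vs-KO and
#'   Het-vs-KO reporting).
#' @return A list of class `group_summary`: `stats` (data.frame group, n,
#'   mean, dispersion) and `tests` (data.frame with p-values and tier).
#' @export
group_summary <- function(values, group, dispersion = c("sd", "se"),
                          comparisons = NULL) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(values) == length(group), length(values) > 0)
  group <- as.character(group)
  labs <- unique(group)
  st <- do.call(rbind, lapply(labs, function(g) {
    v <- values[group == g]
    disp <- stats::sd(v)
    if (dispersion == "se") disp <- disp / sqrt(length(v))
    data.frame(group = g, n = length(v), mean = mean(v), dispersion = disp)
  }))
  names(st)[4] <- dispersion
  if (is.null(comparisons)) {
    ref <- labs[length(labs)]
    comparisons <- lapply(setdiff(labs, ref), function(g) c(g, ref))
  }
  tests <- do.call(rbind, lapply(comparisons, function(cmp) {
    a <- values[group == cmp[1]]; b <- values[group == cmp[2]]
    if (length(a) < 2L || length(b) < 2L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))) {
      p <- if (length(a) && length(b) && mean(a) == mean(b)) 1 else NA_real_
      if (length(a) < 2L || length(b) < 2L) {
        warning("comparison ", cmp[1], " vs ", cmp[2],
                " skipped: group with n < 2", call. = FALSE)
        p <- NA_real_
      }
    } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p <- 0  # distinct means, no within-group variance: limit case
    } else {
      p <- stats::t.test(a, b)$p.value
    }
    data.frame(comparison = paste(cmp, collapse = " vs "), p = p,
               tier = .p_tier(p), stringsAsFactors = FALSE)
  }))
  structure(list(stats = st, tests = tests), class = "group_summary")
}

.p_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.0001) "****" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$stats, row.names = FALSE)
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param spec A [cohort_spec()].
#' @param stages Subset of `c("occupancy", "glycoform", "crosslinks",
#'   "typing", "afm")`.
#' @param sites Site labels to analyse (default: all four-state helical
#'   glycosylation sites).
#' @param noise Logical: run with the spec's noise model (default `TRUE`).
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @param seed Overrides `spec$seed` when given.
#' @param ... Must be empty (unknown keys are an error).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), stages = c("occupancy",
                            "glycoform", "crosslinks", "typing", "afm"),
                            sites = NULL, noise = TRUE, out_dir = NULL,
                            seed = NULL, ...) {
  extra <- list(...)
  if (length(extra)) stop("unknown configuration key(s): ",
                          paste(names(extra), collapse = ", "), call. = FALSE)
  known <- c("occupancy", "glycoform", "crosslinks", "typing", "afm")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(seed)) spec$seed <- seed
  structure(list(spec = spec, stages = stages, sites = sites, noise = noise,
                 out_dir = out_dir), class = "run_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates per-sample instrument data with the cohort spec's set-points
#' and noise model, pushes each sample through the corresponding
#' quantification stage, and aggregates per-sample results into report
#' tables: site occupancy (mean ± SD per genotype), glycoform profiles,
#' cross-link levels with total aldehyde, collagen typing, and regional
#' indentation moduli (mean ± SE). Occupancies and profiles are computed
#' per sample and then averaged across the group.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return A list of class `pipeline_result` with one data.frame per stage
#'   plus `provenance` (seed, package version, configuration echo).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  out <- list()
  sites_tab <- site_table()
  labels <- config$sites
  if (is.null(labels)) {
    occ <- spec$occupancy
    labels <- unique(occ[occ$class == "GG-Hyl", c("chain", "site")])
  } else if (is.character(labels)) {
    labels <- unique(sites_tab[sites_tab$label %in% labels,
                               c("chain", "label")])
    names(labels) <- c("chain", "site")
  }

  if (any(c("occupancy", "glycoform") %in% config$stages)) {
    rows <- list(); grows <- list()
    for (r in seq_len(nrow(labels))) {
      site <- site_definition(labels$site[r], labels$chain[r], sites_tab)
      for (g in spec$genotypes) {
        for (s in seq_len(spec$n_ms)) {
          chrom <- simulate_chromatogram(site, spec = spec, genotype = g,
                                         sample = s, noise = config$noise)
          areas <- site_class_areas(chrom, site)
          occ <- site_occupancy(stats::setNames(areas$area,
                                                areas$report_label))
          rows[[length(rows) + 1L]] <- data.frame(
            chain = site$chain, site = site$label, genotype = g, sample = s,
            class = names(occ), percent = as.numeric(occ),
            stringsAsFactors = FALSE)
          if ("glycoform" %in% config$stages &&
              sum(unclass(occ)[intersect(c("Hyl", "G-Hyl", "GG-Hyl"),
                                         names(occ))]) > 0) {
            gp <- glycoform_profile(occ)
            grows[[length(grows) + 1L]] <- data.frame(
              chain = site$chain, site = site$label, genotype = g,
              sample = s, class = names(gp), percent = as.numeric(gp),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if ("occupancy" %in% config$stages) {
      out$occupancy <- .summarise_percent(do.call(rbind, rows))
    }
    if ("glycoform" %in% config$stages && length(grows)) {
      out$glycoform <- .summarise_percent(do.call(rbind, grows))
    }
  }

  if ("crosslinks" %in% config$stages) {
    cal <- quant_calibration(specific_activity = 1e12, collagen_mol = 2e-9)
    lev <- spec$xlink_levels
    rows <- list()
    for (g in spec$genotypes) {
      for (s in seq_len(spec$n_xlink)) {
        seed_s <- (spec$seed * 2003L + match(g, spec$genotypes) * 211L + s) %%
          .Machine$integer.max
        for (mode in c("acid", "base")) {
          sel <- lev[lev$mode == mode, , drop = FALSE]
          mu <- stats::setNames(sel[[paste0(g, "_mean")]], sel$species)
          if (config$noise) {
            sdv <- stats::setNames(sel[[paste0(g, "_sd")]], sel$species)
            mu <- with_seed(seed_s + (mode == "base"), {
              stats::setNames(vapply(seq_along(mu), function(i)
                .rtruncnorm_pos(1, mu[i], sdv[i]), numeric(1)), names(mu))
            })
          }
          trace <- simulate_hplc_trace(mu, mode, cal,
                                       poisson = config$noise &&
                                         isTRUE(spec$noise$poisson_counts),
                                       seed = seed_s + 7L)
          w <- crosslink_windows()
          res <- quantify_crosslinks(trace, w[w$mode == mode, ], cal)
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = g, sample = s, mode = mode, species = names(res),
            level = as.numeric(res), stringsAsFactors = FALSE)
        }
      }
    }
    xl <- do.call(rbind, rows)
    # per-sample total aldehyde from the acid run
    ta <- do.call(rbind, lapply(split(xl[xl$mode == "acid", ],
                                      list(xl$genotype[xl$mode == "acid"],
                                           xl$sample[xl$mode == "acid"]),
                                      drop = TRUE), function(d) {
      data.frame(genotype = d$genotype[1], sample = d$sample[1],
                 mode = "acid", species = "total aldehyde",
                 level = total_aldehyde(stats::setNames(d$level, d$species)))
    }))
    xl <- rbind(xl, ta)
    agg <- stats::aggregate(level ~ mode + species + genotype, xl,
                            function(v) c(mean = mean(v), sd = stats::sd(v),
                                          n = length(v)))
    out$crosslinks <- data.frame(agg[1:3], mean = agg$level[, "mean"],
                                 sd = agg$level[, "sd"], n = agg$level[, "n"])
    out$crosslinks_samples <- xl
  }

  if ("typing" %in% config$stages) {
    rows <- list()
    type_setpoints <- list(WT = c(I = 85.8, III = 14.2),
                           Het = c(I = 85.0, III = 15.0),
                           KO = c(I = 86.1, III = 13.9))
    for (g in spec$genotypes) {
      tp <- type_setpoints[[g]]
      if (is.null(tp)) tp <- c(I = 85.8, III = 14.2)
      for (s in seq_len(spec$n_ms)) {
        seed_s <- (spec$seed * 3001L + match(g, spec$genotypes) * 307L + s) %%
          .Machine$integer.max
        sim <- simulate_marker_peptides(tp, noise = if (config$noise)
          spec$noise$area_cv else 0, seed = seed_s)
        q <- quantify_collagen_type(sim$chromatogram, sim$markers)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, sample = s, type_III_percent = q$percent[["III"]])
      }
    }
    out$typing <- do.call(rbind, rows)
  }

  if ("afm" %in% config$stages) {
    rows <- list()
    mod <- spec$moduli
    for (r in seq_len(nrow(mod))) {
      for (g in c("WT", "KO")) {
        mu <- mod[[paste0(g, "_mean_kpa")]][r]
        se <- mod[[paste0(g, "_se_kpa")]][r]
        for (s in seq_len(spec$n_afm)) {
          seed_s <- (spec$seed * 4001L + r * 401L +
                       (g == "KO") * 97L + s) %% .Machine$integer.max
          E_s <- if (config$noise) {
            with_seed(seed_s, .rtruncnorm_pos(1, mu, se * sqrt(spec$n_afm),
                                              lower = 0.1))
          } else mu
          curves <- simulate_force_curves(E_s * 1e3,
                                          rel_noise = if (config$noise)
                                            spec$noise$force_rel else 0,
                                          seed = seed_s + 13L)
          fit <- fit_hertz(curves[[1]]$depth, curves[[1]]$force,
                           R = 5e-6, h = 40e-6, nu = 0.45)
          rows[[length(rows) + 1L]] <- data.frame(
            region = mod$region[r], genotype = g, sample = s,
            E_ind_kpa = coef(fit)[["E_ind"]] / 1e3)
        }
      }
    }
    afm <- do.call(rbind, rows)
    agg <- stats::aggregate(E_ind_kpa ~ region + genotype, afm,
                            function(v) c(mean = mean(v),
                                          se = stats::sd(v) / sqrt(length(v)),
                                          n = length(v)))
    out$afm <- data.frame(agg[1:2], mean = agg$E_ind_kpa[, "mean"],
                          se = agg$E_ind_kpa[, "se"], n = agg$E_ind_kpa[, "n"])
    out$afm_samples <- afm
  }

  out$provenance <- list(
    package = as.character(utils::packageVersion("collagenQ")),
    seed = spec$seed, stages = config$stages, noise = config$noise,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) .write_reports(out, config$out_dir)
  out
}

.summarise_percent <- function(df) {
  agg <- stats::aggregate(percent ~ chain + site + class + genotype, df,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  data.frame(agg[1:4], mean = agg$percent[, "mean"],
             sd = agg$percent[, "sd"], n = agg$percent[, "n"])
}

.write_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(res), "provenance")) {
    utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline result> stages:",
      paste(setdiff(names(x), c("provenance", "crosslinks_samples",
                                "afm_samples")), collapse = ", "),
      "\n  seed:", x$provenance$seed, "\n")
  invisible(x)
}
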