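# Chromatogram handling: reading long-format MS1 data, extracting ion
# chromatograms in a fixed absolute m/z window, and trapezoidal peak
# integration with automatic bounds.

#' Read an MS1 chromatogram CSV
#'
#' Long format, one row per (retention time, m/z) intensity record. Required
#' columns: `sample_id`, `rt_s` (seconds), `mz`, `intensity`.
#'
#' @param path CSV path.
#' @return A data.frame of class `chromatogram`.
#' @export
read_chromatogram <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_chromatogram(x)
}

#' Validate a data.frame as a chromatogram
#'
#' @param x A data.frame with columns `sample_id`, `rt_s`, `mz`, `intensity`.
#' @return `x` with class `chromatogram` prepended.
#' @export
as_chromatogram <- function(x) {
  need <- c("sample_id", "rt_s", "mz", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("chromatogram lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!inherits(x, "chromatogram")) class(x) <- c("chromatogram", class(x))
  x
}

#' Extract an ion chromatogram (EIC)
#'
#' For every retention time in the chromatogram, sums intensity over records
#' with |m/z − target| ≤ tolerance. The tolerance is an absolute m/z window
#' (±0.02 by default), not ppm. Retention times with no in-window record
#' yield zero, so all EICs of one sample share the same time base.
#'
#' @param chrom A `chromatogram` (one sample).
#' @param target_mz Target m/z.
#' @param tolerance Absolute m/z half-window (default 0.02).
#' @return A data.frame of class `eic` with columns `rt_s`, `intensity`, and
#'   attributes `target_mz`, `tolerance`.
#' @export
extract_eic <- function(chrom, target_mz, tolerance = 0.02) {
  chrom <- as_chromatogram(chrom)
  if (!nrow(chrom)) stop("empty chromatogram", call. = FALSE)
  stopifnot(tolerance > 0, is.finite(target_mz))
  rt <- sort(unique(chrom$rt_s))
  sel <- abs(chrom$mz - target_mz) <= tolerance
  y <- rep(0, length(rt))
  if (any(sel)) {
    agg <- tapply(chrom$intensity[sel], chrom$rt_s[sel], sum)
    y[match(as.numeric(names(agg)), rt)] <- as.numeric(agg)
  }
  structure(data.frame(rt_s = rt, intensity = y),
            class = c("eic", "data.frame"),
            target_mz = target_mz, tolerance = tolerance)
}

#' Integrate an EIC peak
#'
#' Trapezoidal area over a retention-time window. With `window = "auto"` the
#' apex (global maximum) is located and the bounds are walked outward to the
#' first flanking local minima whose intensity falls below `floor_frac` of
#' the apex (default 1%), or to the EIC ends.
#'
#' @param eic An `eic` (or data.frame with `rt_s`, `intensity`).
#' @param window `"auto"` or numeric `c(start, end)` in seconds.
#' @param floor_frac Fraction of apex intensity treated as baseline when
#'   auto-detecting bounds.
#' @return Peak area (intensity × seconds).
#' @export
integrate_peak <- function(eic, window = "auto", floor_frac = 0.01) {
  rt <- eic$rt_s; y <- eic$intensity
  if (length(rt) < 2L) return(0)
  if (identical(window, "auto")) {
    if (all(y == 0)) return(0)
    apex <- which.max(y)
    floor_y <- floor_frac * y[apex]
    n <- length(y)
    # walk outward while still descending and above the baseline floor;
    # stops at a flanking local minimum or once intensity falls below floor
    lo <- apex
    while (lo > 1L && y[lo] > floor_y && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- apex
    while (hi < n && y[hi] > floor_y && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    idx <- lo:hi
  } else {
    stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
    idx <- which(rt >= window[1] & rt <= window[2])
    if (length(idx) < 2L) stop("integration window contains fewer than two points",
                               call. = FALSE)
  }
  r <- rt[idx]; v <- y[idx]
  sum(diff(r) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Extract and integrate all class EICs of one site in one sample
#'
#' Convenience wrapper: builds the site's EIC queries, extracts each class
#' EIC (summing areas over the queried charge states), and returns per-class
#' areas keyed by reporting label (aldehyde species pool into `Lys`).
#'
#' @param chrom A single-sample `chromatogram`.
#' @param site A `site_definition`.
#' @param charges Charge states to query (default 2).
#' @param tolerance Absolute m/z half-window (default 0.02).
#' @param heavy_shift_da If non-`NULL`, also integrate the co-eluting heavy
#'   internal-standard channel at `neutral mass + heavy_shift_da`.
#' @return A data.frame `report_label`, `area` (and `heavy_area` when
#'   requested), one row per reporting class.
#' @export
site_class_areas <- function(chrom, site, charges = 2L, tolerance = 0.02,
                             heavy_shift_da = NULL) {
  q <- build_eic_queries(site, charges = charges, tolerance = tolerance)
  q$area <- vapply(seq_len(nrow(q)), function(i) {
    integrate_peak(extract_eic(chrom, q$mz[i], tolerance))
  }, numeric(1))
  if (!is.null(heavy_shift_da)) {
    q$heavy_area <- vapply(seq_len(nrow(q)), function(i) {
      hm <- q$mz[i] + heavy_shift_da / q$charge[i]
      integrate_peak(extract_eic(chrom, hm, tolerance))
    }, numeric(1))
  }
  cols <- intersect(c("area", "heavy_area"), names(q))
  out <- stats::aggregate(q[cols], by = list(report_label = q$report_label), sum)
  out[match(unique(q$report_label), out$report_label), , drop = FALSE]
}
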