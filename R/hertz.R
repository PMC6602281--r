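# Finite-thickness-corrected Hertz (Dimitriadis) contact model for
# sphere-on-thin-layer AFM nanoindentation, and the single-parameter
# modulus fit.
#
# F(delta) = (4/3) * E/(1 - nu^2) * sqrt(R) * delta^(3/2) * C(chi),
# chi = sqrt(R * delta) / h, with C a 4th-order polynomial correction for a
# layer of finite thickness h (C(0) = 1 recovers plain Hertz). The force is
# linear in E, so the least-squares modulus has a closed form; an intercept
# can be co-fitted to absorb an imperfect force zero.

.DIMITRIADIS <- list(
  bonded = c(1.133, 1.283, 0.769, 0.0975),
  free   = c(0.884, 0.781, 0.386, 0.0048)
)

#' Finite-thickness correction factor
#'
#' @param chi Dimensionless contact parameter `sqrt(R*delta)/h`.
#' @param bonded Layer bonded to the substrate (default `TRUE`; cryo-sections
#'   adhere to the slide)? `FALSE` selects the free-slip coefficient set.
#' @return Correction factor C(chi) ≥ 1.
#' @export
dimitriadis_correction <- function(chi, bonded = TRUE) {
  a <- if (bonded) .DIMITRIADIS$bonded else .DIMITRIADIS$free
  1 + a[1] * chi + a[2] * chi^2 + a[3] * chi^3 + a[4] * chi^4
}

#' Forward force of the thin-layer Hertz model
#'
#' @param E Indentation modulus in Pa.
#' @param delta Indentation depth(s) in m (≥ 0).
#' @param R Tip radius in m.
#' @param h Sample thickness in m (`Inf` gives plain Hertz).
#' @param nu Poisson ratio (default 0.45, nearly incompressible soft
#'   tissue).
#' @param bonded Bonded boundary condition (default `TRUE`).
#' @return Force(s) in N.
#' @examples
#' hertz_force(12.04e3, 1e-6, R = 5e-6, h = 40e-6)
#' @export
hertz_force <- function(E, delta, R, h = Inf, nu = 0.45, bonded = TRUE) {
  if (any(delta < 0)) stop("indentation depth must be non-negative",
                           call. = FALSE)
  stopifnot(R > 0, h > 0, nu >= 0, nu < 0.5, E >= 0)
  chi <- if (is.finite(h)) sqrt(R * delta) / h else 0 * delta
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5 *
    dimitriadis_correction(chi, bonded)
}

#' Fit the indentation modulus of a force-indentation curve
#'
#' Least-squares fit of the single free parameter E (optionally plus a force
#' offset) of the finite-thickness-corrected Hertz model to the loading
#' portion of a pre-zeroed force curve. Because force is linear in E the
#' least-squares problem is solved exactly via [stats::lm()] on the model
#' basis `g(delta) = F(E = 1, delta)`; the closed-form Hertz inversion at
#' the deepest point provides the reported starting value (diagnostic only).
#' Points deeper than `max_depth_frac * h` are excluded to stay inside the
#' correction's validity range.
#'
#' @param depth Indentation depths in m (loading portion, non-decreasing).
#' @param force Forces in N.
#' @param R,h,nu,bonded Geometry, as in [hertz_force()].
#' @param max_depth_frac Maximum analysed depth as a fraction of thickness
#'   (default 0.1).
#' @param fit_offset Co-fit a constant force offset (default `FALSE`:
#'   curves are assumed pre-zeroed).
#' @return An object of class `hertz_fit` with components `coefficients`
#'   (named: `E_ind` in Pa, and `offset` in N when co-fitted), `fitted.values`,
#'   `residuals`, `rss`, `n`, `converged`, `start`, `geometry`, `data`.
#' @examples
#' d <- seq(0, 1e-6, length.out = 100)
#' f <- hertz_force(12040, d, R = 5e-6, h = 40e-6)
#' fit_hertz(d, f, R = 5e-6, h = 40e-6)
#' @export
fit_hertz <- function(depth, force, R, h = Inf, nu = 0.45, bonded = TRUE,
                      max_depth_frac = 0.1, fit_offset = FALSE) {
  stopifnot(length(depth) == length(force), all(is.finite(force)))
  if (any(depth < 0)) stop("negative indentation depth", call. = FALSE)
  if (is.unsorted(depth)) stop("loading portion must have non-decreasing depth",
                               call. = FALSE)
  keep <- depth <= max_depth_frac * h
  d <- depth[keep]; f <- force[keep]
  if (length(d) < 10L) stop("need at least 10 points on the loading portion",
                            call. = FALSE)
  g <- hertz_force(1, d, R, h, nu, bonded)
  # starting value: closed-form inversion at the deepest point
  imax <- which.max(d)
  start <- if (g[imax] > 0) f[imax] / g[imax] else NA_real_
  fit <- if (fit_offset) stats::lm(f ~ g) else stats::lm(f ~ g - 1)
  co <- stats::coef(fit)
  E <- unname(co[["g"]])
  converged <- is.finite(E) && E > 0
  coefs <- c(E_ind = E)
  if (fit_offset) coefs <- c(coefs, offset = unname(co[["(Intercept)"]]))
  structure(list(
    coefficients = coefs,
    fitted.values = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    rss = sum(stats::residuals(fit)^2),
    n = length(d),
    converged = converged,
    start = start,
    geometry = list(R = R, h = h, nu = nu, bonded = bonded,
                    max_depth_frac = max_depth_frac),
    data = data.frame(depth = d, force = f)
  ), class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("Thin-layer Hertz indentation fit\n")
  cat(sprintf("  E_ind = %.4g kPa  (%d points%s)\n",
              x$coefficients[["E_ind"]] / 1e3, x$n,
              if (x$converged) "" else "; NOT converged"))
  if ("offset" %in% names(x$coefficients)) {
    cat(sprintf("  force offset = %.3g N\n", x$coefficients[["offset"]]))
  }
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) object$coefficients

#' @export
fitted.hertz_fit <- function(object, ...) object$fitted.values

#' @export
residuals.hertz_fit <- function(object, ...) object$residuals

#' @export
summary.hertz_fit <- function(object, ...) {
  g <- object$geometry
  structure(list(
    E_ind_kpa = object$coefficients[["E_ind"]] / 1e3,
    offset = if ("offset" %in% names(object$coefficients))
      object$coefficients[["offset"]] else NULL,
    n = object$n, rss = object$rss,
    rmse = sqrt(object$rss / object$n),
    converged = object$converged, geometry = g
  ), class = "summary.hertz_fit")
}

#' @export
print.summary.hertz_fit <- function(x, ...) {
  g <- x$geometry
  cat("Thin-layer Hertz indentation fit\n")
  cat(sprintf("  geometry: R = %.3g m, h = %.3g m, nu = %.2f, %s\n",
              g$R, g$h, g$nu, if (g$bonded) "bonded" else "free-slip"))
  cat(sprintf("  E_ind = %.4f kPa   (n = %d, RMSE = %.3g N)\n",
              x$E_ind_kpa, x$n, x$rmse))
  if (!is.null(x$offset)) cat(sprintf("  offset = %.3g N\n", x$offset))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
predict.hertz_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$depth else {
    if (is.data.frame(newdata)) newdata$depth else newdata
  }
  g <- object$geometry
  f <- hertz_force(object$coefficients[["E_ind"]], d, g$R, g$h, g$nu, g$bonded)
  if ("offset" %in% names(object$coefficients)) {
    f <- f + object$coefficients[["offset"]]
  }
  f
}

#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$data$depth * 1e6, x$data$force * 1e9,
                 xlab = expression(paste("indentation depth (", mu, "m)")),
                 ylab = "force (nN)", ...)
  o <- order(x$data$depth)
  graphics::lines(x$data$depth[o] * 1e6, x$fitted.values[o] * 1e9, col = 2)
  invisible(x)
}

#' Simulate force curves from a fitted indentation model
#'
#' Draws `nsim` replicate force vectors at the fitted depths from the
#' forward model with multiplicative Gaussian force noise.
#'
#' @param object A `hertz_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @param rel_noise Relative force noise SD (default 0.05).
#' @param ... Unused.
#' @return A data.frame with `nsim` columns (`sim_1`, ...), one row per depth.
#' @export
simulate.hertz_fit <- function(object, nsim = 1, seed = NULL,
                               rel_noise = 0.05, ...) {
  f0 <- predict(object)
  with_seed(seed, {
    out <- replicate(nsim, f0 * (1 + stats::rnorm(length(f0), 0, rel_noise)))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}
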