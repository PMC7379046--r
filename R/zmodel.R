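#' Z-Model: linear plus saturating-exponential constitutive form
#'
#' sigma(eps) = a * (eps - eps0) + b * (1 - exp(-c * (eps - eps0))) + sigma0.
#'
#' The tangent modulus decreases monotonically from E_0 = a + b*c at the
#' origin to the linear-asymptotic modulus E_lin = a, describing strain
#' softening toward a linear asymptote. The knee strain 1/c marks the
#' intersection of the initial-tangent line with the asymptote. The plain
#' form has origin (0, 0); translated variants pin the origin at a segment
#' join to impose continuity by construction.
#'
#' @param a linear (asymptotic) stiffness a_Z, MPa; a >= 0.
#' @param b saturating-term amplitude b_Z, MPa; b >= 0.
#' @param c saturation rate c_Z, dimensionless; c > 0.
#' @param origin numeric `c(strain, stress)` of the (pinned) origin.
#' @param rss residual sum of squares of the fit that produced the
#'   parameters (MPa^2), if any.
#' @param segment `"whole"`, `"initial"` or `"final"` for composite fits.
#' @return An object of class `z_fit` with derived fields `modulus_0`
#'   (E_0 = a + b*c), `modulus_lin` (= a), `strain_knee` (= 1/c) and
#'   `softening_ratio` (Delta_Z = (E_lin - E_0)/E_0 = -b*c/(a + b*c)).
#' @export
z_model <- function(a, b, c, origin = c(0, 0), rss = NA_real_,
                    segment = c("whole", "initial", "final")) {
  segment <- match.arg(segment)
  if (!is.finite(c) || c <= 0) stop("c must be positive")
  if (a < 0 || b < 0) stop("a and b must be non-negative")
  e0 <- a + b * c
  structure(
    list(a = a, b = b, c = c,
         origin_strain = origin[1], origin_stress = origin[2],
         modulus_0 = e0, modulus_lin = a,
         strain_knee = 1 / c,
         softening_ratio = if (e0 > 0) (a - e0) / e0 else 0,
         rss = rss, segment = segment),
    class = "z_fit"
  )
}

#' @export
print.z_fit <- function(x, ...) {
  cat(sprintf("Z-Model fit (%s segment): a = %.4g, b = %.4g, c = %.4g MPa\n",
              x$segment, x$a, x$b, x$c))
  cat(sprintf("  E_0 = %.4g MPa, E_lin = %.4g MPa, knee strain = %.4g, Delta_Z = %.1f%%\n",
              x$modulus_0, x$modulus_lin, x$strain_knee,
              100 * x$softening_ratio))
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.4g MPa^2\n", x$rss))
  invisible(x)
}

#' Evaluate a Z-Model
#'
#' @param fit a [z_model()] fit.
#' @param strain strain values, each >= the fit's origin strain.
#' @return stress in MPa.
#' @export
z_eval <- function(fit, strain) {
  stopifnot(inherits(fit, "z_fit"))
  if (any(strain < fit$origin_strain - 1e-12)) {
    stop("strain below the model origin")
  }
  x <- strain - fit$origin_strain
  fit$a * x + fit$b * (1 - exp(-fit$c * x)) + fit$origin_stress
}

#' Tangent modulus of a Z-Model
#'
#' E(eps) = a + b*c*exp(-c*(eps - eps0)): strictly decreasing, from
#' E_0 = a + b*c at the origin to the asymptote a.
#'
#' @inheritParams z_eval
#' @return tangent modulus in MPa.
#' @export
z_tangent_modulus <- function(fit, strain) {
  stopifnot(inherits(fit, "z_fit"))
  x <- strain - fit$origin_strain
  fit$a + fit$b * fit$c * exp(-fit$c * x)
}

#' Knee strain and stiffness-variation ratio of a Z-Model
#'
#' The knee strain is the intersection of the initial-tangent line
#' sigma = E_0 * eps with the linear asymptote sigma = a * eps + b, which
#' reduces to 1/c. The softening ratio Delta_Z = (E_lin - E_0)/E_0 =
#' -b*c/(a + b*c) is the fractional stiffness drop across the knee.
#'
#' @param fit a [z_model()] fit.
#' @return list with `strain_knee` and `softening_ratio`.
#' @export
z_knee <- function(fit) {
  stopifnot(inherits(fit, "z_fit"))
  list(strain_knee = fit$strain_knee, softening_ratio = fit$softening_ratio)
}

# internal: best (a, b) >= 0 for fixed c by linear least squares with
# non-negativity handled by boundary comparison (2 parameters only)
z_linear_coef <- function(x, y, c) {
  g2 <- 1 - exp(-c * x)
  X <- cbind(x, g2)
  ab <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
  cand <- list()
  if (all(is.finite(ab)) && all(ab >= 0)) cand <- list(ab)
  # boundary candidates: a = 0 or b = 0
  b_only <- max(0, sum(g2 * y) / sum(g2 * g2))
  a_only <- max(0, sum(x * y) / sum(x * x))
  cand <- c(cand, list(c(0, b_only), c(a_only, 0)))
  rss <- vapply(cand, function(p) sum((y - X %*% p)^2), numeric(1))
  best <- cand[[which.min(rss)]]
  list(a = best[1], b = best[2], rss = min(rss))
}

#' Fit the Z-Model to a curve segment by least squares
#'
#' Minimises the residual sum of squares of [z_eval()] over (a, b, c) with
#' the origin pinned at `origin` (continuity by construction for translated
#' segments). The two linear parameters are profiled out analytically for
#' each candidate c (separable least squares); c is located by a log-scale
#' grid refined with 1-D optimisation, and the triple is polished with
#' Levenberg-Marquardt under the shape bounds a, b >= 0, c > 0.
#'
#' @param strain,stress segment samples; strain strictly increasing,
#'   >= 10 samples.
#' @param origin pinned origin `c(strain, stress)`; defaults to `(0, 0)`.
#' @param segment segment label stored on the fit.
#' @param c_range search range for c (log-spanned).
#' @param min_samples minimum segment length; the standard protocol uses
#'   10, degenerate-fallback callers may relax it.
#' @return A [z_model()] fit with `rss` populated.
#' @export
fit_z <- function(strain, stress, origin = c(0, 0),
                  segment = c("whole", "initial", "final"),
                  c_range = c(1e-3, 1e4), min_samples = 10L) {
  segment <- match.arg(segment)
  if (inherits(strain, "stress_strain_curve")) {
    stress <- strain$stress; strain <- strain$strain
  }
  if (length(strain) < max(4L, min_samples)) {
    stop("fit_z needs at least ", max(4L, min_samples), " samples")
  }
  if (any(diff(strain) <= 0)) stop("strain must be strictly increasing")
  x <- strain - origin[1]; y <- stress - origin[2]
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    stop("degenerate segment: stress has no variation")
  }
  prof <- function(logc) z_linear_coef(x, y, exp(logc))$rss
  grid <- seq(log(c_range[1]), log(c_range[2]), length.out = 60)
  rssg <- vapply(grid, prof, numeric(1))
  i <- which.min(rssg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), tol = 1e-12)
  c_hat <- exp(opt$minimum)
  ab <- z_linear_coef(x, y, c_hat)
  start <- c(a = ab$a, b = ab$b, c = c_hat)
  pol <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) y - (p[1] * x + p[2] * (1 - exp(-p[3] * x))),
      lower = c(0, 0, 1e-10), upper = c(Inf, Inf, c_range[2] * 10),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$deviance) && pol$deviance <= ab$rss) {
    p <- pol$par; rss <- pol$deviance
  } else {
    p <- start; rss <- ab$rss
  }
  z_model(p[[1]], p[[2]], max(p[[3]], 1e-10), origin = origin, rss = rss,
          segment = segment)
}
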