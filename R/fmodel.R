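#' F-Model: exponential soft-tissue toe-region constitutive form
#'
#' sigma(eps) = B * (exp(C * (eps - eps0)) - 1) + sigma0, the classical
#' exponential model of the toe region of soft collagenous tissues, here
#' describing the progressive recruitment (shrinkage recovery) of crimped
#' nanofibers. The tangent modulus grows from E_0 = B*C at the origin to
#' E_TP = B*C*exp(C*(eps_TP - eps0)) at the transition point where the
#' model is handed over to the linear-asymptotic regime.
#'
#' @param B amplitude B_F, MPa; B > 0.
#' @param C exponential rate C_F, dimensionless; C > 0.
#' @param origin numeric `c(strain, stress)` of the (pinned) origin.
#' @param strain_tp endpoint strain of the model's domain (the transition
#'   point), `NA` if not yet set.
#' @param rss residual sum of squares, MPa^2.
#' @return An object of class `f_fit` with derived fields `modulus_0`
#'   (= B*C), `modulus_tp`, `stress_tp` and `stiffening_ratio`
#'   (Delta_F = exp(C*(eps_TP - eps0)) - 1).
#' @export
f_model <- function(B, C, origin = c(0, 0), strain_tp = NA_real_,
                    rss = NA_real_) {
  if (!is.finite(B) || B <= 0) stop("B must be positive")
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  e0 <- B * C
  span <- strain_tp - origin[1]
  structure(
    list(B = B, C = C,
         origin_strain = origin[1], origin_stress = origin[2],
         strain_tp = strain_tp,
         stress_tp = if (is.na(strain_tp)) NA_real_ else
           B * (exp(C * span) - 1) + origin[2],
         modulus_0 = e0,
         modulus_tp = if (is.na(strain_tp)) NA_real_ else e0 * exp(C * span),
         stiffening_ratio = if (is.na(strain_tp)) NA_real_ else
           exp(C * span) - 1,
         rss = rss),
    class = "f_fit"
  )
}

#' @export
print.f_fit <- function(x, ...) {
  cat(sprintf("F-Model fit: B = %.4g MPa, C = %.4g\n", x$B, x$C))
  cat(sprintf("  E_0 = %.4g MPa", x$modulus_0))
  if (!is.na(x$strain_tp)) {
    cat(sprintf(", E_TP = %.4g MPa at eps_TP = %.4g (Delta_F = %.0f%%)",
                x$modulus_tp, x$strain_tp, 100 * x$stiffening_ratio))
  }
  cat("\n")
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.4g MPa^2\n", x$rss))
  invisible(x)
}

#' Evaluate an F-Model
#'
#' @param fit an [f_model()] fit.
#' @param strain strain values within `[origin strain, strain_tp]` (the
#'   upper bound is enforced only when the fit has one).
#' @return stress in MPa.
#' @export
f_eval <- function(fit, strain) {
  stopifnot(inherits(fit, "f_fit"))
  if (any(strain < fit$origin_strain - 1e-12)) {
    stop("strain below the model origin")
  }
  if (!is.na(fit$strain_tp) && any(strain > fit$strain_tp + 1e-9)) {
    stop("strain beyond the model's transition point")
  }
  x <- strain - fit$origin_strain
  fit$B * (exp(fit$C * x) - 1) + fit$origin_stress
}

#' Tangent modulus of an F-Model
#'
#' E(eps) = B*C*exp(C*(eps - eps0)): strictly increasing.
#'
#' @inheritParams f_eval
#' @return tangent modulus in MPa.
#' @export
f_tangent_modulus <- function(fit, strain) {
  stopifnot(inherits(fit, "f_fit"))
  fit$B * fit$C * exp(fit$C * (strain - fit$origin_strain))
}

#' Stiffening ratio of an F-Model
#'
#' Delta_F = (E_TP - E_0)/E_0 = exp(C*(eps_TP - eps0)) - 1: the fractional
#' modulus increase across the toe region, 0 when the domain is empty.
#'
#' @param fit an [f_model()] fit with `strain_tp` set.
#' @return dimensionless fraction.
#' @export
f_stiffening_ratio <- function(fit) {
  stopifnot(inherits(fit, "f_fit"))
  if (is.na(fit$strain_tp)) stop("strain_tp not set on this fit")
  fit$stiffening_ratio
}

#' Amplitude from the continuity condition at the transition point
#'
#' B = (sigma_TP - sigma0) / (exp(C*(eps_TP - eps0)) - 1), so that the
#' F-Model passes through the transition point exactly; linear in the
#' stress at the transition point.
#'
#' @param stress_tp stress at the transition point, MPa.
#' @param C exponential rate.
#' @param strain_tp transition-point strain.
#' @param origin `c(strain, stress)` origin of the (possibly translated)
#'   model.
#' @return B in MPa.
#' @export
b_from_continuity <- function(stress_tp, C, strain_tp, origin = c(0, 0)) {
  span <- strain_tp - origin[1]
  if (stress_tp <= origin[2]) stop("stress_tp must exceed the origin stress")
  if (span <= 0) stop("strain_tp must exceed the origin strain")
  if (C * span < 1e-6) {
    stop("ill-conditioned continuity condition: C * (strain_tp - origin) too small")
  }
  denom <- exp(C * span) - 1
  if (!is.finite(denom)) stop("continuity condition overflows")
  (stress_tp - origin[2]) / denom
}

# internal: profiled RSS over C; B >= 0 closed-form for fixed C
f_profile <- function(x, y, C) {
  g <- exp(pmin(C * x, 700)) - 1
  B <- max(sum(g * y) / sum(g * g), 1e-12)
  list(B = B, rss = sum((y - B * g)^2))
}

#' Fit the F-Model to a curve segment by least squares
#'
#' Unconstrained mode fits (B, C) with the origin pinned; the amplitude B
#' is profiled out analytically for each candidate C (separable least
#' squares) and C is located on a log grid refined by 1-D optimisation,
#' then polished by Levenberg-Marquardt under B > 0, C in (0, `c_max`].
#' Constrained mode (`continuity` supplied as `c(strain_tp, stress_tp)`)
#' fits C alone, with B from [b_from_continuity()], so the fitted curve
#' interpolates the transition point exactly.
#'
#' A segment that is not convex (stress increments decreasing) drives C to
#' the lower bound and is rejected as a shape violation.
#'
#' @param strain,stress segment samples; >= 8 samples.
#' @param origin pinned origin `c(strain, stress)`.
#' @param continuity optional `c(strain_tp, stress_tp)` continuity
#'   constraint.
#' @param c_max upper bound for C (default 200).
#' @param min_samples minimum segment length; the standard protocol uses
#'   8, degenerate-fallback callers may relax it.
#' @return An [f_model()] fit with `rss` (and `strain_tp` in constrained
#'   mode) populated.
#' @export
fit_f <- function(strain, stress, origin = c(0, 0), continuity = NULL,
                  c_max = 200, min_samples = 8L) {
  if (inherits(strain, "stress_strain_curve")) {
    stress <- strain$stress; strain <- strain$strain
  }
  if (length(strain) < max(3L, min_samples)) {
    stop("fit_f needs at least ", max(3L, min_samples), " samples")
  }
  x <- strain - origin[1]; y <- stress - origin[2]
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    stop("degenerate segment: stress has no variation")
  }
  c_min <- 1e-3
  if (is.null(continuity)) {
    prof <- function(logC) f_profile(x, y, exp(logC))$rss
    grid <- seq(log(c_min), log(c_max), length.out = 60)
    i <- which.min(vapply(grid, prof, numeric(1)))
    opt <- stats::optimize(prof, c(grid[max(1, i - 1)],
                                   grid[min(length(grid), i + 1)]),
                           tol = 1e-12)
    C_hat <- exp(opt$minimum)
    pr <- f_profile(x, y, C_hat)
    start <- c(B = pr$B, C = C_hat)
    pol <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(p) y - p[1] * (exp(pmin(p[2] * x, 700)) - 1),
        lower = c(1e-12, c_min), upper = c(Inf, c_max),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$deviance) && pol$deviance <= pr$rss) {
      B <- pol$par[[1]]; C <- pol$par[[2]]; rss <- pol$deviance
    } else {
      B <- pr$B; C <- C_hat; rss <- pr$rss
    }
    if (C <= c_min * (1 + 1e-6)) {
      stop("segment is not convex: C driven to its lower bound (shape violation)")
    }
    f_model(B, C, origin = origin, rss = rss)
  } else {
    strain_tp <- continuity[1]; stress_tp <- continuity[2]
    obj <- function(logC) {
      C <- exp(logC)
      B <- tryCatch(b_from_continuity(stress_tp, C, strain_tp, origin),
                    error = function(e) NA_real_)
      if (!is.finite(B)) return(Inf)
      sum((y - B * (exp(pmin(C * x, 700)) - 1))^2)
    }
    grid <- seq(log(c_min), log(c_max), length.out = 60)
    i <- which.min(vapply(grid, obj, numeric(1)))
    opt <- stats::optimize(obj, c(grid[max(1, i - 1)],
                                  grid[min(length(grid), i + 1)]),
                           tol = 1e-12)
    C <- exp(opt$minimum)
    if (C <= c_min * (1 + 1e-6)) {
      stop("segment is not convex: C driven to its lower bound (shape violation)")
    }
    B <- b_from_continuity(stress_tp, C, strain_tp, origin)
    f_model(B, C, origin = origin, strain_tp = strain_tp,
            rss = opt$objective)
  }
}
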