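# Composite fitting: curve taxonomy, inflection anchors, continuity-joined
# Z/F/Z model sequence and the iterative backward transition-point search.

# internal: local-linear-regression slope of stress vs strain over a
# centered window of `w` samples (edge windows shrink). This is the
# tangent-modulus estimate used for classification.
local_slope <- function(strain, stress, w) {
  n <- length(strain)
  k <- max(2L, w %/% 2L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    x <- strain[lo:hi]; y <- stress[lo:hi]
    xc <- x - mean(x)
    out[i] <- sum(xc * y) / sum(xc * xc)
  }
  out
}

# internal: fitted value of the same local linear regression at each sample
# (used to pin continuity points without inheriting single-sample noise)
local_fit <- function(strain, stress, w) {
  n <- length(strain)
  k <- max(2L, w %/% 2L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    x <- strain[lo:hi]; y <- stress[lo:hi]
    xc <- x - mean(x)
    b <- sum(xc * y) / sum(xc * xc)
    out[i] <- mean(y) + b * (strain[i] - mean(x))
  }
  out
}

# internal: centered moving average with shrinking edge windows
movavg <- function(v, w) {
  n <- length(v)
  k <- w %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# internal: isotonic fits (increasing / decreasing) as plain vectors
iso_inc <- function(v) stats::isoreg(v)$yf
iso_dec <- function(v) -stats::isoreg(-v)$yf

# internal: best piecewise-isotonic decreasing-increasing-decreasing fit of
# a series, over a grid of candidate split points. The three archetype
# modulus trends are all special cases of this shape (with empty phases),
# so the fitted phase amplitudes give a noise-robust read of the sign
# pattern of the modulus derivative.
dud_shape_fit <- function(v, ngrid = 40L) {
  n <- length(v)
  cand <- unique(round(seq(1L, n, length.out = min(ngrid, n))))
  pre <- lapply(cand, function(s) if (s > 1) iso_dec(v[1:s]) else numeric(0))
  suf <- lapply(cand, function(s) if (s < n) iso_dec(v[s:n]) else numeric(0))
  best <- NULL; bestrss <- Inf
  for (i1 in seq_along(cand)) {
    for (i2 in i1:length(cand)) {
      s1 <- cand[i1]; s2 <- cand[i2]
      f2 <- iso_inc(v[s1:s2])
      fit <- c(if (s1 > 1) pre[[i1]][-s1] else numeric(0),
               f2,
               if (s2 < n) suf[[i2]][-1] else numeric(0))
      rss <- sum((v - fit)^2)
      if (rss < bestrss) {
        bestrss <- rss
        best <- list(s1 = s1, s2 = s2, fit = fit, rss = rss)
      }
    }
  }
  best
}

# internal: noise standard deviation of the smoothed tangent-modulus trend.
# The local-slope estimator followed by the moving average is one linear
# filter of the stress samples, so its noise sd is the stress noise times
# the filter's coefficient norm.
trend_noise_sd <- function(stress_noise_sd, w, M, h) {
  k <- w %/% 2L
  c0 <- (-k:k) / (sum(((-k):k)^2) * h)
  if (M < 2) return(stress_noise_sd * sqrt(sum(c0^2)))
  Mh <- M %/% 2L
  g <- rep(0, 2 * (k + Mh) + 1L)
  for (s in -Mh:Mh) {
    idx <- (s + Mh) + seq_along(c0)
    g[idx] <- g[idx] + c0 / (2 * Mh + 1)
  }
  stress_noise_sd * sqrt(sum(g^2))
}

#' Classify a stress-strain curve into one of the three archetypes
#'
#' Estimates the tangent modulus by a local linear regression over a moving
#' window (plus a second moving-average pass), then reads the sign pattern
#' of the modulus trend from its best piecewise-isotonic
#' decreasing-increasing-decreasing approximation: phases whose fitted
#' amplitude is below a noise-based tolerance are treated as absent.
#' Monotone decreasing -> `"Z_ONLY"`; increasing then decreasing ->
#' `"F_THEN_Z"` with the second inflection point IF2 at the modulus
#' maximum; decreasing-increasing-decreasing -> `"Z_F_Z"` with IF1 at the
#' modulus minimum and IF2 at the subsequent maximum. A trend that ends
#' stiffening (no final softening phase while a toe rise is present) is
#' outside the taxonomy and raises a classification failure.
#'
#' Anchor indices are refined to the extremum of the single-pass modulus
#' estimate near each phase boundary; on effectively noise-free data they
#' are refined once more on raw central differences, which are exact at a
#' segment join.
#'
#' @param curve a truncated [stress_strain_curve()] with >= 50 samples.
#' @param config a [run_config()]; `smoothing_window` defaults to 5% of the
#'   samples (at least 5).
#' @param noise_multiple amplitude tolerance for a phase to count as
#'   present, in multiples of the trend's noise standard deviation (which
#'   is computed exactly from the smoothing filter and the stress noise
#'   estimated via second differences).
#' @param shape_grid number of candidate split points for the
#'   piecewise-isotonic shape fit.
#' @return list with `curve_type`, candidate anchors `strain_if1`,
#'   `strain_if2` and their sample indices `index_if1`, `index_if2` (`NA`
#'   where not applicable), the smoothed `modulus` trace, the fitted
#'   phase `amplitudes`, and the `tolerance` used.
#' @export
classify_curve <- function(curve, config = run_config(),
                           noise_multiple = 5, shape_grid = 40L) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  n <- length(curve$strain)
  if (n < 50) stop("classification needs at least 50 samples")
  w <- config$smoothing_window
  if (is.null(w)) w <- max(5L, round(0.05 * n))
  if (w %% 2 == 0) w <- w + 1L
  em <- local_slope(curve$strain, curve$stress, w)
  ems <- movavg(em, 2L * w)
  noise_hat <- sqrt(mean(diff(curve$stress, differences = 2)^2) / 6)
  h <- stats::median(diff(curve$strain))
  tol <- noise_multiple * trend_noise_sd(noise_hat, w, 2L * w, h)
  shp <- dud_shape_fit(ems, shape_grid)
  amp_down1 <- shp$fit[1] - shp$fit[shp$s1]
  amp_up <- shp$fit[shp$s2] - shp$fit[shp$s1]
  amp_down2 <- shp$fit[shp$s2] - shp$fit[n]
  # anchor refinement near the fitted phase boundaries
  raw_ok <- noise_hat < 1e-4 * diff(range(curve$stress))
  # forward differences locate a modulus jump exactly at the join sample
  raw_mod <- if (raw_ok) {
    c(diff(curve$stress) / diff(curve$strain), NA)
  } else NULL
  refine <- function(i0, what) {
    pick <- if (what == "max") which.max else which.min
    lo <- max(1L, i0 - w); hi <- min(n, i0 + w)
    i1 <- (lo:hi)[pick(em[lo:hi])]
    if (raw_ok) {
      lo2 <- max(1L, i1 - w %/% 2L); hi2 <- min(n - 1L, i1 + w %/% 2L)
      i1 <- (lo2:hi2)[pick(raw_mod[lo2:hi2])]
    }
    i1
  }
  res <- list(curve_type = NA_character_,
              strain_if1 = NA_real_, strain_if2 = NA_real_,
              index_if1 = NA_integer_, index_if2 = NA_integer_,
              modulus = em, window = w,
              amplitudes = c(down1 = amp_down1, up = amp_up,
                             down2 = amp_down2),
              tolerance = tol)
  if (amp_up <= tol || (amp_down2 <= tol && amp_up <= 3 * tol)) {
    # no toe rise, or a near-tolerance blip with no softening after it
    res$curve_type <- "Z_ONLY"
  } else if (amp_down2 <= tol) {
    stop(sprintf("classification failure: modulus trend ends stiffening (toe rise %.3g MPa with no final softening above tolerance %.3g MPa), outside the curve taxonomy",
                 amp_up, tol))
  } else if (amp_down1 <= tol) {
    res$curve_type <- "F_THEN_Z"
    res$index_if2 <- refine(shp$s2, "max")
    res$strain_if2 <- curve$strain[res$index_if2]
  } else {
    res$curve_type <- "Z_F_Z"
    res$index_if1 <- refine(shp$s1, "min")
    res$index_if2 <- refine(shp$s2, "max")
    if (res$index_if2 <= res$index_if1) res$index_if2 <- shp$s2
    res$strain_if1 <- curve$strain[res$index_if1]
    res$strain_if2 <- curve$strain[res$index_if2]
  }
  res
}

#' Locally smoothed stress of a curve
#'
#' Fitted values of a local linear regression of stress on strain over a
#' centered moving window: the stress estimate used to pin continuity
#' points on noisy curves (single-sample noise would otherwise propagate
#' into every constrained segment fit).
#'
#' @param curve a [stress_strain_curve()].
#' @param window window size in samples; `NULL` uses 5% of the samples (at
#'   least 5), the same default as the transition-point search.
#' @return numeric vector of smoothed stress values, MPa.
#' @export
smooth_stress <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  n <- length(curve$strain)
  if (is.null(window)) window <- max(5L, round(0.05 * n))
  local_fit(curve$strain, curve$stress, window)
}

#' Iterative backward search for the transition point
#'
#' Scans candidate samples backward from the second inflection point toward
#' the first (bounded below at IF1 plus `tp_lower_bound_fraction` of the
#' span, to prevent collapse onto IF1). At each candidate p the toe model
#' is refit on `[origin, p]` with the continuity condition through
#' `(strain_p, stress_p)` (so it interpolates the candidate exactly) and
#' the tail Z-Model is refit translated to the same point; the candidate
#' minimising the tangent-modulus gap `|E_F(p) - E_Z(p)|` is the
#' transition point. The returned stress is the fitted stress at p (equal
#' to the measured one by the continuity construction).
#'
#' @param curve a truncated [stress_strain_curve()].
#' @param index_if2 sample index of the second inflection point.
#' @param origin `c(strain, stress)` origin of the toe model (IF1 join for
#'   three-segment curves, `(0, 0)` otherwise).
#' @param index_if1 sample index of IF1 (1 when the toe starts at the
#'   origin).
#' @param config a [run_config()].
#' @return list with `index_tp`, `strain_tp`, `stress_tp`, the winning
#'   segment fits `f_fit` and `z_fit`, the per-candidate `scores` (named by
#'   index) and `fallback` (TRUE when the candidate set was empty and IF2
#'   was returned).
#' @export
find_transition_point <- function(curve, index_if2, origin = c(0, 0),
                                  index_if1 = 1L, config = run_config()) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  eps <- curve$strain; sig <- curve$stress
  n <- length(eps)
  if (index_if2 >= n) stop("IF2 must be interior to the data")
  # pin continuity points to the locally smoothed stress when the curve is
  # noisy; raw samples are exact when it is not
  noise_hat <- sqrt(mean(diff(sig, differences = 2)^2) / 6)
  if (noise_hat < 1e-4 * diff(range(sig))) {
    sig_pin <- sig
  } else {
    w <- config$smoothing_window
    if (is.null(w)) w <- max(5L, round(0.05 * n))
    sig_pin <- local_fit(eps, sig, w)
  }
  span <- eps[index_if2] - eps[index_if1]
  lb <- eps[index_if1] + config$tp_lower_bound_fraction * span
  o_i <- index_if1
  cand <- which(eps >= lb & seq_len(n) <= index_if2 &
                  seq_len(n) - o_i + 1 >= 8 &
                  n - seq_len(n) + 1 >= 10)
  cand <- cand[sig_pin[cand] > origin[2]]
  eval_candidate <- function(p, min_f = 8L, min_z = 10L) {
    ft <- tryCatch(
      fit_f(eps[o_i:p], sig[o_i:p], origin = origin,
            continuity = c(eps[p], sig_pin[p]), min_samples = min_f),
      error = function(e) NULL)
    zt <- tryCatch(
      fit_z(eps[p:n], sig[p:n], origin = c(eps[p], sig_pin[p]),
            segment = "final", min_samples = min_z),
      error = function(e) NULL)
    if (is.null(ft) || is.null(zt)) return(NULL)
    list(f = ft, z = zt,
         score = abs(f_tangent_modulus(ft, eps[p]) - zt$modulus_0))
  }
  if (length(cand) == 0) {
    warning("empty transition-point candidate set; falling back to IF2")
    p <- index_if2
    res <- eval_candidate(p, min_f = 3L, min_z = 5L)
    if (is.null(res)) stop("transition-point fallback fit failed at IF2")
    return(list(index_tp = p, strain_tp = eps[p], stress_tp = sig_pin[p],
                f_fit = res$f, z_fit = res$z,
                scores = stats::setNames(res$score, p), fallback = TRUE))
  }
  scores <- rep(NA_real_, length(cand))
  fits <- vector("list", length(cand))
  for (j in rev(seq_along(cand))) {  # backward scan from IF2
    res <- eval_candidate(cand[j])
    if (!is.null(res)) { scores[j] <- res$score; fits[[j]] <- res }
  }
  if (all(is.na(scores))) stop("every transition-point candidate fit failed")
  jbest <- which.min(scores)
  p <- cand[jbest]
  list(index_tp = p, strain_tp = eps[p], stress_tp = sig_pin[p],
       f_fit = fits[[jbest]]$f, z_fit = fits[[jbest]]$z,
       scores = stats::setNames(scores, cand), fallback = FALSE)
}

#' Fit the composite constitutive model to a curve
#'
#' Classifies the curve (unless a type and anchors are supplied), then fits
#' the model sequence with stress continuity imposed at every join:
#' \itemize{
#'   \item `Z_ONLY`: a single Z-Model over the whole truncated curve.
#'   \item `F_THEN_Z`: toe F-Model from the origin, transition-point search
#'     below IF2, then the tail Z-Model translated to the transition point.
#'   \item `Z_F_Z`: initial Z-Model up to IF1; F-Model translated to the
#'     IF1 join (continuity by construction); transition-point search; tail
#'     Z-Model translated to the transition point.
#' }
#' Both toe-adjacent segments are refit at the chosen transition point, so
#' the reported parameters correspond to the reported anchor. The modulus
#' at the transition point is reported as the mean of the F-side and Z-side
#' tangent moduli there (they differ by the minimised slope gap).
#'
#' @param curve a [stress_strain_curve()]; truncated internally if needed.
#' @param config a [run_config()].
#' @param curve_type optional override of the classification.
#' @param anchors optional override of the anchor indices, a list with
#'   `index_if1` and/or `index_if2`.
#' @return An object of class `composite_fit`.
#' @export
fit_composite <- function(curve, config = run_config(), curve_type = NULL,
                          anchors = NULL) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (!isTRUE(curve$truncated)) curve <- truncate_at_limit(curve)
  eps <- curve$strain; sig <- curve$stress
  n <- length(eps)
  if (is.null(curve_type)) {
    cls <- classify_curve(curve, config)
    curve_type <- cls$curve_type
    i1 <- cls$index_if1; i2 <- cls$index_if2
  } else {
    curve_type <- match.arg(curve_type, c("Z_ONLY", "F_THEN_Z", "Z_F_Z"))
    i1 <- NA_integer_; i2 <- NA_integer_
  }
  if (!is.null(anchors)) {
    if (!is.null(anchors$index_if1)) i1 <- anchors$index_if1
    if (!is.null(anchors$index_if2)) i2 <- anchors$index_if2
  }
  out <- list(specimen_id = curve$specimen_id, curve_type = curve_type,
              stress_basis = curve$stress_basis,
              strain_limit = curve$strain_limit)

  if (curve_type == "Z_ONLY") {
    zf <- with_segment_error("whole Z segment",
                             fit_z(eps, sig, origin = c(0, 0)))
    out <- c(out, list(
      z_whole = zf, total_rss = zf$rss,
      modulus_0 = zf$modulus_0, modulus_lin = zf$modulus_lin))
    class(out) <- "composite_fit"
    return(out)
  }

  if (curve_type == "F_THEN_Z") {
    if (is.na(i2)) stop("F_THEN_Z fitting needs an IF2 anchor")
    origin <- c(0, 0); o_i <- 1L
    out$strain_if2 <- eps[i2]; out$stress_if2 <- sig[i2]
  } else {
    if (is.na(i1) || is.na(i2)) stop("Z_F_Z fitting needs IF1 and IF2 anchors")
    zi <- with_segment_error(
      "initial Z segment",
      fit_z(eps[1:i1], sig[1:i1], origin = c(0, 0), segment = "initial"))
    sig_if1 <- z_eval(zi, eps[i1])
    origin <- c(eps[i1], sig_if1); o_i <- i1
    out$z_initial <- zi
    out$strain_if1 <- eps[i1]; out$stress_if1 <- sig_if1
    out$strain_if2 <- eps[i2]; out$stress_if2 <- sig[i2]
  }

  tp <- with_segment_error(
    "transition-point search",
    find_transition_point(curve, index_if2 = i2, origin = origin,
                          index_if1 = o_i, config = config))
  ff <- tp$f_fit; zf <- tp$z_fit
  out$f_toe <- ff
  out$z_final <- zf
  out$strain_tp <- tp$strain_tp
  out$stress_tp <- tp$stress_tp
  out$tp_fallback <- tp$fallback

  e_f_tp <- f_tangent_modulus(ff, tp$strain_tp)
  e_tp <- mean(c(e_f_tp, zf$modulus_0))
  out$modulus_0 <- if (curve_type == "Z_F_Z") out$z_initial$modulus_0 else
    ff$modulus_0
  out$modulus_if1 <- if (curve_type == "Z_F_Z") ff$modulus_0 else NA_real_
  out$modulus_tp <- e_tp
  out$modulus_lin <- zf$modulus_lin
  out$softening_ratio_initial <- if (curve_type == "Z_F_Z") {
    (out$modulus_if1 - out$modulus_0) / out$modulus_0
  } else NA_real_
  out$stiffening_ratio_toe <- (e_tp - ff$modulus_0) / ff$modulus_0
  out$softening_ratio_final <- (zf$modulus_lin - e_tp) / e_tp
  out$total_rss <- sum(c(if (curve_type == "Z_F_Z") out$z_initial$rss,
                         ff$rss, zf$rss), na.rm = TRUE)
  class(out) <- "composite_fit"
  out
}

# internal: re-raise a fit failure naming the segment
with_segment_error <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s failed: %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.composite_fit <- function(x, ...) {
  cat(sprintf("Composite fit '%s' (%s, %s stress)\n",
              x$specimen_id, x$curve_type, x$stress_basis))
  if (x$curve_type == "Z_ONLY") {
    print(x$z_whole)
  } else {
    if (x$curve_type == "Z_F_Z") {
      cat(sprintf("  IF1 at (%.4g, %.4g MPa)\n", x$strain_if1, x$stress_if1))
    }
    cat(sprintf("  TP at (%.4g, %.4g MPa); IF2 at (%.4g, %.4g MPa)\n",
                x$strain_tp, x$stress_tp, x$strain_if2, x$stress_if2))
    cat(sprintf("  E_0 = %.4g, E_TP = %.4g, E_lin = %.4g MPa\n",
                x$modulus_0, x$modulus_tp, x$modulus_lin))
  }
  cat(sprintf("  total RSS = %.4g MPa^2\n", x$total_rss))
  invisible(x)
}

#' Flat parameter record of a composite fit
#'
#' One named row covering every reported symbol applicable to the curve
#' type, with stiffness-variation ratios as percentages. Strain anchors are
#' dimensionless, stresses and moduli in MPa.
#'
#' @param fit a [fit_composite()] result.
#' @return named list of numerics with attribute `specimen_id`; suitable
#'   for [write_results()].
#' @export
report_table <- function(fit) {
  stopifnot(inherits(fit, "composite_fit"))
  if (fit$curve_type == "Z_ONLY") {
    z <- fit$z_whole
    rec <- list(a_z = z$a, b_z = z$b, c_z = z$c,
                modulus_0 = z$modulus_0, modulus_lin = z$modulus_lin,
                strain_knee = z$strain_knee,
                softening_pct = 100 * z$softening_ratio)
  } else {
    rec <- list(
      strain_if1 = fit$strain_if1 %||% NA_real_,
      stress_if1 = fit$stress_if1 %||% NA_real_,
      strain_tp = fit$strain_tp, stress_tp = fit$stress_tp,
      strain_if2 = fit$strain_if2, stress_if2 = fit$stress_if2,
      a_z_initial = if (!is.null(fit$z_initial)) fit$z_initial$a else NA_real_,
      b_z_initial = if (!is.null(fit$z_initial)) fit$z_initial$b else NA_real_,
      c_z_initial = if (!is.null(fit$z_initial)) fit$z_initial$c else NA_real_,
      B_f = fit$f_toe$B, C_f = fit$f_toe$C,
      a_z_final = fit$z_final$a, b_z_final = fit$z_final$b,
      c_z_final = fit$z_final$c,
      modulus_0 = fit$modulus_0, modulus_if1 = fit$modulus_if1,
      modulus_tp = fit$modulus_tp, modulus_lin = fit$modulus_lin,
      strain_knee_initial = if (!is.null(fit$z_initial))
        fit$z_initial$strain_knee else NA_real_,
      strain_knee_final = fit$z_final$strain_knee,
      softening_initial_pct = 100 * fit$softening_ratio_initial,
      stiffening_toe_pct = 100 * fit$stiffening_ratio_toe,
      softening_final_pct = 100 * fit$softening_ratio_final)
  }
  attr(rec, "specimen_id") <- fit$specimen_id
  rec
}

#' Predict stress from a composite fit
#'
#' Evaluates the fitted segment models over their own domains, giving a
#' stress prediction continuous across the joins.
#'
#' @param object a `composite_fit`.
#' @param strain strain values within the fitted range.
#' @param ... unused.
#' @return stress in MPa.
#' @export
predict.composite_fit <- function(object, strain, ...) {
  if (object$curve_type == "Z_ONLY") return(z_eval(object$z_whole, strain))
  out <- numeric(length(strain))
  tp <- object$strain_tp
  if (object$curve_type == "Z_F_Z") {
    if1 <- object$strain_if1
    seg1 <- strain < if1
    out[seg1] <- z_eval(object$z_initial, strain[seg1])
  } else {
    if1 <- -Inf
    seg1 <- logical(length(strain))
  }
  seg2 <- !seg1 & strain < tp
  seg3 <- !seg1 & !seg2
  f <- object$f_toe; f$strain_tp <- NA_real_  # allow eval up to tp inclusive
  out[seg2] <- f_eval(f, strain[seg2])
  out[seg3] <- z_eval(object$z_final, strain[seg3])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
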