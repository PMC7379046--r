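#' Failure point of a curve
#'
#' The failure stress is the highest stress in the entire curve; ties are
#' broken at the first occurrence. When the basis is apparent and an area is
#' supplied, the failure force F_F = sigma_F * A is also reported.
#'
#' @param curve a [stress_strain_curve()] (pre-truncation allowed).
#' @param area_mm2 optional cross-sectional area for the failure force.
#' @return list with `stress_f` (MPa), `strain_f`, `force_f` (N or `NA`).
#' @export
failure_point <- function(curve, area_mm2 = NA_real_) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  i <- which.max(curve$stress)
  force <- if (!is.na(area_mm2) && curve$stress_basis == "apparent") {
    curve$stress[i] * area_mm2
  } else NA_real_
  list(stress_f = curve$stress[i], strain_f = curve$strain[i], force_f = force)
}

#' Offset-yield point and elastic modulus
#'
#' Implements the 0.001-strain offset criterion: (1) a provisional linear
#' regression from `fit_start` over the initial window (ending where stress
#' first reaches `window_fraction` of the failure stress); (2) a parallel
#' line shifted by `+offset` strain; (3) the yield point is the first
#' intersection of that line with the curve, located by piecewise-linear
#' interpolation between samples; (4) the elastic modulus E is the slope of
#' a final regression from `fit_start` to the yield sample.
#'
#' If the offset line never re-intersects the curve before failure (an
#' exactly linear curve, say) the yield is undefined: `stress_y`/`strain_y`
#' are `NA`, `yield_defined` is `FALSE`, and E is still reported from the
#' provisional window.
#'
#' @param curve a truncated [stress_strain_curve()].
#' @param fit_start 1-based index where the elastic regression starts
#'   (from [toe_disregard_start()]; 1 for random specimens with no toe).
#' @param offset strain offset (default 0.001).
#' @param window_fraction the provisional regression window ends where the
#'   stress has climbed this fraction of the way from the window-start
#'   stress to the failure stress (default 0.10, inside the quasi-linear
#'   region for all five specimen classes).
#' @return list with `stress_y`, `strain_y`, `modulus` (E, MPa),
#'   `yield_index` (last sample before the crossing), `yield_defined`.
#' @export
offset_yield <- function(curve, fit_start = 1L, offset = 0.001,
                         window_fraction = 0.10) {
  stopifnot(inherits(curve, "stress_strain_curve"), offset > 0)
  eps <- curve$strain; sig <- curve$stress
  n <- length(eps)
  sigma_f <- max(sig)
  thr <- sig[fit_start] + window_fraction * (sigma_f - sig[fit_start])
  win_end <- which(sig >= thr & seq_len(n) > fit_start)[1]
  if (is.na(win_end) || win_end - fit_start < 2) {
    win_end <- min(n, fit_start + max(2L, floor(0.1 * n)))
  }
  idx <- fit_start:win_end
  prov <- stats::lm.fit(cbind(1, eps[idx]), sig[idx])
  m <- prov$coefficients[2]; q <- prov$coefficients[1]
  # offset line: same slope, shifted right by `offset` strain
  line <- m * (eps - offset) + q
  gap <- sig - line
  # search beyond the provisional window for the first downward crossing
  cross <- NULL
  for (i in seq(max(win_end, fit_start + 1L), n - 1L)) {
    if (gap[i] > 0 && gap[i + 1] <= 0) { cross <- i; break }
  }
  if (is.null(cross)) {
    return(list(stress_y = NA_real_, strain_y = NA_real_,
                modulus = unname(m), yield_index = NA_integer_,
                yield_defined = FALSE))
  }
  # linear interpolation of the sign change of (curve - offset line)
  t <- gap[cross] / (gap[cross] - gap[cross + 1])
  strain_y <- eps[cross] + t * (eps[cross + 1] - eps[cross])
  stress_y <- m * (strain_y - offset) + q
  idx2 <- fit_start:cross
  e_final <- if (length(idx2) >= 2) {
    stats::lm.fit(cbind(1, eps[idx2]), sig[idx2])$coefficients[2]
  } else m
  list(stress_y = unname(stress_y), strain_y = unname(strain_y),
       modulus = unname(e_final), yield_index = cross,
       yield_defined = TRUE)
}

#' Asymptotic stiffness
#'
#' Least-squares slope of the stress-strain curve between the yield sample
#' and the failure sample: the stiffness of the post-yield, pre-failure
#' (ductile/asymptotic) portion of the curve.
#'
#' @param curve a [stress_strain_curve()].
#' @param from 1-based index of the yield sample.
#' @param to 1-based index of the failure sample (default: global stress
#'   maximum).
#' @return slope in MPa.
#' @export
asymptotic_stiffness <- function(curve, from, to = which.max(curve$stress)) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (to - from + 1 < 3) stop("need at least 3 samples between yield and failure")
  idx <- from:to
  unname(stats::lm.fit(cbind(1, curve$strain[idx]),
                       curve$stress[idx])$coefficients[2])
}

#' Strain-energy density up to a strain (trapezoid rule)
#'
#' Area under the stress-strain curve up to `upto`, by the method of
#' trapezoids over the samples with strain <= `upto` plus a linearly
#' interpolated terminal sliver. Stored in MPa * strain, i.e. MJ/m^3.
#'
#' @param curve a [stress_strain_curve()].
#' @param upto upper strain bound (<= the curve's strain limit).
#' @return unit work L in MPa.
#' @export
unit_work <- function(curve, upto) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  eps <- curve$strain; sig <- curve$stress
  if (upto < eps[1]) return(0)
  k <- findInterval(upto, eps)
  w <- if (k >= 2) sum(diff(eps[1:k]) * (sig[1:(k - 1)] + sig[2:k]) / 2) else 0
  if (k < length(eps) && upto > eps[k]) {
    t <- (upto - eps[k]) / (eps[k + 1] - eps[k])
    sig_up <- sig[k] + t * (sig[k + 1] - sig[k])
    w <- w + (upto - eps[k]) * (sig[k] + sig_up) / 2
  }
  w
}

#' Extract the full set of classical mechanical indicators
#'
#' Runs the complete indicator protocol on one curve: failure point, toe
#' disregard, 0.001-offset yield, elastic modulus, asymptotic stiffness and
#' the unit works to yield and to failure.
#'
#' @param curve a [stress_strain_curve()] (it is truncated internally at the
#'   failure strain).
#' @param geom optional [specimen_geometry()]; supplies the area for the
#'   failure force and the class default toe fraction.
#' @param config a [run_config()].
#' @return one-row `data.frame` with columns `specimen_id`, `stress_basis`,
#'   `stress_y`, `strain_y`, `modulus`, `asymptotic_stiffness`, `force_f`,
#'   `stress_f`, `strain_f`, `work_to_yield`, `work_to_failure`,
#'   `yield_defined`.
#' @export
extract_indicators <- function(curve, geom = NULL, config = run_config()) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  area <- if (!is.null(geom)) geom$area_mm2 else NA_real_
  fp <- failure_point(curve, area)
  tr <- truncate_at_limit(curve)
  frac <- config$toe_disregard_fraction
  if (is.null(frac)) {
    frac <- if (!is.null(geom)) default_toe_fraction(geom$specimen_class) else 0
  }
  start <- toe_disregard_start(tr, frac)
  oy <- offset_yield(tr, fit_start = start, offset = config$offset_strain,
                     window_fraction = config$yield_window_fraction)
  as_stiff <- if (oy$yield_defined &&
                  length(tr$strain) - oy$yield_index + 1 >= 3) {
    asymptotic_stiffness(tr, from = oy$yield_index)
  } else NA_real_
  ly <- if (oy$yield_defined) unit_work(tr, oy$strain_y) else NA_real_
  lf <- unit_work(tr, fp$strain_f)
  data.frame(specimen_id = curve$specimen_id,
             stress_basis = curve$stress_basis,
             stress_y = oy$stress_y, strain_y = oy$strain_y,
             modulus = oy$modulus, asymptotic_stiffness = as_stiff,
             force_f = fp$force_f, stress_f = fp$stress_f,
             strain_f = fp$strain_f,
             work_to_yield = ly, work_to_failure = lf,
             yield_defined = oy$yield_defined,
             stringsAsFactors = FALSE)
}

#' Cohort mean and standard deviation of indicators
#'
#' Per-class mean and sample standard deviation (n - 1 denominator) of every
#' numeric indicator column, the format in which cohort tables are reported.
#' All rows must share one stress basis.
#'
#' @param indicators data frame of per-specimen indicator rows (e.g. bound
#'   [extract_indicators()] outputs), with a `specimen_class` column or a
#'   single implicit class.
#' @return data frame with one row per (class, indicator) giving `mean`,
#'   `sd` and `n`; `sd` is 0 when n = 1.
#' @export
summarize_cohort <- function(indicators) {
  stopifnot(is.data.frame(indicators), nrow(indicators) >= 1)
  if ("stress_basis" %in% names(indicators) &&
      length(unique(indicators$stress_basis)) > 1) {
    stop("mixed stress bases in one cohort summary")
  }
  cls <- if ("specimen_class" %in% names(indicators)) {
    indicators$specimen_class
  } else rep("all", nrow(indicators))
  num_cols <- names(indicators)[vapply(indicators, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(split(seq_len(nrow(indicators)), cls), function(idx) {
    do.call(rbind, lapply(num_cols, function(cn) {
      v <- indicators[[cn]][idx]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      data.frame(specimen_class = cls[idx[1]], indicator = cn,
                 mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
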