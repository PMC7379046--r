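#' Specimen geometry and volume fraction
#'
#' Dimensions and weight of a tensile specimen, from which the solid volume
#' fraction v = w / (L * A * rho) is computed. For porous fibrous specimens
#' v is well below 1; net stress divides apparent stress by v.
#'
#' @param gauge_length_mm gauge length L, mm.
#' @param area_mm2 cross-sectional area A, mm^2 (total, including pores).
#' @param weight_mg specimen weight w, mg.
#' @param density_mg_mm3 raw-material density rho, mg/mm^3 (the polyurethane
#'   used for the reference structures has rho = 1.18).
#' @param specimen_class one of [specimen_classes()].
#' @return An object of class `specimen_geometry`.
#' @export
specimen_geometry <- function(gauge_length_mm, area_mm2, weight_mg,
                              density_mg_mm3 = 1.18,
                              specimen_class = "random_mat") {
  specimen_class <- match.arg(specimen_class, specimen_classes())
  vals <- c(gauge_length_mm, area_mm2, weight_mg, density_mg_mm3)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be strictly positive and finite")
  }
  g <- structure(
    list(gauge_length_mm = gauge_length_mm, area_mm2 = area_mm2,
         weight_mg = weight_mg, density_mg_mm3 = density_mg_mm3,
         specimen_class = specimen_class),
    class = "specimen_geometry"
  )
  v <- volume_fraction(g)
  if (v > 1) warning(sprintf("volume fraction %.3f > 1: check weight/dimensions", v))
  g
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf("Specimen geometry (%s): L = %g mm, A = %g mm^2, w = %g mg, rho = %g mg/mm^3, v = %.3f\n",
              x$specimen_class, x$gauge_length_mm, x$area_mm2, x$weight_mg,
              x$density_mg_mm3, volume_fraction(x)))
  invisible(x)
}

#' Solid volume fraction of a specimen
#'
#' v = w / (L * A * rho): the fraction of the nominal specimen volume
#' occupied by solid material. Linear in the weight; a fully dense specimen
#' has v = 1.
#'
#' @param geom a [specimen_geometry()].
#' @return dimensionless volume fraction.
#' @export
volume_fraction <- function(geom) {
  stopifnot(inherits(geom, "specimen_geometry"))
  geom$weight_mg /
    (geom$gauge_length_mm * geom$area_mm2 * geom$density_mg_mm3)
}

#' Convert a force-displacement record to an apparent stress-strain curve
#'
#' Engineering strain is displacement over gauge length; apparent stress is
#' force over the (total) cross-sectional area. Samples sharing a strain
#' value are collapsed by averaging their stress so strain is strictly
#' increasing.
#'
#' @param record a [tensile_record()] of kind `force_displacement` (a
#'   `stress_strain` record is passed through, re-validated).
#' @param geom a [specimen_geometry()].
#' @return A [stress_strain_curve()] on the apparent basis.
#' @export
to_stress_strain <- function(record, geom) {
  stopifnot(inherits(record, "tensile_record"),
            inherits(geom, "specimen_geometry"))
  if (record$sample_kind == "stress_strain") {
    return(stress_strain_curve(record$x, record$y,
                               specimen_id = record$specimen_id,
                               stress_basis = "apparent"))
  }
  if (geom$gauge_length_mm <= 0 || geom$area_mm2 <= 0) {
    stop("gauge length and area must be positive")
  }
  stress_strain_curve(record$x / geom$gauge_length_mm,
                      record$y / geom$area_mm2,
                      specimen_id = record$specimen_id,
                      stress_basis = "apparent")
}

#' Convert apparent stress to net stress
#'
#' Divides the apparent stress pointwise by the solid volume fraction,
#' yielding the stress carried by the material itself (porosity removed).
#' Multiplying the result by `v` recovers the apparent curve exactly.
#'
#' @param curve an apparent-basis [stress_strain_curve()].
#' @param v volume fraction in (0, 1], or a [specimen_geometry()] from which
#'   it is computed.
#' @return A net-basis [stress_strain_curve()].
#' @export
to_net <- function(curve, v) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (inherits(v, "specimen_geometry")) v <- volume_fraction(v)
  if (!is.finite(v) || v <= 0) stop("volume fraction must be positive")
  if (curve$stress_basis != "apparent") {
    stop("to_net expects an apparent-basis curve")
  }
  curve$stress <- curve$stress / v
  curve$stress_basis <- "net"
  curve
}

#' Truncate a curve at the analysis strain limit
#'
#' The analysis limit is the strain at the global stress maximum (the
#' failure-stress definition), so the fitted portion ends where the specimen
#' starts to fail. A monotonically rising curve with no interior peak is
#' returned unchanged with `truncated = FALSE` recorded and attribute
#' `no_interior_peak` set.
#'
#' @param curve a [stress_strain_curve()].
#' @return the truncated curve; its `strain_limit` records the cut.
#' @export
truncate_at_limit <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  peak <- which.max(curve$stress)  # first occurrence on ties
  flag <- peak == length(curve$stress)
  out <- curve_slice(curve, seq_len(peak))
  out$strain_limit <- curve$strain[peak]
  out$truncated <- TRUE
  attr(out, "no_interior_peak") <- flag
  out
}

#' First sample index past the toe-disregard threshold
#'
#' Returns the first sample whose stress reaches `fraction` of the failure
#' stress (the curve's global maximum). Used only on the indicator path:
#' model fitting always uses the full curve. Non-decreasing in `fraction`.
#'
#' @param curve a [stress_strain_curve()].
#' @param fraction fraction of failure stress in `[0, 0.5)`.
#' @return integer sample index (1-based).
#' @export
toe_disregard_start <- function(curve, fraction) {
  stopifnot(inherits(curve, "stress_strain_curve"),
            fraction >= 0, fraction < 0.5)
  if (fraction == 0) return(1L)
  sigma_f <- max(curve$stress)
  idx <- which(curve$stress >= fraction * sigma_f)
  if (length(idx) == 0) stop("toe threshold above every sample")
  idx[1]
}
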