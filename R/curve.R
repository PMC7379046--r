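#' Stress-strain curve for one specimen
#'
#' Container for the ordered strain/stress samples of a single tensile test on
#' one stress basis. Strain is dimensionless (mm/mm) throughout; stress is in
#' MPa. Apparent stress is force over the total cross-section; net stress is
#' apparent stress divided by the solid volume fraction, removing porosity
#' from the stress measure.
#'
#' @param strain numeric vector, dimensionless, non-decreasing.
#' @param stress numeric vector, MPa, same length as `strain`.
#' @param specimen_id character scalar.
#' @param stress_basis `"apparent"` or `"net"`.
#' @param strain_limit analysis strain limit; defaults to `max(strain)`.
#' @param collapse_duplicates collapse samples sharing a strain value by
#'   averaging their stress, so strain is strictly increasing.
#'
#' @return An object of class `stress_strain_curve`: a list with elements
#'   `specimen_id`, `strain`, `stress`, `stress_basis`, `strain_limit`,
#'   and `truncated` (logical, set by [truncate_at_limit()]).
#' @export
stress_strain_curve <- function(strain, stress, specimen_id = "specimen",
                                stress_basis = c("apparent", "net"),
                                strain_limit = NULL,
                                collapse_duplicates = TRUE) {
  stress_basis <- match.arg(stress_basis)
  strain <- as.numeric(strain)
  stress <- as.numeric(stress)
  if (length(strain) != length(stress)) {
    stop("strain and stress must have equal length")
  }
  if (any(!is.finite(strain)) || any(!is.finite(stress))) {
    stop("strain and stress must be finite")
  }
  if (any(diff(strain) < 0)) {
    stop("strain must be non-decreasing")
  }
  if (collapse_duplicates && anyDuplicated(strain)) {
    stress <- as.numeric(tapply(stress, match(strain, unique(strain)), mean))
    strain <- unique(strain)
  }
  if (is.null(strain_limit)) strain_limit <- max(strain)
  if (strain_limit > max(strain)) {
    stop("strain_limit cannot exceed the largest measured strain")
  }
  structure(
    list(specimen_id = as.character(specimen_id)[1],
         strain = strain, stress = stress,
         stress_basis = stress_basis,
         strain_limit = strain_limit,
         truncated = FALSE),
    class = "stress_strain_curve"
  )
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve '%s' (%s stress)\n",
              x$specimen_id, x$stress_basis))
  cat(sprintf("  %d samples, strain [%g, %g], stress [%g, %g] MPa\n",
              length(x$strain), min(x$strain), max(x$strain),
              min(x$stress), max(x$stress)))
  cat(sprintf("  strain limit %g%s\n", x$strain_limit,
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}

#' @export
as.data.frame.stress_strain_curve <- function(x, ...) {
  data.frame(strain = x$strain, stress = x$stress)
}

#' @export
length.stress_strain_curve <- function(x) length(x$strain)

# internal: subset a curve by sample index, keeping metadata
curve_slice <- function(curve, idx) {
  curve$strain <- curve$strain[idx]
  curve$stress <- curve$stress[idx]
  curve
}
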