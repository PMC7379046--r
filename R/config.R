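#' Run configuration for the analysis pipeline
#'
#' Collects the tunable settings of the indicator-extraction and
#' composite-fitting paths. Defaults follow the protocol used for
#' electrospun mats, bundles and hierarchical assemblies: the toe region is
#' disregarded (for indicator extraction only) up to 20% of the failure
#' stress for mats and bundles and 25% for hierarchical structures, and
#' yield is defined by a 0.001-strain offset criterion.
#'
#' @param stress_basis basis the pipeline analyses: `"apparent"`, `"net"` or
#'   `"both"`. Model fitting is conventionally run on net stress.
#' @param toe_disregard_fraction fraction of failure stress below which the
#'   toe is disregarded on the indicator path. `NULL` selects the class
#'   default (0.20 for mats/bundles, 0.25 for `hnes`, 0 for random classes
#'   with no toe).
#' @param offset_strain strain offset of the yield criterion (dimensionless).
#' @param yield_window_fraction the provisional elastic regression ends
#'   where the stress has climbed this fraction of the way from the
#'   window-start stress to the failure stress.
#' @param smoothing_window sample count of the moving-average window used to
#'   smooth the tangent-modulus estimate for curve classification. `NULL`
#'   uses 5% of the samples (at least 5, forced odd).
#' @param tp_lower_bound_fraction lower bound of the transition-point search,
#'   as a fraction of the span between the first and second inflection
#'   points (prevents collapse onto IF1).
#' @param seed integer seed for any stochastic step.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(stress_basis = c("net", "apparent", "both"),
                       toe_disregard_fraction = NULL,
                       offset_strain = 0.001,
                       yield_window_fraction = 0.10,
                       smoothing_window = NULL,
                       tp_lower_bound_fraction = 0.25,
                       seed = 20200716L) {
  stress_basis <- match.arg(stress_basis)
  if (!is.null(toe_disregard_fraction)) {
    stopifnot(toe_disregard_fraction >= 0, toe_disregard_fraction < 0.5)
  }
  stopifnot(offset_strain > 0,
            yield_window_fraction > 0, yield_window_fraction < 1,
            tp_lower_bound_fraction >= 0, tp_lower_bound_fraction < 1)
  structure(
    list(stress_basis = stress_basis,
         toe_disregard_fraction = toe_disregard_fraction,
         offset_strain = offset_strain,
         yield_window_fraction = yield_window_fraction,
         smoothing_window = smoothing_window,
         tp_lower_bound_fraction = tp_lower_bound_fraction,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Default toe-disregard fraction for a specimen class
#'
#' Mats and bundles of aligned fibers use 20% of the failure stress,
#' hierarchical structures (`hnes`) 25%; random classes show no toe region
#' and use 0.
#'
#' @param specimen_class one of `"random_mat"`, `"random_bundle"`,
#'   `"aligned_mat"`, `"aligned_bundle"`, `"hnes"`.
#' @return a fraction in `[0, 0.5)`.
#' @export
default_toe_fraction <- function(specimen_class) {
  switch(match.arg(specimen_class, specimen_classes()),
         random_mat = 0, random_bundle = 0,
         aligned_mat = 0.20, aligned_bundle = 0.20,
         hnes = 0.25)
}

#' Recognised specimen classes
#' @return character vector of class labels.
#' @export
specimen_classes <- function() {
  c("random_mat", "random_bundle", "aligned_mat", "aligned_bundle", "hnes")
}
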