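# Synthetic tensile curves with the statistical structure the analysis
# assumes: the three archetypal curve shapes evaluated forward with
# continuity enforced at every join, plus i.i.d. Gaussian stress noise.

# Archetype parameter sets on the net-stress basis, one per specimen class.
# Magnitudes follow the fitted cohorts of the reference electrospun
# polyurethane structures; volume fractions and gauge geometry follow the
# morphology of those cohorts. Strain limits sit below the cohort failure
# strains, at the end of the strain-softening region. The aligned-bundle
# IF1 strain is 0.10, the value consistent with that cohort's printed
# IF1 stress and initial-segment stiffness.
.archetypes <- list(
  random_mat = list(
    curve_type = "Z_ONLY",
    z_whole = c(a = 2.51, b = 1.13, c = 6.20),
    strain_limit = 2.2,
    geometry = list(gauge_length_mm = 45, area_mm2 = 0.372, v = 0.30),
    sd = list(z_whole = c(a = 0.09, b = 0.06, c = 0.28), v = 0.03)),
  random_bundle = list(
    curve_type = "Z_ONLY",
    z_whole = c(a = 1.82, b = 1.35, c = 6.93),
    strain_limit = 1.7,
    geometry = list(gauge_length_mm = 228, area_mm2 = 0.172, v = 0.32),
    sd = list(z_whole = c(a = 0.24, b = 0.16, c = 1.08), v = 0.02)),
  aligned_mat = list(
    curve_type = "F_THEN_Z",
    f_toe = c(B = 2.20, C = 15.8),
    z_final = c(a = 65.0, b = 5.98, c = 19.3),
    strain_if1 = NA_real_, strain_tp = 0.104, strain_limit = 0.45,
    geometry = list(gauge_length_mm = 40, area_mm2 = 0.284, v = 0.37),
    sd = list(f_toe = c(B = 0.12, C = 0.5),
              z_final = c(a = 2.3, b = 0.47, c = 1.7),
              strain_tp = 0.004, v = 0.02)),
  aligned_bundle = list(
    curve_type = "Z_F_Z",
    z_initial = c(a = 34.8, b = 0.58, c = 25.1),
    f_toe = c(B = 4.55, C = 6.87),
    z_final = c(a = 55.0, b = 2.25, c = 13.6),
    strain_if1 = 0.10, strain_tp = 0.24, strain_limit = 0.85,
    geometry = list(gauge_length_mm = 197.5, area_mm2 = 0.138, v = 0.44),
    sd = list(z_initial = c(a = 1.0, b = 0.12, c = 3.7),
              f_toe = c(B = 0.26, C = 0.46),
              z_final = c(a = 1.9, b = 0.28, c = 2.6),
              strain_if1 = 0.017, strain_tp = 0.01, v = 0.02)),
  hnes = list(
    curve_type = "Z_F_Z",
    z_initial = c(a = 25.6, b = 0.29, c = 28.1),
    f_toe = c(B = 4.65, C = 5.06),
    z_final = c(a = 39.6, b = 2.87, c = 9.87),
    strain_if1 = 0.10, strain_tp = 0.31, strain_limit = 0.90,
    geometry = list(gauge_length_mm = 98, area_mm2 = 1.021, v = 0.47),
    sd = list(z_initial = c(a = 0.4, b = 0.08, c = 3.4),
              f_toe = c(B = 0.90, C = 0.75),
              z_final = c(a = 1.1, b = 0.69, c = 1.35),
              strain_if1 = 0.017, strain_tp = 0.07, v = 0.08))
)

#' Archetype parameters for a specimen class
#'
#' The generating parameter set (net-stress basis) for one of the five
#' specimen classes, usable directly as a [synthetic_curve_spec()].
#'
#' @param specimen_class one of [specimen_classes()].
#' @return list of curve type, per-segment parameters, anchors, geometry
#'   and cohort standard deviations.
#' @export
archetype_params <- function(specimen_class) {
  .archetypes[[match.arg(specimen_class, specimen_classes())]]
}

#' Specification of one synthetic curve
#'
#' @param curve_type `"Z_ONLY"`, `"F_THEN_Z"` or `"Z_F_Z"`.
#' @param z_whole,z_initial,f_toe,z_final named numeric parameter vectors
#'   for the segments the type uses (`c(a=, b=, c=)` or `c(B=, C=)`).
#' @param strain_if1 first join strain (Z_F_Z only).
#' @param strain_tp toe-to-linear join strain (F_THEN_Z, Z_F_Z).
#' @param strain_limit final strain of the generated curve.
#' @param noise_sd i.i.d. Gaussian stress noise, MPa.
#' @param n_points sample count (>= 50), uniform in strain.
#' @param seed integer seed.
#' @return list of class `synthetic_curve_spec`.
#' @export
synthetic_curve_spec <- function(curve_type = c("Z_ONLY", "F_THEN_Z", "Z_F_Z"),
                                 z_whole = NULL, z_initial = NULL,
                                 f_toe = NULL, z_final = NULL,
                                 strain_if1 = NA_real_, strain_tp = NA_real_,
                                 strain_limit = 1, noise_sd = 0.1,
                                 n_points = 500L, seed = 20200716L) {
  curve_type <- match.arg(curve_type)
  stopifnot(noise_sd >= 0, n_points >= 50)
  if (curve_type == "Z_ONLY") {
    stopifnot(!is.null(z_whole))
  } else {
    stopifnot(!is.null(f_toe), !is.null(z_final),
              is.finite(strain_tp), strain_tp < strain_limit)
    if (curve_type == "Z_F_Z") {
      stopifnot(!is.null(z_initial), is.finite(strain_if1),
                strain_if1 < strain_tp)
    }
  }
  structure(list(curve_type = curve_type, z_whole = z_whole,
                 z_initial = z_initial, f_toe = f_toe, z_final = z_final,
                 strain_if1 = strain_if1, strain_tp = strain_tp,
                 strain_limit = strain_limit, noise_sd = noise_sd,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "synthetic_curve_spec")
}

#' Curve spec for a specimen class at the archetype means
#'
#' @param specimen_class one of [specimen_classes()].
#' @param ... overrides passed to [synthetic_curve_spec()] (e.g. `noise_sd`,
#'   `n_points`, `seed`).
#' @return a [synthetic_curve_spec()].
#' @export
archetype_curve_spec <- function(specimen_class, ...) {
  p <- archetype_params(specimen_class)
  args <- utils::modifyList(
    list(curve_type = p$curve_type, z_whole = p$z_whole,
         z_initial = p$z_initial, f_toe = p$f_toe, z_final = p$z_final,
         strain_if1 = if (is.null(p$strain_if1)) NA_real_ else p$strain_if1,
         strain_tp = if (is.null(p$strain_tp)) NA_real_ else p$strain_tp,
         strain_limit = p$strain_limit),
    list(...))
  do.call(synthetic_curve_spec, args)
}

# internal: noise-free forward evaluation of a spec on given strains
compose_forward <- function(spec, strain) {
  if (spec$curve_type == "Z_ONLY") {
    z <- do.call(z_model, as.list(spec$z_whole))
    return(z_eval(z, strain))
  }
  if (spec$curve_type == "Z_F_Z") {
    zi <- do.call(z_model, c(as.list(spec$z_initial),
                             list(segment = "initial")))
    sig_if1 <- z_eval(zi, spec$strain_if1)
    org <- c(spec$strain_if1, sig_if1)
  } else {
    zi <- NULL
    org <- c(0, 0)
  }
  f <- f_model(spec$f_toe[["B"]], spec$f_toe[["C"]], origin = org)
  sig_tp <- f_eval(f, spec$strain_tp)
  zf <- do.call(z_model, c(as.list(spec$z_final),
                           list(origin = c(spec$strain_tp, sig_tp),
                                segment = "final")))
  out <- numeric(length(strain))
  s1 <- strain < org[1]
  s2 <- !s1 & strain < spec$strain_tp
  s3 <- !s1 & !s2
  if (any(s1)) out[s1] <- z_eval(zi, strain[s1])
  out[s2] <- f_eval(f, strain[s2])
  out[s3] <- z_eval(zf, strain[s3])
  out
}

#' Generate one synthetic stress-strain curve
#'
#' Evaluates the composite model forward (segment origins translated to the
#' previous segment's endpoint, so stress is continuous at every join by
#' construction), samples strain uniformly on `[0, strain_limit]`, and adds
#' independent Gaussian stress noise. The exact generating parameters are
#' attached as attribute `ground_truth`. Identical seeds give identical
#' curves.
#'
#' @param spec a [synthetic_curve_spec()].
#' @param stress_basis basis label for the generated curve (archetype
#'   parameters are net-basis).
#' @return a [stress_strain_curve()] with attribute `ground_truth = spec`.
#' @export
make_curve <- function(spec, stress_basis = "net") {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  strain <- seq(0, spec$strain_limit, length.out = spec$n_points)
  sigma <- compose_forward(spec, strain)
  if (any(sigma < -1e-9)) {
    stop("incompatible parameters: composite model produces negative stress")
  }
  if (spec$noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(spec$seed)
    sigma <- sigma + stats::rnorm(length(sigma), 0, spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  cv <- stress_strain_curve(strain, sigma,
                            specimen_id = sprintf("synthetic_%s_%d",
                                                  tolower(spec$curve_type),
                                                  spec$seed),
                            stress_basis = stress_basis)
  attr(cv, "ground_truth") <- spec
  cv
}

#' Specification of a synthetic cohort
#'
#' @param specimen_class one of [specimen_classes()]; sets the archetype
#'   means, the cohort standard deviations and the geometry.
#' @param n_specimens cohort size (>= 1).
#' @param noise_sd per-curve Gaussian stress noise, MPa.
#' @param n_points samples per curve.
#' @param parameter_scatter multiplier on the archetype between-specimen
#'   SDs (0 puts every specimen at the means).
#' @param seed integer seed.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(specimen_class, n_specimens = 10L,
                                  noise_sd = 0.1, n_points = 500L,
                                  parameter_scatter = 1,
                                  seed = 20200716L) {
  specimen_class <- match.arg(specimen_class, specimen_classes())
  stopifnot(n_specimens >= 1, noise_sd >= 0, parameter_scatter >= 0)
  structure(list(specimen_class = specimen_class,
                 n_specimens = as.integer(n_specimens),
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 parameter_scatter = parameter_scatter,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# internal: Gaussian draw truncated at (just above) zero
rtruncpos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- stats::rnorm(n, mean, sd)
  bad <- v <= 0
  tries <- 0
  while (any(bad) && tries < 100) {
    v[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- v <= 0
    tries <- tries + 1
  }
  v[bad] <- mean * 1e-3
  v
}

#' Generate a synthetic cohort of specimens
#'
#' Draws per-specimen model parameters and volume fractions from
#' independent Gaussians truncated at zero (means and SDs from the class
#' archetype), builds each specimen's geometry, evaluates its composite
#' curve forward on the net basis, and converts it back to a raw
#' force-displacement record so the cohort can exercise the full reading
#' and preprocessing pipeline.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return list of per-specimen lists, each with elements `record` (a
#'   [tensile_record()]), `geometry` (a [specimen_geometry()]), `curve`
#'   (the noise-bearing net-basis [stress_strain_curve()]) and `truth`
#'   (the generating [synthetic_curve_spec()] plus the drawn volume
#'   fraction).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  arch <- archetype_params(spec$specimen_class)
  set.seed(spec$seed)
  sc <- spec$parameter_scatter
  draws <- lapply(seq_len(spec$n_specimens), function(i) {
    draw_seg <- function(seg) {
      if (is.null(arch[[seg]])) return(NULL)
      sds <- arch$sd[[seg]] * sc
      stats::setNames(
        vapply(seq_along(arch[[seg]]),
               function(j) rtruncpos(1, arch[[seg]][j], sds[j]), numeric(1)),
        names(arch[[seg]]))
    }
    pars <- list(z_whole = draw_seg("z_whole"),
                 z_initial = draw_seg("z_initial"),
                 f_toe = draw_seg("f_toe"),
                 z_final = draw_seg("z_final"))
    if1 <- arch$strain_if1
    if (!is.null(if1) && is.finite(if1) && !is.null(arch$sd$strain_if1)) {
      if1 <- rtruncpos(1, if1, arch$sd$strain_if1 * sc)
    }
    tp <- arch$strain_tp
    if (!is.null(tp) && is.finite(tp) && !is.null(arch$sd$strain_tp)) {
      tp <- rtruncpos(1, tp, arch$sd$strain_tp * sc)
      if (!is.null(if1) && is.finite(if1)) tp <- max(tp, if1 * 1.5)
    }
    v <- rtruncpos(1, arch$geometry$v, arch$sd$v * sc)
    list(pars = pars, if1 = if1, tp = tp, v = min(v, 1),
         seed = spec$seed + i)
  })
  lapply(seq_along(draws), function(i) {
    d <- draws[[i]]
    cs <- synthetic_curve_spec(
      curve_type = arch$curve_type,
      z_whole = d$pars$z_whole, z_initial = d$pars$z_initial,
      f_toe = d$pars$f_toe, z_final = d$pars$z_final,
      strain_if1 = if (is.null(d$if1)) NA_real_ else d$if1,
      strain_tp = if (is.null(d$tp)) NA_real_ else d$tp,
      strain_limit = arch$strain_limit,
      noise_sd = spec$noise_sd, n_points = spec$n_points, seed = d$seed)
    curve <- make_curve(cs, stress_basis = "net")
    curve$specimen_id <- sprintf("%s_%02d", spec$specimen_class, i)
    L <- arch$geometry$gauge_length_mm
    A <- arch$geometry$area_mm2
    geom <- specimen_geometry(
      gauge_length_mm = L, area_mm2 = A,
      weight_mg = d$v * L * A * 1.18, density_mg_mm3 = 1.18,
      specimen_class = spec$specimen_class)
    force <- curve$stress * d$v * A
    force[1] <- max(force[1], 0)  # noise cannot make the unloaded grip pull
    curve$stress <- force / (d$v * A)  # keep curve and record consistent
    rec <- tensile_record(curve$strain * L, force,
                          sample_kind = "force_displacement",
                          specimen_id = curve$specimen_id,
                          gauge_length_mm = L)
    list(record = rec, geometry = geom, curve = curve,
         truth = c(unclass(cs), list(volume_fraction = d$v)))
  })
}
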