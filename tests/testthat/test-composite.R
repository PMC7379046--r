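# The on-grid sample counts place the construction joins exactly on the
# strain grid, so noise-free anchors and parameters are recoverable without
# quantisation error (851 points over 0.85 strain gives a 0.001 spacing).

test_that("noise-free archetypes classify into their curve families", {
  cases <- list(random_mat = "Z_ONLY", aligned_mat = "F_THEN_Z",
                aligned_bundle = "Z_F_Z", hnes = "Z_F_Z")
  for (cl in names(cases)) {
    cvt <- truncate_at_limit(make_curve(
      archetype_curve_spec(cl, noise_sd = 0, n_points = 800)))
    cls <- classify_curve(cvt)
    expect_identical(cls$curve_type, cases[[cl]])
  }
})

test_that("noise-free anchors land within one sample of construction joins", {
  h <- 0.001
  cvt <- truncate_at_limit(make_curve(
    archetype_curve_spec("aligned_bundle", noise_sd = 0, n_points = 851)))
  cls <- classify_curve(cvt)
  expect_lte(abs(cls$strain_if1 - 0.10), h + 1e-12)
  expect_lte(abs(cls$strain_if2 - 0.24), h + 1e-12)
  cvm <- truncate_at_limit(make_curve(
    archetype_curve_spec("aligned_mat", noise_sd = 0, n_points = 800)))
  clm <- classify_curve(cvm)
  hm <- diff(cvm$strain[1:2])
  expect_lte(abs(clm$strain_if2 - 0.104), hm + 1e-12)
})

test_that("noise-free composite fits recover all generating parameters within 1%", {
  for (cl in c("aligned_bundle", "hnes")) {
    np <- if (cl == "aligned_bundle") 851L else 901L
    cvt <- truncate_at_limit(make_curve(
      archetype_curve_spec(cl, noise_sd = 0, n_points = np)))
    cf <- fit_composite(cvt)
    expect_identical(cf$curve_type, "Z_F_Z")
    truth <- archetype_params(cl)
    est <- c(cf$z_initial$a, cf$z_initial$b, cf$z_initial$c,
             cf$f_toe$B, cf$f_toe$C,
             cf$z_final$a, cf$z_final$b, cf$z_final$c, cf$strain_tp)
    tru <- c(truth$z_initial, truth$f_toe, truth$z_final, truth$strain_tp)
    expect_lt(max(abs(est - tru) / tru), 0.01)
  }
})

test_that("constrained joins are stress-continuous to 1e-8 MPa", {
  for (cl in c("aligned_mat", "aligned_bundle")) {
    cvt <- truncate_at_limit(make_curve(
      archetype_curve_spec(cl, noise_sd = 0.05, n_points = 600, seed = 5)))
    cf <- fit_composite(cvt)
    ftp <- cf$f_toe; ftp$strain_tp <- NA_real_
    gap_tp <- abs(f_eval(ftp, cf$strain_tp) - z_eval(cf$z_final, cf$strain_tp))
    expect_lt(gap_tp, 1e-8)
    if (cf$curve_type == "Z_F_Z") {
      gap_if1 <- abs(z_eval(cf$z_initial, cf$strain_if1) -
                       f_eval(ftp, cf$strain_if1))
      expect_lt(gap_if1, 1e-8)
    }
    # the composite prediction is finite and continuous over the domain
    eps <- seq(0, cf$strain_limit, length.out = 400)
    pred <- predict(cf, eps)
    expect_true(all(is.finite(pred)))
    expect_lt(max(abs(diff(pred))), max(diff(range(pred)) / 50, 1e-6))
  }
})

test_that("the backward scan matches an exhaustive grid oracle", {
  # brute force recomputed through the public API only
  brute_force_tp <- function(cvt, i1, i2, origin, cfg) {
    eps <- cvt$strain; sig <- cvt$stress; n <- length(eps)
    noise_hat <- sqrt(mean(diff(sig, differences = 2)^2) / 6)
    pin <- if (noise_hat < 1e-4 * diff(range(sig))) sig else
      smooth_stress(cvt)
    lb <- eps[i1] + cfg$tp_lower_bound_fraction * (eps[i2] - eps[i1])
    cand <- which(eps >= lb & seq_len(n) <= i2 &
                    seq_len(n) - i1 + 1 >= 8 & n - seq_len(n) + 1 >= 10)
    cand <- cand[pin[cand] > origin[2]]
    scores <- vapply(cand, function(p) {
      ft <- fit_f(eps[i1:p], sig[i1:p], origin = origin,
                  continuity = c(eps[p], pin[p]))
      zt <- fit_z(eps[p:n], sig[p:n], origin = c(eps[p], pin[p]),
                  segment = "final")
      abs(f_tangent_modulus(ft, eps[p]) - zt$modulus_0)
    }, numeric(1))
    cand[which.min(scores)]
  }
  cfg <- run_config()
  cohort <- make_cohort(synthetic_cohort_spec("aligned_bundle",
                                              n_specimens = 3,
                                              noise_sd = 0, n_points = 400,
                                              seed = 99))
  for (sp in cohort) {
    cvt <- truncate_at_limit(sp$curve)
    cls <- classify_curve(cvt, cfg)
    expect_identical(cls$curve_type, "Z_F_Z")
    zi <- fit_z(cvt$strain[1:cls$index_if1], cvt$stress[1:cls$index_if1],
                segment = "initial")
    origin <- c(cvt$strain[cls$index_if1],
                z_eval(zi, cvt$strain[cls$index_if1]))
    tp <- find_transition_point(cvt, cls$index_if2, origin = origin,
                                index_if1 = cls$index_if1, config = cfg)
    expect_identical(tp$index_tp,
                     brute_force_tp(cvt, cls$index_if1, cls$index_if2,
                                    origin, cfg))
  }
})

test_that("an empty transition-point candidate set falls back to IF2", {
  cvt <- truncate_at_limit(make_curve(
    archetype_curve_spec("aligned_mat", noise_sd = 0, n_points = 400)))
  # an IF2 fewer than 8 samples from the toe origin leaves no admissible
  # candidate; the search then returns IF2 itself with relaxed segment fits
  expect_warning(
    tp <- find_transition_point(cvt, index_if2 = 7L, origin = c(0, 0),
                                index_if1 = 1L),
    "falling back to IF2")
  expect_true(tp$fallback)
  expect_identical(tp$index_tp, 7L)
  expect_equal(tp$strain_tp, cvt$strain[7])
})

test_that("segment failures are reported by name", {
  cvt <- truncate_at_limit(make_curve(
    archetype_curve_spec("aligned_bundle", noise_sd = 0, n_points = 400)))
  expect_error(fit_composite(cvt, curve_type = "Z_F_Z",
                             anchors = list(index_if1 = 5L, index_if2 = 200L)),
               "initial Z segment")
  expect_error(fit_composite(cvt, curve_type = "F_THEN_Z"), "IF2 anchor")
})

test_that("report tables carry the full symbol set for each curve type", {
  cvz <- truncate_at_limit(make_curve(
    archetype_curve_spec("random_mat", noise_sd = 0, n_points = 300)))
  rz <- report_table(fit_composite(cvz))
  expect_named(rz, c("a_z", "b_z", "c_z", "modulus_0", "modulus_lin",
                     "strain_knee", "softening_pct"))
  cvt <- truncate_at_limit(make_curve(
    archetype_curve_spec("aligned_bundle", noise_sd = 0, n_points = 400)))
  cf <- fit_composite(cvt)
  rt <- report_table(cf)
  expect_true(all(c("strain_if1", "stress_if1", "strain_tp", "stress_tp",
                    "strain_if2", "stress_if2", "a_z_initial", "b_z_initial",
                    "c_z_initial", "B_f", "C_f", "a_z_final", "b_z_final",
                    "c_z_final", "modulus_0", "modulus_if1", "modulus_tp",
                    "modulus_lin", "strain_knee_initial", "strain_knee_final",
                    "softening_initial_pct", "stiffening_toe_pct",
                    "softening_final_pct") %in% names(rt)))
  # percentage ratios are consistent with the headline moduli
  expect_equal(rt$softening_initial_pct,
               100 * (rt$modulus_if1 - rt$modulus_0) / rt$modulus_0)
  expect_equal(rt$stiffening_toe_pct,
               100 * (rt$modulus_tp - rt$modulus_if1) / rt$modulus_if1)
  # per-segment knee identities
  expect_equal(rt$strain_knee_initial, 1 / rt$c_z_initial)
  expect_equal(rt$strain_knee_final, 1 / rt$c_z_final)
  # softening sign pattern of a three-segment curve
  expect_lt(cf$modulus_if1, cf$modulus_0)
  expect_lt(cf$modulus_lin, cf$modulus_tp)
})
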