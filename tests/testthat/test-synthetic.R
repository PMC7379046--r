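test_that("noise-free generation equals the composite model evaluated forward", {
  spec <- archetype_curve_spec("aligned_bundle", noise_sd = 0,
                               n_points = 200)
  cv <- make_curve(spec)
  # rebuild the piecewise model independently from the spec parameters
  zi <- do.call(z_model, c(as.list(spec$z_initial), list(segment = "initial")))
  s_if1 <- z_eval(zi, spec$strain_if1)
  f <- f_model(spec$f_toe[["B"]], spec$f_toe[["C"]],
               origin = c(spec$strain_if1, s_if1))
  s_tp <- f_eval(f, spec$strain_tp)
  zf <- do.call(z_model, c(as.list(spec$z_final),
                           list(origin = c(spec$strain_tp, s_tp),
                                segment = "final")))
  expected <- numeric(length(cv$strain))
  s1 <- cv$strain < spec$strain_if1
  s2 <- !s1 & cv$strain < spec$strain_tp
  s3 <- !s1 & !s2
  expected[s1] <- z_eval(zi, cv$strain[s1])
  expected[s2] <- f$B * (exp(f$C * (cv$strain[s2] - f$origin_strain)) - 1) +
    f$origin_stress
  expected[s3] <- z_eval(zf, cv$strain[s3])
  expect_equal(cv$stress, expected, tolerance = 1e-12)
  # stress is continuous at both joins by construction
  expect_lt(max(abs(diff(cv$stress))), diff(range(cv$stress)) / 20)
})

test_that("generation is seed-deterministic and leaves the RNG stream alone", {
  s1 <- archetype_curve_spec("random_mat", noise_sd = 0.1, seed = 123)
  s2 <- archetype_curve_spec("random_mat", noise_sd = 0.1, seed = 124)
  expect_identical(make_curve(s1)$stress, make_curve(s1)$stress)
  expect_false(identical(make_curve(s1)$stress, make_curve(s2)$stress))
  set.seed(77); x1 <- runif(3)
  set.seed(77); invisible(make_curve(s1)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("a scatter-free cohort of one sits exactly at the archetype means", {
  sp <- synthetic_cohort_spec("random_mat", n_specimens = 1, noise_sd = 0,
                              parameter_scatter = 0, seed = 1)
  cohort <- make_cohort(sp)
  expect_length(cohort, 1)
  arch <- archetype_params("random_mat")
  cv <- cohort[[1]]$curve
  z <- do.call(z_model, as.list(arch$z_whole))
  expect_equal(cv$stress, z_eval(z, cv$strain), tolerance = 1e-12)
  expect_equal(volume_fraction(cohort[[1]]$geometry), arch$geometry$v,
               tolerance = 1e-9)
})

test_that("cohort records round-trip the full reading and conversion pipeline", {
  sp <- synthetic_cohort_spec("random_mat", n_specimens = 3, noise_sd = 0.02,
                              n_points = 300, seed = 42)
  cohort <- make_cohort(sp)
  dir <- withr::local_tempdir()
  inds <- list()
  for (spn in cohort) {
    path <- file.path(dir, paste0(spn$record$specimen_id, ".csv"))
    write_tensile_record(spn$record, path)
    rec <- read_tensile_record(path, gauge_length_mm = spn$geometry$gauge_length_mm)
    cv <- to_net(to_stress_strain(rec, spn$geometry), spn$geometry)
    # net conversion undoes the generator's apparent-stress construction
    expect_equal(cv$stress, spn$curve$stress, tolerance = 1e-9)
    inds[[spn$record$specimen_id]] <- cbind(
      extract_indicators(cv, spn$geometry),
      specimen_class = spn$geometry$specimen_class)
  }
  s <- summarize_cohort(do.call(rbind, inds))
  expect_true("modulus" %in% s$indicator)
  expect_equal(s$n[s$indicator == "modulus"], 3L)
  expect_equal(s$n[s$indicator == "stress_f"], 3L)
})

test_that("fitted cohort parameters concentrate on the injected means", {
  sp <- synthetic_cohort_spec("random_mat", n_specimens = 10, noise_sd = 0.02,
                              n_points = 400, seed = 8)
  cohort <- make_cohort(sp)
  c_hat <- vapply(cohort, function(spn) {
    fit_z(truncate_at_limit(spn$curve))$c
  }, numeric(1))
  se <- stats::sd(c_hat) / sqrt(length(c_hat))
  expect_lt(abs(mean(c_hat) - 6.20), 2 * se + 1e-12)
})

test_that("invalid synthetic specifications are rejected", {
  expect_error(synthetic_curve_spec("Z_ONLY"), "z_whole")
  expect_error(synthetic_curve_spec("Z_F_Z", f_toe = c(B = 1, C = 5),
                                    z_final = c(a = 1, b = 1, c = 5),
                                    strain_tp = 0.2, strain_limit = 1),
               "z_initial")
  expect_error(archetype_curve_spec("random_mat", n_points = 20),
               "n_points")
})
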