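test_that("Z-Model evaluation matches hand arithmetic and its asymptote", {
  z <- z_model(2.51, 1.13, 6.20)
  expect_equal(z_eval(z, 0), 0)
  # a*eps + b*(1 - exp(-c*eps)) at eps = 0.5 with the random-mat parameters
  expect_equal(z_eval(z, 0.5), 2.3340944, tolerance = 1e-6)
  # far out, the curve approaches the linear asymptote a*eps + b
  eps <- 5
  expect_lt(abs(z_eval(z, eps) - (2.51 * eps + 1.13)), 1e-10)
  # translated form pins the origin
  zt <- z_model(2.51, 1.13, 6.20, origin = c(0.2, 1.5))
  expect_equal(z_eval(zt, 0.2), 1.5)
  expect_error(z_eval(zt, 0.1), "below the model origin")
})

test_that("tangent modulus decreases from a + b c toward a", {
  z <- z_model(2.51, 1.13, 6.20)
  expect_equal(z_tangent_modulus(z, 0), 2.51 + 1.13 * 6.20)
  # the initial modulus of the random-mat parameter set reproduces the
  # reported cohort mean within its rounding
  expect_equal(z_tangent_modulus(z, 0), 9.49, tolerance = 0.005)
  eps <- seq(0, 2, length.out = 50)
  expect_true(all(diff(z_tangent_modulus(z, eps)) < 0))
  expect_equal(z_tangent_modulus(z, 100), 2.51, tolerance = 1e-8)
  # finite differences of the evaluation agree with the closed form
  h <- 1e-7
  for (e in c(0.05, 0.3, 1.2)) {
    fd <- (z_eval(z, e + h) - z_eval(z, e - h)) / (2 * h)
    expect_equal(fd, z_tangent_modulus(z, e), tolerance = 1e-6)
  }
})

test_that("knee strain and softening ratio follow their closed forms", {
  z <- z_model(2.51, 1.13, 6.20)
  k <- z_knee(z)
  expect_equal(k$strain_knee, 1 / 6.20)
  expect_equal(round(k$strain_knee, 2), 0.16)
  expect_equal(k$softening_ratio, -1.13 * 6.20 / (2.51 + 1.13 * 6.20))
  expect_equal(100 * k$softening_ratio, -73.5, tolerance = 0.002)
  # b = 0 degenerates to a purely linear model with no softening
  z0 <- z_model(2.51, 0, 6.20)
  expect_equal(z_knee(z0)$softening_ratio, 0)
  expect_equal(z_eval(z0, 0.7), 2.51 * 0.7)
})

test_that("Z-Model identities hold exactly for every fit", {
  set.seed(20200716)
  for (i in 1:10) {
    a <- runif(1, 0.5, 60); b <- runif(1, 0.1, 6); c <- runif(1, 2, 30)
    eps <- seq(0, runif(1, 0.5, 2), length.out = 200)
    z <- fit_z(eps, z_eval(z_model(a, b, c), eps))
    expect_equal(z$modulus_0, z$a + z$b * z$c)
    expect_equal(z$modulus_lin, z$a)
    expect_equal(z$strain_knee, 1 / z$c)
    expect_equal(z$softening_ratio,
                 (z$modulus_lin - z$modulus_0) / z$modulus_0)
  }
})

test_that("least squares recovers noise-free Z parameters to solver precision", {
  truth <- c(a = 2.51, b = 1.13, c = 6.20)
  eps <- seq(0, 2.2, length.out = 400)
  sig <- z_eval(do.call(z_model, as.list(truth)), eps)
  fit <- fit_z(eps, sig)
  expect_equal(fit$a, truth[["a"]], tolerance = 1e-6)
  expect_equal(fit$b, truth[["b"]], tolerance = 1e-6)
  expect_equal(fit$c, truth[["c"]], tolerance = 1e-6)
  # refitting the fit's own predictions is idempotent
  refit <- fit_z(eps, z_eval(fit, eps))
  expect_equal(refit$a, fit$a, tolerance = 1e-8)
  expect_equal(refit$c, fit$c, tolerance = 1e-8)
  # translated origin is honored exactly
  org <- c(0.1, 0.8)
  sig_t <- z_eval(do.call(z_model, c(as.list(truth), list(origin = org))), eps + 0.1)
  fit_t <- fit_z(eps + 0.1, sig_t, origin = org)
  expect_equal(z_eval(fit_t, 0.1), 0.8)
  expect_equal(fit_t$c, truth[["c"]], tolerance = 1e-6)
})

test_that("noisy Z fits recover each parameter within 5% in the median", {
  truth <- c(a = 2.51, b = 1.13, c = 6.20)
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    eps <- seq(0, 2.2, length.out = 500)
    sig <- z_eval(do.call(z_model, as.list(truth)), eps) + rnorm(500, 0, 0.05)
    fit <- fit_z(eps, sig)
    abs(c(fit$a, fit$b, fit$c) - truth) / truth
  })
  expect_lt(max(apply(errs, 1, median)), 0.05)
})

test_that("degenerate inputs are rejected", {
  eps <- seq(0, 1, length.out = 100)
  expect_error(fit_z(eps, rep(0, 100)), "degenerate")
  expect_error(fit_z(eps[1:5], eps[1:5]), "at least 10")
  expect_error(z_model(1, 1, -2), "positive")
  expect_error(z_model(-1, 1, 2), "non-negative")
})
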