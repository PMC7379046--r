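test_that("failure point is the first global stress maximum", {
  eps <- seq(0, 1, length.out = 101)
  sig <- ifelse(eps <= 0.5, 6 * eps, 3 - 4 * (eps - 0.5))
  fp <- failure_point(stress_strain_curve(eps, sig), area_mm2 = 2)
  expect_equal(fp$stress_f, 3)
  expect_equal(fp$strain_f, 0.5)
  expect_equal(fp$force_f, 6)
  # plateau ties break at the first occurrence
  sigp <- pmin(10 * eps, 4)
  fpp <- failure_point(stress_strain_curve(eps, sigp))
  expect_equal(fpp$strain_f, eps[which(sigp == 4)[1]])
})

test_that("offset yield flags exactly linear curves and reports E", {
  oy <- offset_yield(linear_curve(slope = 10))
  expect_false(oy$yield_defined)
  expect_true(is.na(oy$strain_y))
  expect_equal(oy$modulus, 10, tolerance = 1e-10)
})

test_that("offset yield matches the analytic intersection on a bilinear curve", {
  cv <- bilinear_curve(s1 = 10, s2 = 1, eps_break = 0.1, n = 2001)
  oy <- offset_yield(cv, offset = 0.001)
  # offset line 10(e - 0.001) meets the second branch 1 + (e - 0.1) at
  # e = 0.91/9, sigma = 10*(0.91/9 - 0.001)
  eps_exact <- 0.91 / 9
  sig_exact <- 10 * (eps_exact - 0.001)
  h <- diff(cv$strain[1:2])
  expect_true(oy$yield_defined)
  expect_lt(abs(oy$strain_y - eps_exact), h)
  expect_lt(abs(oy$stress_y - sig_exact), 10 * h)
  expect_gt(oy$strain_y, 0.101)
})

test_that("asymptotic stiffness is the regression slope after yield", {
  eps <- seq(0, 1, length.out = 101)
  cv <- stress_strain_curve(eps, 1 + 0.87 * eps)
  expect_equal(asymptotic_stiffness(cv, from = 10, to = 90), 0.87)
  expect_error(asymptotic_stiffness(cv, from = 50, to = 51), "3 samples")
  # zero-mean noise moves the slope by less than 3 standard errors
  set.seed(11)
  noise <- rnorm(101, 0, 0.02)
  cvn <- stress_strain_curve(eps, 1 + 0.87 * eps + noise)
  fitn <- stats::lm(cvn$stress[10:90] ~ cvn$strain[10:90])
  se <- summary(fitn)$coefficients[2, 2]
  expect_lt(abs(asymptotic_stiffness(cvn, 10, 90) - 0.87), 3 * se)
})

test_that("unit work is the trapezoid area with an interpolated sliver", {
  eps <- seq(0, 0.5, length.out = 26)
  expect_equal(unit_work(stress_strain_curve(eps, rep(2, 26)), 0.5), 1.0)
  cv <- linear_curve(slope = 10, n = 51)
  expect_equal(unit_work(cv, 1), 5.0)        # trapezoid exact on a line
  expect_equal(unit_work(cv, 0.35), 10 * 0.35^2 / 2)  # off-sample endpoint
  expect_equal(unit_work(cv, -0.1), 0)
  # refining the sampling converges to adaptive quadrature
  f <- function(x) 2 * x + sin(5 * x)^2
  oracle <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  for (n in c(2001, 8001)) {
    x <- seq(0, 1, length.out = n)
    lw <- unit_work(stress_strain_curve(x, f(x)), 1)
    expect_equal(lw, oracle, tolerance = 1e-4)
  }
})

test_that("the full indicator protocol is internally consistent on archetypes", {
  cv <- make_curve(archetype_curve_spec("random_mat", noise_sd = 0.02,
                                        n_points = 1000, seed = 3))
  ind <- extract_indicators(cv)
  expect_true(ind$yield_defined)
  expect_lte(ind$strain_y, ind$strain_f)
  expect_gte(ind$work_to_yield, 0)
  expect_lte(ind$work_to_yield, ind$work_to_failure)
  # strain-softening curve: elastic modulus exceeds asymptotic stiffness
  expect_gt(ind$modulus, ind$asymptotic_stiffness)
  # E sits between the asymptote a_Z and the initial modulus a_Z + b_Z c_Z
  expect_gt(ind$modulus, 2.51)
  expect_lt(ind$modulus, 9.52)
})

test_that("offset yield converges to the proportionality limit as offset -> 0", {
  cv <- bilinear_curve(s1 = 10, s2 = 1, eps_break = 0.1, n = 4001)
  ys <- vapply(c(0.01, 0.003, 0.001, 3e-4), function(o) {
    offset_yield(cv, offset = o)$strain_y
  }, numeric(1))
  expect_true(all(diff(ys) < 0))
  expect_lt(abs(ys[4] - 0.1), 0.002)
})

test_that("cohort summaries report per-class mean and n-1 standard deviation", {
  df <- data.frame(specimen_class = "random_mat", stress_basis = "net",
                   modulus = c(1, 2, 3))
  s <- summarize_cohort(df)
  row <- s[s$indicator == "modulus", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  expect_equal(row$n, 3L)
  one <- summarize_cohort(df[1, ])
  expect_equal(one$sd[one$indicator == "modulus"], 0)
  mixed <- rbind(df, data.frame(specimen_class = "random_mat",
                                stress_basis = "apparent", modulus = 4))
  expect_error(summarize_cohort(mixed), "mixed stress bases")
})
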