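# closed-form force models and derived moduli

test_that("Hertz force matches the closed form and its scalings", {
  # hand evaluation: (4/3)*1000/0.75*sqrt(2.5e-6)*(1e-6)^1.5 = 2.8109e-9 N
  expect_equal(hertz_force(1000, 0.5, 2.5e-6, 1e-6), 2.810913e-9,
               tolerance = 1e-6)
  expect_identical(hertz_force(500, 0.5, 2.5e-6, 0), 0)
  # linear in E
  expect_equal(hertz_force(2000, 0.5, 2.5e-6, 0.3e-6),
               2 * hertz_force(1000, 0.5, 2.5e-6, 0.3e-6))
  # negative indentation: error unless clipped
  expect_error(hertz_force(1000, 0.5, 2.5e-6, -1e-7), "negative indentation")
  expect_identical(hertz_force(1000, 0.5, 2.5e-6, c(-1e-7, 0), clip = TRUE),
                   c(0, 0))
})

test_that("large-indentation correction behaves as (1 - 0.15 delta/R)", {
  R <- 2.5e-6
  expect_identical(ding_force(1000, 0.5, R, 0), 0)
  # at delta = 0.1 R the ratio to Hertz is 0.985
  expect_equal(ding_force(1000, 0.5, R, 0.1 * R) /
                 hertz_force(1000, 0.5, R, 0.1 * R), 0.985)
  # small-indentation limit and first-order agreement bound
  d <- R * 10^seq(-6, -0.2, length.out = 40)
  ratio <- ding_force(800, 0.45, R, d) / hertz_force(800, 0.45, R, d)
  expect_true(all(abs(ratio - 1) <= 0.15 * d / R + 1e-15))
  expect_lt(abs(ratio[1] - 1), 1e-6)
})

test_that("KVM force sums its three addends and reduces correctly", {
  cc <- calibration_constants()
  R <- 2.5e-6; v <- 5e-6
  p <- viscoelastic_params(E0 = 1000, E1 = 1000, lam = 0.1, eta = 1)
  # hand evaluation at delta = 0.5 um: 0.964 + 0.669 + 0.0405 = 1.674 nN
  tm <- kvm_force(p, cc, R, v, 0.5e-6, terms = TRUE)
  expect_equal(unname(tm[1, ]), c(9.639938e-10, 6.692012e-10, 4.052873e-11),
               tolerance = 1e-6)
  expect_equal(kvm_force(p, cc, R, v, 0.5e-6), sum(tm), tolerance = 1e-12)
  expect_equal(kvm_force(p, cc, R, v, 0.5e-6), 1.6737e-9, tolerance = 1e-4)
  # model reduction: E1 = eta = 0 is exactly the corrected Hertz force
  pe <- viscoelastic_params(E0 = 1234)
  d <- seq(0, 1e-6, length.out = 25)
  expect_equal(kvm_force(pe, cc, R, v, d), ding_force(1234, 0.5, R, d))
  # zero at contact
  expect_identical(kvm_force(p, cc, R, v, 0), 0)
  # Maxwell arm undefined without a relaxation time
  expect_error(viscoelastic_params(1000, 500, lam = 0, eta = 1),
               "lam must be positive")
})

test_that("KVM force dominates the elastic arm and is monotone in delta", {
  cc <- calibration_constants()
  R <- 2.5e-6; v <- 5e-6
  d <- seq(0, R, length.out = 60)
  set.seed(42)
  for (i in 1:20) {
    p <- viscoelastic_params(runif(1, 100, 5000), runif(1, 0, 3000),
                             lam = runif(1, 0.01, 1), eta = runif(1, 0, 5))
    f <- kvm_force(p, cc, R, v, d)
    expect_true(all(diff(f) >= -1e-18), info = paste("seed case", i))
    expect_true(all(f >= ding_force(p$E0, p$nu, R, d) - 1e-18))
  }
  # equality iff the Maxwell arm and viscosity vanish
  pe <- viscoelastic_params(900)
  expect_equal(kvm_force(pe, cc, R, v, d), ding_force(900, 0.5, R, d))
  pv <- viscoelastic_params(900, 0, 0, eta = 0.5)
  expect_gt(min((kvm_force(pv, cc, R, v, d) -
                   ding_force(900, 0.5, R, d))[-1]), 0)
})

test_that("slow-relaxation limit is the unrelaxed elastic force plus drag", {
  cc <- calibration_constants()
  R <- 2.5e-6; v <- 5e-6
  d <- seq(1e-8, 0.8e-6, length.out = 30)
  lam_big <- 1e6 * max(d) / v
  p <- viscoelastic_params(700, 900, lam = lam_big, eta = 2)
  expected <- ding_force(700 + 900, 0.5, R, d) + cc$alpha2 * sqrt(R * d) * 2 * v
  expect_equal(kvm_force(p, cc, R, v, d), expected, tolerance = 1e-6)
})

test_that("viscous term carries units of force via sqrt(R*delta)*eta*v", {
  cc <- calibration_constants()
  p <- viscoelastic_params(0, 0, 0, eta = 3)
  f1 <- kvm_force(p, cc, R = 2.5e-6, v = 5e-6, delta = 0.4e-6)
  # quadrupling R and delta doubles the force (sqrt scaling in each)
  f2 <- kvm_force(p, cc, R = 4 * 2.5e-6, v = 5e-6, delta = 4 * 0.4e-6)
  expect_equal(f2, 4 * f1, tolerance = 1e-12)
  expect_equal(f1, cc$alpha2 * sqrt(2.5e-6 * 0.4e-6) * 3 * 5e-6)
})

test_that("fast optimizer path agrees with the reference model", {
  cc <- calibration_constants()
  set.seed(7)
  for (i in 1:10) {
    p <- viscoelastic_params(runif(1, 100, 3000), runif(1, 0, 2000),
                             lam = runif(1, 0.02, 2), eta = runif(1, 0, 4),
                             nu = runif(1, 0.3, 0.5))
    d <- c(-1e-7, 0, sort(runif(20, 0, 1e-6)))
    ref <- vapply(d, function(x)
      if (x > 0) kvm_force(p, cc, 2.5e-6, 5e-6, x) else 0, 0)
    expect_equal(
      afmkvm:::.kvm_piecewise_fast(p$E0, p$E1, p$lam, p$eta, p$nu, cc,
                                   2.5e-6, 5e-6, d),
      ref, tolerance = 1e-14)
  }
})

test_that("derived moduli obey E0 <= Eapp <= Eu with the stated limits", {
  p <- viscoelastic_params(1000, 1000, lam = 0.1, eta = 1)
  dm <- derived_moduli(p, delta_max = 0.5e-6, v = 5e-6)
  # Eapp = 1000 + 1000*exp(-0.365) = 1694.2 Pa
  expect_equal(dm$Eapp, 1000 + 1000 * exp(-0.365))
  expect_equal(dm$Eapp, 1694.2, tolerance = 1e-4)
  expect_equal(dm$Eu, 2000)
  expect_equal(dm$t_ind, 0.1)
  # purely elastic: all moduli coincide
  dm0 <- derived_moduli(viscoelastic_params(800), delta_max = 1e-6, v = 5e-6)
  expect_equal(dm0$Eu, 800); expect_equal(dm0$Eapp, 800)
  # no-relaxation limit
  dmL <- derived_moduli(viscoelastic_params(1000, 500, lam = 1e9, eta = 0),
                        delta_max = 1e-6, v = 5e-6)
  expect_equal(dmL$Eapp, dmL$Eu, tolerance = 1e-6)
  # ordering holds across random parameters
  set.seed(11)
  for (i in 1:20) {
    p <- viscoelastic_params(runif(1, 0, 3000), runif(1, 0, 3000),
                             lam = runif(1, 1e-3, 10), eta = 0)
    dm <- derived_moduli(p, delta_max = runif(1, 1e-7, 2e-6), v = 5e-6)
    expect_true(p$E0 <= dm$Eapp + 1e-12 && dm$Eapp <= dm$Eu + 1e-12)
  }
})

test_that("Stokes drag reproduces the published diagnostic and is linear", {
  f <- stokes_drag(1e-3, 2.5e-6, 5e-6)
  expect_equal(f, 6 * pi * 1e-3 * 2.5e-6 * 5e-6)
  expect_equal(f * 1e9, 2.4e-4, tolerance = 0.02)  # ~2.4e-4 nN
  expect_identical(stokes_drag(1e-3, 2.5e-6, 0), 0)
  expect_equal(stokes_drag(2e-3, 2.5e-6, 5e-6), 2 * f)
  expect_equal(stokes_drag(1e-3, 5e-6, 5e-6), 2 * f)
})

test_that("remaining-relaxation fractions justify the lambda box", {
  expect_equal(relaxation_remaining(lam = 10, t_ind = 1), exp(-0.1))
  expect_equal(relaxation_remaining(lam = 0.2, t_ind = 1), exp(-5))
  expect_equal(relaxation_remaining(10, 1), 0.9, tolerance = 6e-3)
  expect_equal(relaxation_remaining(0.2, 1), 0.006, tolerance = 0.15)
})

test_that("parameter containers validate their invariants", {
  expect_error(viscoelastic_params(-1), "non-negative")
  expect_error(viscoelastic_params(1000, nu = 0.7), "nu")
  expect_error(calibration_constants(alpha1 = 0), "positive")
  expect_error(probe_geometry(R = -1))
  g <- probe_geometry(R = 2.5e-6, Rcell = 7.5e-6, h = 15e-6)
  expect_equal(g$Reff, 1.875e-6)
  expect_gt(g$K, 0); expect_lt(g$K, 1)
})
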