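# synthetic-curve generator and hereditary-integral oracle

test_that("generation is deterministic in the seed and matches the model", {
  sp <- cheap_spec(noise_sd = 3e-11, seed = 21)
  a <- generate_kvm_curve(sp)
  b <- generate_kvm_curve(sp)
  expect_identical(a$F, b$F)
  expect_identical(a$z, b$z)
  sp2 <- sp; sp2$seed <- 22L
  expect_false(identical(generate_kvm_curve(sp2)$F, a$F))
  # the generator does not disturb the session RNG stream
  set.seed(123); before <- .Random.seed
  invisible(generate_kvm_curve(sp))
  expect_identical(.Random.seed, before)
})

test_that("noiseless elastic curves equal the corrected Hertz model beyond contact", {
  sp <- cheap_spec(params = viscoelastic_params(E0 = 1400))
  cv <- generate_kvm_curve(sp)
  gt <- cv$meta$ground_truth
  d <- pmax(gt$separation - gt$cp, 0)
  expect_equal(cv$F, ding_force(1400, 0.5, 2.5e-6, d), tolerance = 1e-9)
})

test_that("generated force interpolates the hand-evaluated KVM value", {
  p <- viscoelastic_params(1000, 1000, 0.1, 1)
  cv <- generate_kvm_curve(cheap_spec(params = p))
  gt <- cv$meta$ground_truth
  d <- gt$separation - gt$cp
  F_half <- stats::approx(d, cv$F, xout = 0.5e-6)$y
  expect_equal(F_half, 1.674e-9, tolerance = 1e-3)
})

test_that("oracle reduces to Hertz for a constant relaxation kernel", {
  t <- seq(0, 0.16, length.out = 801)
  d <- 5e-6 * t
  Fo <- hereditary_integral_force(viscoelastic_params(E0 = 1000), 2.5e-6, d, t)
  Fh <- hertz_force(1000, 0.5, 2.5e-6, d)
  sel <- d > 0.1 * max(d)
  expect_lt(max(abs(Fo[sel] - Fh[sel]) / Fh[sel]), 1e-3)
})

test_that("the Dirac term of the oracle is the closed-form viscous drag", {
  t <- seq(0, 0.16, length.out = 801)
  v <- 5e-6
  d <- v * t
  p <- viscoelastic_params(0, 0, 0, eta = 2)
  Fo <- hereditary_integral_force(p, 2.5e-6, d, t)
  # (4/(3(1-nu^2))) * sqrt(R) * eta * (3/2) * sqrt(d) * v: same sqrt(R d)
  # functional form as the explicit relation's viscous term, different
  # prefactor (2/(1-nu^2) vs the calibrated 7.25)
  expected <- (4 / (3 * 0.75)) * sqrt(2.5e-6) * 2 * 1.5 * sqrt(d) * v
  sel <- seq(3, 799)  # interior: endpoints use one-sided rates
  expect_equal(Fo[sel], expected[sel], tolerance = 1e-6)
})

test_that("halving the oracle time step changes the result by far less than 0.1%", {
  p <- viscoelastic_params(1000, 800, 0.08, 2)
  F_end <- vapply(c(401, 801), function(n) {
    t <- seq(0, 0.16, length.out = n)
    utils::tail(hereditary_integral_force(p, 2.5e-6, 5e-6 * t, t), 1)
  }, 0)
  expect_lt(abs(diff(F_end)) / F_end[2], 1e-3)
})

test_that("oracle relaxation limits match the apparent-modulus limits", {
  t <- seq(0, 0.16, length.out = 801)
  d <- 5e-6 * t
  sel <- d > 0.3 * max(d)
  cc <- calibration_constants()
  for (lam_mult in c(100, 0.001)) {
    lam <- lam_mult * 0.16
    p <- viscoelastic_params(1000, 800, lam, 0)
    Fo <- hereditary_integral_force(p, 2.5e-6, d, t)
    dm <- derived_moduli(p, cc, delta_max = max(d), v = 5e-6)
    E_lim <- if (lam_mult > 1) dm$Eu else p$E0
    expect_lt(max(abs(Fo[sel] / hertz_force(E_lim, 0.5, 2.5e-6, d[sel]) - 1)),
              0.05)
    # derived moduli agree with the limit the oracle approaches
    expect_lt(abs(dm$Eapp - E_lim) / E_lim, 0.05)
  }
})

test_that("the Maxwell contribution decays monotonically with contact time", {
  cc <- calibration_constants()
  p <- viscoelastic_params(1000, 800, 0.08, 0)
  d <- seq(1e-8, 0.8e-6, length.out = 100)
  # explicit relation: Maxwell term relative to its elastic twin
  ratio_explicit <- kvm_force(p, cc, 2.5e-6, 5e-6, d, terms = TRUE)[, "maxwell"] /
    ding_force(800, 0.5, 2.5e-6, d)
  expect_true(all(diff(ratio_explicit) < 0))
  # oracle: Maxwell content = full minus the pure-E0 run, relative to Hertz(E1)
  t <- d / 5e-6
  Fm <- hereditary_integral_force(p, 2.5e-6, d, t) -
    hereditary_integral_force(viscoelastic_params(E0 = 1000), 2.5e-6, d, t)
  # the first few samples carry the quadrature startup transient of the
  # sqrt(t) rate singularity; beyond them the decay is strictly monotone
  ratio_oracle <- (Fm / hertz_force(800, 0.5, 2.5e-6, d))[-(1:10)]
  expect_true(all(diff(ratio_oracle) < 0))
})

test_that("oracle rejects retraction histories and non-uniform grids", {
  t <- seq(0, 0.1, length.out = 100)
  d <- c(seq(0, 1e-6, length.out = 60), seq(1e-6, 0.5e-6, length.out = 40))
  expect_error(hereditary_integral_force(viscoelastic_params(1000), 2.5e-6,
                                         d, t), "retraction")
  t2 <- c(t[1:50], t[51:100] + 0.01)
  expect_error(hereditary_integral_force(viscoelastic_params(1000), 2.5e-6,
                                         5e-6 * seq_along(t2), t2), "uniform")
})

test_that("batch simulation writes readable curves and a consistent manifest", {
  dir <- withr::local_tempdir()
  man <- simulate_dataset(dir, n = 4, spec = cheap_spec(noise_sd = 2e-11),
                          group = "condA", cells = 2, seed = 7)
  files <- list.files(dir, pattern = "\\.tsv$")
  expect_length(files, 4)
  expect_equal(nrow(man), length(files))
  expect_setequal(man$file, files)
  back <- read_force_curve(file.path(dir, man$file[2]))
  expect_equal(back$meta$group, "condA")
  expect_match(back$meta$cell, "condA_cell")
  # deterministic rerun
  dir2 <- withr::local_tempdir()
  simulate_dataset(dir2, n = 4, spec = cheap_spec(noise_sd = 2e-11),
                   group = "condA", cells = 2, seed = 7)
  expect_identical(readLines(file.path(dir, files[1])),
                   readLines(file.path(dir2, files[1])))
})
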