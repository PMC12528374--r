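# Clean synthetic SLS hold-phase curve built directly from the closed form,
# independent of the package's generator.
manual_curve <- function(k1 = 1, k2 = 1, tau = 1, F0 = 2, t_app = 0.6,
                         hold = 20, dt = 0.02, baseline = 0,
                         pre_contact = 0.2) {
  t_pre <- seq(-pre_contact, -dt, by = dt)
  t_ramp <- seq(0, t_app, by = dt)
  f_ramp <- F0 * (t_ramp / t_app)^1.5
  t_hold <- seq(dt, hold, by = dt)
  f_hold <- F0 * (k2 + k1 * exp(-t_hold / tau)) / (k1 + k2)
  force_time_curve(c(t_pre, t_ramp, t_app + t_hold),
                   c(rep(0, length(t_pre)), f_ramp, f_hold) + baseline)
}

test_that("indentation strain follows the spherical-contact formula", {
  # h = 3 um, R = 27.5 um: approximately 7% strain
  expect_equal(compute_strain(3, 27.5), 0.2 * sqrt(3 / 27.5))
  expect_lt(abs(compute_strain(3, 27.5) - 0.07), 0.005)
  expect_equal(compute_strain(0, 10), 0)
  expect_equal(compute_strain(10, 10), 0.2)
  expect_error(compute_strain(1, 0), "radius")
})

test_that("preprocessing aligns, crops and normalises relaxation curves", {
  cv <- manual_curve(F0 = 2)
  pre <- preprocess_relaxation(cv)
  expect_equal(pre$t[1], 0)
  expect_equal(pre$F[1], 1)
  expect_equal(attr(pre, "F0"), 2)
  expect_equal(max(pre$t), 20)           # hold phase only
  expect_true(all(pre$F <= 1 + 1e-12))
  # negative baseline is shifted away; output identical
  shifted <- preprocess_relaxation(manual_curve(F0 = 2, baseline = -0.1))
  expect_equal(shifted$F, pre$F, tolerance = 1e-10)
  # idempotence on an already-normalised curve
  expect_equal(preprocess_relaxation(pre)$F, pre$F)
  # monotonically rising force (no hold phase) is rejected
  rising <- force_time_curve(seq(0, 1, 0.01), seq(0, 1, 0.01)^1.5 + 0.01)
  expect_error(preprocess_relaxation(rising), "hold")
})

test_that("noisy peaks are detected near the true peak", {
  set.seed(31)
  noise_sd <- 0.02 * 2
  detected <- replicate(50, {
    cv <- manual_curve(F0 = 2)
    cv$F <- cv$F + rnorm(length(cv$F), 0, noise_sd)
    attr(preprocess_relaxation(cv), "F0")
  })
  expect_true(all(abs(detected - 2) < 3 * noise_sd + 0.05))
})

test_that("curve averaging gives the pointwise mean and SD", {
  flat <- function(level, hold = 10, dt = 0.05) {
    cv <- force_time_curve(seq(0, hold, dt),
                           c(1, rep(level, hold / dt)),
                           normalized = TRUE)
    cv
  }
  avg <- average_curves(list(flat(1), flat(0.8)))
  expect_equal(mean(avg$F[-1]), 0.9, tolerance = 1e-12)
  # identical curves: SD identically zero
  same <- average_curves(list(flat(0.7), flat(0.7), flat(0.7)))
  expect_equal(attr(same, "sd"), rep(0, length(same$t)))
  # disjoint windows are rejected
  a <- force_time_curve(0:10, rep(1, 11), normalized = TRUE)
  b <- force_time_curve(20:30, rep(1, 11), normalized = TRUE)
  expect_error(average_curves(list(a, b)), "disjoint")
  # 20 noisy replicates of one truth: mean within CLT bounds of the truth
  set.seed(7)
  truth <- preprocess_relaxation(manual_curve())
  noisy <- lapply(1:20, function(i) {
    cv <- truth
    cv$F <- cv$F + rnorm(length(cv$F), 0, 0.02)
    cv
  })
  m <- average_curves(noisy)
  expect_true(all(abs(m$F - truth$F) < 3 * 0.02 / sqrt(20) + 0.01))
})

test_that("t80 is the interpolated first crossing of 80% force", {
  # SLS with k1 = k2: normalised 0.5*(1 + exp(-t/tau)) crosses 0.8 at
  # tau * ln(5/3)
  for (tau in c(0.5, 1, 3)) {
    pre <- preprocess_relaxation(manual_curve(k1 = 1, k2 = 1, tau = tau,
                                              dt = 0.01))
    r <- time_to_80pct(pre)
    expect_true(r$reached)
    expect_equal(r$t80, tau * log(5 / 3), tolerance = 0.01)
  }
  # purely elastic curve never reaches 80%
  flat <- force_time_curve(seq(0, 5, 0.1), rep(1, 51), normalized = TRUE)
  r <- time_to_80pct(flat)
  expect_false(r$reached)
  expect_true(is.na(r$t80))
  # already below the threshold at the first hold sample
  low <- force_time_curve(c(0, 1, 2), c(0.75, 0.7, 0.6), normalized = TRUE)
  expect_equal(time_to_80pct(low)$t80, 0)
})

test_that("energy dissipation reflects the relaxation amplitude", {
  flat <- force_time_curve(seq(0, 5, 0.1), rep(1, 51), normalized = TRUE)
  expect_equal(energy_dissipation_pct(flat), 0)
  # Maxwell limit (k2 = 0) held much longer than tau: full dissipation
  mx <- preprocess_relaxation(manual_curve(k1 = 1, k2 = 0, tau = 1,
                                           hold = 30))
  expect_equal(energy_dissipation_pct(mx), 100, tolerance = 0.1)
  # k1 = k2 relaxes to half the instantaneous force
  half <- preprocess_relaxation(manual_curve(k1 = 1, k2 = 1, tau = 1,
                                             hold = 30))
  expect_equal(energy_dissipation_pct(half), 50, tolerance = 0.1)
  # area definition integrates the whole transient
  expect_lt(energy_dissipation_pct(half, method = "area"),
            energy_dissipation_pct(half))
})

test_that("t80 and dissipation are invariant to uniform force rescaling", {
  cv <- manual_curve(k1 = 1, k2 = 1, tau = 2)
  cv5 <- cv; cv5$F <- cv5$F * 5
  p1 <- preprocess_relaxation(cv); p5 <- preprocess_relaxation(cv5)
  expect_equal(time_to_80pct(p1)$t80, time_to_80pct(p5)$t80)
  expect_equal(energy_dissipation_pct(p1), energy_dissipation_pct(p5))
})

test_that("Hertz fitting recovers the generating modulus", {
  # noiseless round trip is exact
  cv <- make_indentation_curve(E = 400, R = 27.5, depth_max = 3)
  expect_equal(as.numeric(hertz_fit(cv)), 400, tolerance = 1e-10)
  # all-zero force means zero modulus
  z <- indentation_curve(seq(0, 3, length.out = 50), rep(0, 50))
  expect_equal(as.numeric(hertz_fit(z)), 0)
  # 1% noise: stiff-gel modulus recovered within 2% (Monte Carlo)
  fits <- vapply(1:100, function(s)
    as.numeric(hertz_fit(make_indentation_curve(25000, noise_sd = 0.01,
                                                seed = s))), numeric(1))
  expect_true(all(abs(fits / 25000 - 1) < 0.02))
  expect_error(hertz_fit(indentation_curve(0:5, rep(0, 6))), "10 post-contact")
})

test_that("curve files round-trip through the text format", {
  cv <- manual_curve(F0 = 1.7)
  cv$group <- "soft_Vplus"
  path <- tempfile(fileext = ".tsv")
  write_curve(cv, path)
  back <- read_curve(path)
  expect_equal(back$t, cv$t, tolerance = 1e-5)
  expect_equal(back$F, cv$F, tolerance = 1e-5)
  expect_equal(back$R, cv$R)
  expect_equal(back$group, "soft_Vplus")
  expect_false(back$normalized)
})
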