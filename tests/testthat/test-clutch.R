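cp_fast <- function(...) clutch_params(n_clutch_init = 10, n_clutch_max = 20,
                                       ...)

test_that("slip-bond dissociation rate and genotype scaling", {
  p <- clutch_params()
  sc <- genotype("scRNA")
  si <- genotype("siPiezo1")
  expect_equal(koff_of_force(0, p, sc), p$k_off0)
  # Piezo1 knockdown raises force-free dissociation by 15%
  expect_equal(koff_of_force(0, p, si), 1.15 * p$k_off0)
  expect_equal(koff_of_force(p$f_bond, p, sc), exp(1) * p$k_off0)
  f <- seq(0, 20, by = 0.5)
  expect_true(all(diff(koff_of_force(f, p, sc)) >= 0))
  expect_error(koff_of_force(-1, p, sc), "negative")
  # custom knockdown strength is honoured
  expect_equal(koff_of_force(0, p, genotype("siPiezo1", koff_factor = 1.5)),
               1.5 * p$k_off0)
})

test_that("myosin force-velocity relation is linear and clamps at stall", {
  m <- motor_params(n_myosin = 10, f_stall = 2, v_unloaded = 100)
  expect_equal(retrograde_velocity(0, m), 100)
  expect_equal(retrograde_velocity(20, m), 0)
  expect_equal(retrograde_velocity(10, m), 50)
  expect_equal(retrograde_velocity(40, m), 0)  # clamped beyond stall
})

test_that("no binding is possible when k_on = 0", {
  cp <- cp_fast(k_on = 0)
  mp <- motor_params()
  sls <- sls_params(1, 1, 1)
  st <- clutch_state(cp, mp)
  set.seed(1)
  for (i in 1:50) st <- step_ensemble(st, cp, mp, sls, genotype("scRNA"),
                                      dt = 0.01)
  expect_equal(sum(st$bound), 0)
  expect_equal(st$n_recruited, cp$n_clutch_init)
  expect_equal(st$t, 0.5)
})

test_that("reinforcement is disabled by an unreachable unfolding force", {
  cp <- cp_fast(f_unfold = 1e9)
  mp <- motor_params()
  sls <- sls_params(1, 1, 1)
  st <- clutch_state(cp, mp)
  set.seed(2)
  for (i in 1:300) st <- step_ensemble(st, cp, mp, sls, genotype("scRNA"),
                                       dt = 0.005)
  expect_equal(st$n_recruited, cp$n_clutch_init)
  expect_true(all(st$vinc == 0))
})

test_that("force-free occupancy matches the two-state steady state", {
  # zero motor speed: no forces, so occupancy is k_on/(k_on + k_off)
  cp <- clutch_params(n_clutch_init = 50, n_clutch_max = 50, k_on = 1,
                      k_off0 = 2)
  mp <- motor_params(v_unloaded = 0)
  sls <- sls_params(1, 1, 1)
  res <- run_simulation(cp, mp, sls, genotype("scRNA"),
                        sim_config(duration = 400, dt = 0.02,
                                   record_every = 50, seed = 11))
  traj <- res$trajectory
  ss <- traj[traj$t > 40, ]
  p_hat <- mean(ss$n_bound) / 50
  p_true <- 1 / (1 + 2)
  # 3 standard errors with an effective-sample-size correction for
  # autocorrelation (relaxation rate k_on + k_off, samples 1 s apart)
  n_eff <- nrow(ss) / 2
  se <- sqrt(p_true * (1 - p_true) / (50 * n_eff))
  expect_lt(abs(p_hat - p_true), 3 * se + 0.01)
})

test_that("fixed-step engine matches an event-driven oracle on a 3-clutch toy", {
  k_on <- 1; k_off <- 2
  orc <- gillespie_bound_counts(3, k_on, k_off, n_events = 1e4, seed = 5)
  cp <- clutch_params(n_clutch_init = 3, n_clutch_max = 3, k_on = k_on,
                      k_off0 = k_off)
  mp <- motor_params(v_unloaded = 0)
  res <- run_simulation(cp, mp, sls_params(1, 1, 1), genotype("scRNA"),
                        sim_config(duration = 3000, dt = 0.025,
                                   record_every = 40, seed = 6))
  traj <- res$trajectory
  fixed <- traj$n_bound[traj$t > 20]
  tab <- rbind(tabulate(fixed + 1, 4), tabulate(orc$samples + 1, 4))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
  # both should centre on the binomial mean 3 * kon/(kon+koff) = 1
  expect_equal(mean(fixed), 1, tolerance = 0.1)
  expect_equal(sum(orc$occupancy * 0:3), 1, tolerance = 0.1)
})

test_that("identical seeds give bit-identical simulations", {
  cp <- clutch_params()
  mp <- motor_params()
  sls <- sls_params(0.8, 0.4, 0.4)
  cfg <- sim_config(duration = 5, seed = 99)
  r1 <- run_simulation(cp, mp, sls, genotype("scRNA"), cfg)
  r2 <- run_simulation(cp, mp, sls, genotype("scRNA"), cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$summary, r2$summary)
})

test_that("substrate force balances the summed clutch spring forces", {
  cp <- clutch_params()
  mp <- motor_params()
  for (sls in list(sls_params(0.8, 0.4, 0.4), sls_params(50, 25, 25))) {
    res <- run_simulation(cp, mp, sls, genotype("scRNA"),
                          sim_config(duration = 10, seed = 3))
    expect_lt(max(abs(res$trajectory$f_sub - res$trajectory$f_clutch_sum)),
              1e-6)
  }
})

test_that("raising the dissociation factor never raises mean occupancy", {
  cp <- clutch_params()
  mp <- motor_params()
  sls <- sls_params(0.8, 0.4, 0.4)
  bound_frac <- function(factor, seeds) {
    mean(vapply(seeds, function(s) {
      gt <- genotype("siPiezo1", koff_factor = factor)
      run_simulation(cp, mp, sls, gt,
                     sim_config(duration = 30, seed = s))$summary$bound_fraction
    }, numeric(1)))
  }
  seeds <- 1:8
  bf <- vapply(c(1, 1.5, 2.5), bound_frac, numeric(1), seeds = seeds)
  expect_true(all(diff(bf) < 0.02))   # non-increasing within noise
  expect_lt(bf[3], bf[1])             # and clearly lower at 2.5x
})

test_that("recruitment is non-decreasing and requires vinculin events", {
  cp <- clutch_params()
  mp <- motor_params()
  res <- run_simulation(cp, mp, sls_params(0.8, 0.4, 0.4), genotype("scRNA"),
                        sim_config(duration = 60, seed = 4))
  nr <- res$trajectory$n_recruited
  expect_true(all(diff(nr) >= 0))
  expect_equal(res$final_state$n_recruited,
               min(cp$n_clutch_init + cp$d_recruit * res$n_vinc_events,
                   cp$n_clutch_max))
  expect_gt(res$n_vinc_events, 0)
})

test_that("elastic substrates show the classic flow-stiffness regimes", {
  # k1 -> 0 reduces the simulator to the purely elastic clutch, with its
  # biphasic flow-stiffness curve: engaged (slow) flow at the optimal
  # intermediate stiffness, frictional slippage (fast turnover, fast flow)
  # on stiff substrates and slow force buildup on very soft ones
  cp <- clutch_params()
  mp <- motor_params()
  flows <- vapply(c(0.1, 2, 25), function(k2) {
    mean(vapply(1:4, function(s)
      run_simulation(cp, mp, sls_params(0, k2, 1), genotype("scRNA"),
                     sim_config(duration = 40, seed = s))$summary$flow,
      numeric(1)))
  }, numeric(1))
  expect_lt(flows[2], flows[1])
  expect_lt(flows[2], flows[3])
})

test_that("rate-step contract violations are rejected", {
  cp <- clutch_params()
  mp <- motor_params()
  st <- clutch_state(cp, mp)
  expect_error(step_ensemble(st, cp, mp, sls_params(1, 1, 1),
                             genotype("scRNA"), dt = 10),
               "configuration error")
})
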