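# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation.

# Event-driven (Gillespie) simulation of n independent two-state clutches
# with constant binding/unbinding rates (the zero-motor-speed limit, where
# no forces build up). Returns states of the bound-count chain sampled at
# regular intervals after a burn-in, plus time-weighted occupancy.
gillespie_bound_counts <- function(n, k_on, k_off, n_events = 1e4,
                                   sample_dt = 1, burn_in = 20, seed = 1) {
  set.seed(seed)
  nb <- 0L
  t <- 0
  occ_time <- numeric(n + 1)
  samples <- integer(0)
  next_sample <- burn_in
  for (i in seq_len(n_events)) {
    r_bind <- (n - nb) * k_on
    r_unbind <- nb * k_off
    rate <- r_bind + r_unbind
    dt <- rexp(1, rate)
    while (next_sample <= t + dt) {
      if (next_sample > burn_in - 1e-9) samples <- c(samples, nb)
      next_sample <- next_sample + sample_dt
    }
    occ_time[nb + 1] <- occ_time[nb + 1] + dt
    t <- t + dt
    nb <- if (runif(1) < r_bind / rate) nb + 1L else nb - 1L
  }
  list(samples = samples, occupancy = occ_time / sum(occ_time))
}

# Numerical energy dissipated by the SLS over one sinusoidal displacement
# cycle, by direct integration of F dx with the package's displacement-
# controlled stepper providing only the constitutive update.
sls_cycle_energy <- function(params, amp, omega, n_steps = 4000,
                             n_settle_cycles = 10) {
  period <- 2 * pi / omega
  dt <- period / n_steps
  st <- substrate_state()
  x_of <- function(tt) amp * sin(omega * tt)
  t <- 0
  # settle to periodic steady state
  for (i in seq_len(n_settle_cycles * n_steps)) {
    t <- t + dt
    st <- step_substrate_displacement(params, st, x_of(t), dt)
  }
  work <- 0
  for (i in seq_len(n_steps)) {
    x_old <- st$x
    f_old <- substrate_force(params, st)
    t <- t + dt
    st <- step_substrate_displacement(params, st, x_of(t), dt)
    work <- work + 0.5 * (f_old + substrate_force(params, st)) * (st$x - x_old)
  }
  work
}

# Stub simulation result carrying prescribed steady-state summaries, for
# observable-level tests that need deterministic inputs.
stub_result <- function(integrin_density, flow = 50) {
  structure(list(summary = list(integrin_density = integrin_density,
                                flow = flow)),
            class = "sim_result")
}
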