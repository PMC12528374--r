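#' Clutch ensemble parameters
#'
#' Kinetic and mechanical parameters of the actin-talin-integrin-fibronectin
#' clutch ensemble. The defaults are magnitudes from the motor-clutch
#' modelling literature, chosen to place the model in the regimes discussed
#' in the package vignette; they are package defaults, not values fitted to
#' any particular experiment, and every one is overridable.
#'
#' @param n_clutch_init initial available clutches (count).
#' @param n_clutch_max recruitment cap (count), `>= n_clutch_init`.
#' @param k_on clutch association rate (1/s).
#' @param k_off0 force-free dissociation rate (1/s).
#' @param f_bond force scale of slip-bond unbinding (pN): the dissociation
#'   rate grows as `exp(f/f_bond)`.
#' @param k_clutch clutch spring stiffness (pN/nm).
#' @param f_unfold talin unfolding force threshold (pN), `> 0`.
#' @param k_vin vinculin binding rate to unfolded talin (1/s).
#' @param d_recruit integrins added per vinculin-binding (reinforcement)
#'   event (count).
#' @param catch_weight optional catch-bond mixture weight in `[0, 1)`; the
#'   default 0 gives a pure slip bond. With `w > 0` the dissociation rate is
#'   `k_off0 * ((1-w)*exp(f/f_bond) + w*exp(-f/f_catch))`.
#' @param f_catch force scale of the optional catch pathway (pN).
#' @return An object of class `clutch_params`.
#' @export
clutch_params <- function(n_clutch_init = 75, n_clutch_max = 750,
                          k_on = 1, k_off0 = 0.8, f_bond = 2,
                          k_clutch = 5, f_unfold = 5, k_vin = 0.3,
                          d_recruit = 5, catch_weight = 0, f_catch = 5) {
  stopifnot(n_clutch_init >= 1, n_clutch_max >= n_clutch_init,
            k_on >= 0, k_off0 >= 0, f_bond > 0, k_clutch >= 0,
            f_unfold > 0, k_vin >= 0, d_recruit >= 0,
            catch_weight >= 0, catch_weight < 1, f_catch > 0)
  structure(list(n_clutch_init = as.integer(n_clutch_init),
                 n_clutch_max = as.integer(n_clutch_max),
                 k_on = k_on, k_off0 = k_off0, f_bond = f_bond,
                 k_clutch = k_clutch, f_unfold = f_unfold, k_vin = k_vin,
                 d_recruit = as.integer(d_recruit),
                 catch_weight = catch_weight, f_catch = f_catch),
            class = "clutch_params")
}

#' Myosin motor parameters
#'
#' @param n_myosin number of myosin motors.
#' @param f_stall stall force per motor (pN).
#' @param v_unloaded unloaded retrograde flow speed (nm/s).
#' @return An object of class `motor_params`.
#' @export
motor_params <- function(n_myosin = 75, f_stall = 2, v_unloaded = 110) {
  stopifnot(n_myosin > 0, f_stall > 0, v_unloaded >= 0)
  structure(list(n_myosin = n_myosin, f_stall = f_stall,
                 v_unloaded = v_unloaded),
            class = "motor_params")
}

#' Genotype: Piezo1 perturbation as a clutch-dissociation factor
#'
#' Piezo1 acts as an integrin co-regulator whose potentiation stabilises the
#' clutch; its knockdown is modelled as a multiplicative increase of the
#' force-free dissociation rate. The control (`"scRNA"`, scrambled siRNA)
#' has factor 1; the knockdown (`"siPiezo1"`) defaults to a 15% increase.
#'
#' @param label `"scRNA"` or `"siPiezo1"`.
#' @param koff_factor multiplicative factor on `k_off0`; defaults to 1 for
#'   scRNA and 1.15 for siPiezo1.
#' @return An object of class `genotype`.
#' @examples
#' genotype("siPiezo1")$koff_factor  # 1.15
#' @export
genotype <- function(label = c("scRNA", "siPiezo1"), koff_factor = NULL) {
  label <- match.arg(label)
  if (is.null(koff_factor))
    koff_factor <- if (label == "siPiezo1") 1.15 else 1.0
  stopifnot(koff_factor > 0)
  structure(list(label = label, koff_factor = koff_factor),
            class = "genotype")
}

#' Force-dependent clutch dissociation rate
#'
#' Slip-bond law `koff_factor * k_off0 * exp(f/f_bond)` (optionally mixed
#' with a catch pathway, see [clutch_params]). Monotone non-decreasing in
#' force for the pure slip bond.
#'
#' @param f clutch force (pN), `>= 0`; vectorised.
#' @param params a [clutch_params] object.
#' @param genotype a [genotype] object.
#' @return Dissociation rate(s) in 1/s.
#' @examples
#' p <- clutch_params()
#' koff_of_force(0, p, genotype("siPiezo1"))  # 1.15 * k_off0
#' @export
koff_of_force <- function(f, params, genotype) {
  if (any(f < 0))
    stop("negative clutch force: internal force-balance bug")
  slip <- exp(f / params$f_bond)
  k <- if (params$catch_weight > 0) {
    params$k_off0 * ((1 - params$catch_weight) * slip +
                       params$catch_weight * exp(-f / params$f_catch))
  } else {
    params$k_off0 * slip
  }
  genotype$koff_factor * k
}

#' Retrograde flow speed under load
#'
#' Linear myosin force-velocity relation clamped at stall:
#' `v = v_unloaded * max(0, 1 - f_total/(n_myosin * f_stall))`.
#'
#' @param f_total total substrate load opposing the motors (pN), `>= 0`;
#'   vectorised.
#' @param motors a [motor_params] object.
#' @return Speed(s) in nm/s.
#' @export
retrograde_velocity <- function(f_total, motors) {
  stopifnot(all(f_total >= 0))
  motors$v_unloaded * pmax(0, 1 - f_total / (motors$n_myosin * motors$f_stall))
}

#' Initial clutch ensemble state
#'
#' All clutches unbound, substrate at rest, clutch pool at its initial size.
#'
#' @param params a [clutch_params] object.
#' @param motors a [motor_params] object (sets the initial, unloaded,
#'   retrograde velocity).
#' @return An object of class `clutch_state` with per-clutch vectors of
#'   length `n_clutch_max` (`bound`, `xpos`, `unfolded`, `vinc`), a
#'   [substrate_state], the current pool size `n_recruited`, clock `t` and
#'   current actin speed `v`.
#' @export
clutch_state <- function(params, motors) {
  n <- params$n_clutch_max
  structure(list(bound = integer(n), xpos = numeric(n),
                 unfolded = integer(n), vinc = integer(n),
                 substrate = substrate_state(),
                 n_recruited = params$n_clutch_init,
                 t = 0, v = motors$v_unloaded),
            class = "clutch_state")
}

# Auto time step: 0.1 over the largest transition rate encountered in
# practice (association, vinculin binding, and dissociation evaluated at the
# talin unfolding force, beyond which a slip-bond clutch is short-lived),
# additionally capped by the substrate integrator contract dt <= tau/10.
auto_dt <- function(clutch, motors, sls, genotype) {
  k_unbind_hi <- koff_of_force(clutch$f_unfold, clutch, genotype)
  rate_max <- max(clutch$k_on, clutch$k_vin, k_unbind_hi)
  dt <- 0.1 / rate_max
  if (is.finite(sls$tau)) dt <- min(dt, sls$tau / 10)
  dt
}

.run_core <- function(state, clutch, motors, sls, genotype, dt, n_steps,
                      record_every) {
  if (dt <= 0) stop("dt must be > 0")
  # contract: no force-free transition probability above ~0.1 per step, and
  # the quasi-static substrate update needs dt well below tau
  rate_hi <- max(clutch$k_on, clutch$k_vin,
                 genotype$koff_factor * clutch$k_off0)
  if (rate_hi * dt > 0.1 + 1e-12)
    stop("configuration error: max transition rate * dt = ",
         signif(rate_hi * dt, 3), " exceeds 0.1")
  if (is.finite(sls$tau) && dt > sls$tau / 10 + 1e-12)
    stop("configuration error: dt exceeds tau_relax/10")
  out <- clutch_simulate_cpp(
    bound = state$bound, xpos = state$xpos, unfolded = state$unfolded,
    vinc = state$vinc, x_sub = state$substrate$x,
    f_maxwell = state$substrate$f_maxwell,
    n_recruited = state$n_recruited, t = state$t, v = state$v,
    n_clutch_max = clutch$n_clutch_max, k_on = clutch$k_on,
    k_off0 = clutch$k_off0, f_bond = clutch$f_bond,
    k_clutch = clutch$k_clutch, f_unfold = clutch$f_unfold,
    k_vin = clutch$k_vin, d_recruit = clutch$d_recruit,
    catch_weight = clutch$catch_weight, f_catch = clutch$f_catch,
    n_myosin = motors$n_myosin, f_stall = motors$f_stall,
    v_unloaded = motors$v_unloaded,
    k1 = sls$k1, k2 = sls$k2, eta = sls$eta,
    koff_factor = genotype$koff_factor,
    dt = dt, n_steps = n_steps, record_every = record_every)
  new_state <- structure(
    list(bound = out$bound, xpos = out$xpos, unfolded = out$unfolded,
         vinc = out$vinc,
         substrate = substrate_state(out$x_sub, out$f_maxwell),
         n_recruited = out$n_recruited, t = out$t, v = out$v),
    class = "clutch_state")
  list(state = new_state, trajectory = out$trajectory,
       n_vinc_events = out$n_vinc_events)
}

#' Advance the clutch ensemble by one Monte Carlo step
#'
#' Executes a single fixed time step of the clutch Monte Carlo: binding,
#' advection with the actin, substrate force balance, force-dependent
#' unbinding, talin unfolding, vinculin binding with integrin recruitment,
#' and retrograde-velocity update. Randomness comes from R's RNG, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param state a [clutch_state].
#' @param clutch a [clutch_params].
#' @param motors a [motor_params].
#' @param sls an [sls_params].
#' @param genotype a [genotype].
#' @param dt time step (s); must keep the largest transition rate times `dt`
#'   at or below 0.1.
#' @return The advanced [clutch_state].
#' @export
step_ensemble <- function(state, clutch, motors, sls, genotype, dt) {
  .run_core(state, clutch, motors, sls, genotype, dt,
            n_steps = 1L, record_every = 1L)$state
}

#' Simulation configuration
#'
#' @param duration total simulated time (s). The steady-state window used by
#'   summaries is the last `ss_fraction` of the run.
#' @param dt time step (s); `NULL` (default) auto-selects `0.1` over the
#'   largest transition rate, capped at `tau/10`.
#' @param record_every record one output sample every this many steps.
#' @param seed RNG seed for the run (integer).
#' @param ss_fraction fraction of the run, at the end, treated as steady
#'   state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 100, dt = NULL, record_every = 20L,
                       seed = 1L, ss_fraction = 0.5) {
  stopifnot(duration > 0, is.null(dt) || dt > 0, record_every >= 1,
            ss_fraction > 0, ss_fraction <= 1)
  structure(list(duration = duration, dt = dt,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed), ss_fraction = ss_fraction),
            class = "sim_config")
}

#' Run a full clutch simulation
#'
#' Runs the Monte Carlo engine from the rest state for `config$duration`
#' seconds and returns the recorded trajectory together with steady-state
#' summaries (time averages over the last `ss_fraction` of the run):
#' integrin density (`n_recruited`, arb. units), bound fraction, substrate
#' force and retrograde flow speed. Identical seeds give bit-identical
#' results.
#'
#' @inheritParams step_ensemble
#' @param config a [sim_config].
#' @return An object of class `sim_result`: list with `trajectory` (a
#'   data.frame, one row per recorded step), `summary` (named list),
#'   `n_vinc_events`, and the parameter objects used.
#' @export
run_simulation <- function(clutch, motors, sls, genotype, config) {
  dt <- if (is.null(config$dt)) auto_dt(clutch, motors, sls, genotype)
        else config$dt
  n_steps <- max(1L, as.integer(ceiling(config$duration / dt)))
  set.seed(config$seed)
  state <- clutch_state(clutch, motors)
  res <- .run_core(state, clutch, motors, sls, genotype, dt, n_steps,
                   config$record_every)
  traj <- res$trajectory
  ss <- traj[traj$t >= (1 - config$ss_fraction) * max(traj$t), , drop = FALSE]
  summary <- list(
    integrin_density = mean(ss$n_recruited),
    bound_fraction = mean(ss$n_bound / ss$n_recruited),
    f_sub = mean(ss$f_sub),
    flow = mean(ss$v),
    dt = dt, duration = config$duration, seed = config$seed)
  structure(list(trajectory = traj, summary = summary,
                 n_vinc_events = res$n_vinc_events,
                 final_state = res$state,
                 params = list(clutch = clutch, motors = motors, sls = sls,
                               genotype = genotype, config = config)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("Clutch simulation (%s, %.0f s, dt = %.2g s)\n",
           "  steady-state integrin density: %.1f arb.units\n",
           "  steady-state bound fraction:   %.3f\n",
           "  steady-state substrate force:  %.1f pN\n",
           "  steady-state retrograde flow:  %.1f nm/s\n"),
    x$params$genotype$label, s$duration, s$dt,
    s$integrin_density, s$bound_fraction, s$f_sub, s$flow))
  invisible(x)
}
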