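#' Specification for a synthetic stress-relaxation curve
#'
#' Mirrors the nanoindentation protocol: spherical probe of radius `R`
#' driven at `approach_speed` to depth `h`, then held for `hold_time` while
#' force relaxes under SLS (Standard Linear Solid) viscoelasticity.
#'
#' @param sls an [sls_params] object (ground truth).
#' @param R probe radius (µm), default 27.5.
#' @param h indentation depth (µm), default 3.
#' @param approach_speed indentation speed (µm/s), default 5.
#' @param hold_time hold duration (s), default 60.
#' @param sampling_rate samples per second (Hz).
#' @param noise_sd additive Gaussian force noise, as a fraction of the peak
#'   force F0.
#' @param f0 peak force at the end of the approach (nN).
#' @param seed RNG seed.
#' @param group label attached to generated curves.
#' @return An object of class `curve_gen_spec`.
#' @export
curve_gen_spec <- function(sls, R = 27.5, h = 3, approach_speed = 5,
                           hold_time = 60, sampling_rate = 20,
                           noise_sd = 0, f0 = 2, seed = 1L,
                           group = NA_character_) {
  stopifnot(inherits(sls, "sls_params"), hold_time > 0, noise_sd >= 0,
            R > 0, h > 0, approach_speed > 0, sampling_rate > 0, f0 > 0)
  structure(list(sls = sls, R = R, h = h, approach_speed = approach_speed,
                 hold_time = hold_time, sampling_rate = sampling_rate,
                 noise_sd = noise_sd, f0 = f0, seed = as.integer(seed),
                 group = group),
            class = "curve_gen_spec")
}

#' Generate a synthetic stress-relaxation curve
#'
#' Forward model of the indentation protocol: a monotone Hertz-shaped
#' approach ramp reaching the peak force `f0` at depth `h`, followed by a
#' hold phase whose force follows the SLS reduced relaxation function,
#' `f0 * (k2 + k1 * exp(-t/tau)) / (k1 + k2)`, plus i.i.d. Gaussian noise of
#' standard deviation `noise_sd * f0`. The approach (h / approach_speed,
#' 0.6 s under the default protocol) is treated quasi-statically; it is two
#' orders of magnitude shorter than the default 60 s hold.
#'
#' @param spec a [curve_gen_spec].
#' @return A raw [force_time_curve] (seed-deterministic).
#' @export
make_relaxation_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_gen_spec"))
  p <- spec$sls
  t_app <- spec$h / spec$approach_speed
  dt <- 1 / spec$sampling_rate
  t_ramp <- seq(0, t_app, by = dt)
  depth <- spec$approach_speed * t_ramp
  f_ramp <- spec$f0 * (depth / spec$h)^1.5
  t_hold <- seq(dt, spec$hold_time, by = dt)
  f_hold <- spec$f0 * relaxation_force(p, 1, t_hold) / (p$k1 + p$k2)
  t_all <- c(t_ramp, t_app + t_hold)
  f_all <- c(f_ramp, f_hold)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    f_all <- f_all + rnorm(length(f_all), 0, spec$noise_sd * spec$f0)
  }
  force_time_curve(t_all, f_all, R = spec$R, h = spec$h, group = spec$group)
}

#' Generate a synthetic Hertzian indentation curve
#'
#' Forward model used to exercise [hertz_fit]:
#' `F = (4/3) * E/(1-nu^2) * sqrt(R) * depth^(3/2)` plus optional Gaussian
#' noise (as a fraction of the maximum force). The noiseless round trip
#' through [hertz_fit] returns `E` exactly.
#'
#' @param E Young's modulus (Pa), `>= 0`.
#' @param R probe radius (µm).
#' @param depth_max maximum indentation depth (µm).
#' @param noise_sd noise SD as a fraction of the maximum force.
#' @param seed RNG seed.
#' @param n number of samples.
#' @param poisson Poisson ratio used in the forward model.
#' @return An [indentation_curve].
#' @export
make_indentation_curve <- function(E, R = 27.5, depth_max = 3,
                                   noise_sd = 0, seed = 1L, n = 200,
                                   poisson = 0.5) {
  stopifnot(E >= 0, depth_max > 0, n >= 10)
  depth <- seq(0, depth_max, length.out = n)
  # E [Pa] -> prefactor in nN/µm^1.5 (inverse of the unit chain in hertz_fit)
  C <- E * sqrt(R) / (0.75 * (1 - poisson^2) * 1e3)
  FF <- C * depth^1.5
  if (noise_sd > 0) {
    set.seed(seed)
    FF <- FF + rnorm(n, 0, noise_sd * max(FF))
  }
  indentation_curve(depth, FF, R = R)
}

#' Default simulation grid: two stiffnesses x two relaxation classes x two
#' genotypes
#'
#' Encodes the standard experiment: hydrogel pairs of matched equilibrium
#' stiffness but contrasting stress relaxation, each seen by control
#' (scRNA) and Piezo1-knockdown (siPiezo1) cells. Spring constants are in
#' pN/nm per clutch-scale adhesion (about 1 pN/nm per kPa of bulk modulus,
#' so 0.4 and 25 pN/nm for the ~0.4 kPa "soft" and ~25 kPa "stiff"
#' classes). Within each pair the equilibrium spring k2 is identical; the
#' fast-relaxing V+ member has a four-fold larger Maxwell-arm share (higher
#' dissipation amplitude) and half the relaxation time of the slow-relaxing
#' V-. These are package defaults calibrated as described in the vignette,
#' not values fitted to a specific experiment.
#'
#' @param n_replicates simulations per condition (default 26).
#' @param root_seed root seed for deterministic replicate seeds.
#' @param soft_k2,stiff_k2 equilibrium spring constants (pN/nm).
#' @param share_vminus,share_vplus Maxwell-arm share `k1/k2` for V- and V+.
#' @param tau_vminus,tau_vplus relaxation times (s) for V- and V+.
#' @return A `grid_spec` list: `substrates` (named [sls_params] list:
#'   soft_Vminus, soft_Vplus, stiff_Vminus, stiff_Vplus), `genotypes`,
#'   `n_replicates`, `root_seed`, plus the default `clutch`, `motors` and
#'   `sim` blocks.
#' @examples
#' g <- make_default_grid()
#' g$substrates$soft_Vplus$tau / g$substrates$soft_Vminus$tau  # 0.5
#' @export
make_default_grid <- function(n_replicates = 26, root_seed = 1L,
                              soft_k2 = 0.4, stiff_k2 = 25,
                              share_vminus = 0.5, share_vplus = 2,
                              tau_vminus = 1, tau_vplus = 0.5) {
  stopifnot(share_vplus > share_vminus, tau_vplus <= tau_vminus)
  mk <- function(k2, share, tau)
    sls_params(k1 = share * k2, k2 = k2, eta = tau * share * k2)
  structure(list(
    substrates = list(
      soft_Vminus = mk(soft_k2, share_vminus, tau_vminus),
      soft_Vplus = mk(soft_k2, share_vplus, tau_vplus),
      stiff_Vminus = mk(stiff_k2, share_vminus, tau_vminus),
      stiff_Vplus = mk(stiff_k2, share_vplus, tau_vplus)),
    genotypes = c("scRNA", "siPiezo1"),
    koff_factors = list(scRNA = 1.0, siPiezo1 = 1.15),
    n_replicates = as.integer(n_replicates),
    root_seed = as.integer(root_seed),
    clutch = clutch_params(),
    motors = motor_params(),
    sim = sim_config(duration = 100)),
    class = "grid_spec")
}
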