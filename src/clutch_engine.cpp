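#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step (tau-leaping) Monte Carlo engine for the molecular clutch
// ensemble pulling on a Standard Linear Solid substrate.
//
// State vectors have length n_clutch_max; only the first n_recruited slots
// are active. Per step, in order: (1) unbound clutches bind with probability
// 1-exp(-k_on*dt) at zero extension; (2) bound clutches advance with the
// actin at v*dt; (3) the substrate deformation is updated by quasi-static
// force balance against the summed clutch load, with the Maxwell arm
// integrated exactly (linear deformation within the step); (4) bound
// clutches unbind with probability 1-exp(-koff(f)*dt), resetting extension
// and losing talin unfolding / vinculin; (5) clutches at force >= f_unfold
// unfold talin; (6) unfolded clutches acquire vinculin with probability
// 1-exp(-k_vin*dt); (7) each new vinculin event recruits d_recruit clutches
// up to n_clutch_max; (8) the retrograde velocity is recomputed from the
// substrate load via the linear force-velocity relation.
//
// Randomness is drawn from R's RNG (unif_rand) so set.seed() in R makes
// every trajectory reproducible.

static inline double koff_rate(double f, double k_off0, double f_bond,
                               double catch_weight, double f_catch,
                               double koff_factor) {
  double slip = std::exp(f / f_bond);
  double k;
  if (catch_weight > 0.0)
    k = k_off0 * ((1.0 - catch_weight) * slip +
                  catch_weight * std::exp(-f / f_catch));
  else
    k = k_off0 * slip;
  return koff_factor * k;
}

// [[Rcpp::export]]
List clutch_simulate_cpp(IntegerVector bound, NumericVector xpos,
                         IntegerVector unfolded, IntegerVector vinc,
                         double x_sub, double f_maxwell, int n_recruited,
                         double t, double v,
                         int n_clutch_max, double k_on, double k_off0,
                         double f_bond, double k_clutch, double f_unfold,
                         double k_vin, int d_recruit,
                         double catch_weight, double f_catch,
                         double n_myosin, double f_stall, double v_unloaded,
                         double k1, double k2, double eta,
                         double koff_factor,
                         double dt, int n_steps, int record_every) {
  if (bound.size() < n_clutch_max)
    stop("state vectors shorter than n_clutch_max");
  if (n_recruited > n_clutch_max)
    stop("n_recruited exceeds n_clutch_max");

  // Maxwell-arm exponential update coefficients: f_m' = a*f_m + c*dx
  double a, c;
  if (k1 > 0.0) {
    a = std::exp(-dt * k1 / eta);
    c = eta * (1.0 - a) / dt;
  } else {
    a = 1.0;
    c = 0.0;
  }

  const double p_on = 1.0 - std::exp(-k_on * dt);
  const double p_vin = 1.0 - std::exp(-k_vin * dt);
  const double f_stall_total = n_myosin * f_stall;

  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_fsub(n_rec), rec_fclutch(n_rec),
      rec_v(n_rec), rec_xsub(n_rec);
  IntegerVector rec_nbound(n_rec), rec_nrecruited(n_rec);
  int i_rec = 0;
  int n_vinc_events = 0;

  for (int s = 0; s < n_steps; ++s) {
    // (1) binding: unbound active clutches attach at the current substrate
    // position (zero extension)
    for (int i = 0; i < n_recruited; ++i) {
      if (!bound[i]) {
        if (unif_rand() < p_on) {
          bound[i] = 1;
          xpos[i] = x_sub;
          unfolded[i] = 0;
          vinc[i] = 0;
        }
      }
    }

    // (2) bound clutches move with the actin
    double S = 0.0;
    int nb = 0;
    for (int i = 0; i < n_recruited; ++i) {
      if (bound[i]) {
        xpos[i] += v * dt;
        S += xpos[i];
        ++nb;
      }
    }

    // (3) substrate force balance at end of step:
    //   k2*x' + a*f_m + c*(x'-x) = k_clutch * (S - nb*x')
    double x_new;
    if (nb > 0)
      x_new = (k_clutch * S + c * x_sub - a * f_maxwell) /
              (k2 + c + k_clutch * nb);
    else
      x_new = (c * x_sub - a * f_maxwell) / (k2 + c);
    f_maxwell = a * f_maxwell + c * (x_new - x_sub);
    x_sub = x_new;
    double f_sub = k2 * x_sub + f_maxwell;

    if (!std::isfinite(x_sub) || !std::isfinite(f_maxwell))
      stop("non-finite substrate state at t = %f (diverged simulation)", t);

    // snapshot at the force-balance point
    if (s % record_every == 0) {
      double fc = 0.0;
      for (int i = 0; i < n_recruited; ++i)
        if (bound[i]) fc += k_clutch * (xpos[i] - x_sub);
      rec_t[i_rec] = t + dt;
      rec_fsub[i_rec] = f_sub;
      rec_fclutch[i_rec] = fc;
      rec_xsub[i_rec] = x_sub;
      rec_nbound[i_rec] = nb;
      rec_v[i_rec] = v;
      rec_nrecruited[i_rec] = n_recruited;
      ++i_rec;
    }

    // (4)-(7) per-clutch kinetics at the balanced forces
    for (int i = 0; i < n_recruited; ++i) {
      if (!bound[i]) continue;
      double f = k_clutch * (xpos[i] - x_sub);
      if (f < 0.0) f = 0.0;  // transiently slack clutch carries no load
      double koff = koff_rate(f, k_off0, f_bond, catch_weight, f_catch,
                              koff_factor);
      if (unif_rand() < 1.0 - std::exp(-koff * dt)) {
        bound[i] = 0;
        xpos[i] = 0.0;
        unfolded[i] = 0;  // talin refolds, vinculin lost
        vinc[i] = 0;
        continue;
      }
      if (f >= f_unfold) unfolded[i] = 1;
      if (unfolded[i] && !vinc[i]) {
        if (unif_rand() < p_vin) {
          vinc[i] = 1;
          ++n_vinc_events;
          n_recruited = std::min(n_recruited + d_recruit, n_clutch_max);
        }
      }
    }

    // (8) retrograde velocity from the substrate load
    double load = f_sub > 0.0 ? f_sub : 0.0;
    double red = 1.0 - load / f_stall_total;
    v = v_unloaded * (red > 0.0 ? red : 0.0);

    t += dt;
  }

  DataFrame traj = DataFrame::create(
      _["t"] = rec_t[Range(0, i_rec - 1)],
      _["f_sub"] = rec_fsub[Range(0, i_rec - 1)],
      _["f_clutch_sum"] = rec_fclutch[Range(0, i_rec - 1)],
      _["x_sub"] = rec_xsub[Range(0, i_rec - 1)],
      _["n_bound"] = rec_nbound[Range(0, i_rec - 1)],
      _["n_recruited"] = rec_nrecruited[Range(0, i_rec - 1)],
      _["v"] = rec_v[Range(0, i_rec - 1)]);

  return List::create(
      _["bound"] = bound, _["xpos"] = xpos, _["unfolded"] = unfolded,
      _["vinc"] = vinc, _["x_sub"] = x_sub, _["f_maxwell"] = f_maxwell,
      _["n_recruited"] = n_recruited, _["t"] = t, _["v"] = v,
      _["n_vinc_events"] = n_vinc_events, _["trajectory"] = traj);
}
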