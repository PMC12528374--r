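---
title: "Molecular clutch dynamics on viscoelastic substrates: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular clutch dynamics on viscoelastic substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscoclutch)
```

## The model

`viscoclutch` simulates an ensemble of molecular clutches — integrin-based
links between the rearward-flowing actin cytoskeleton and the substrate —
pulling on a viscoelastic substrate, together with the talin/vinculin
reinforcement loop that turns sustained force into adhesion growth.

### Substrate: Standard Linear Solid

The substrate is the minimal viscoelastic solid: an equilibrium spring
$k_2$ in parallel with a Maxwell arm (spring $k_1$ in series with a dashpot
$\eta$). This topology is fixed by the phenomenology we target: a step
indentation meets the instantaneous stiffness $k_1 + k_2$ and relaxes to the
equilibrium stiffness $k_2$,
$$F(t) = x_0\,\bigl(k_2 + k_1 e^{-t/\tau}\bigr), \qquad \tau = \eta / k_1 .$$
Stiffness is expressed as a spring constant (pN/nm) seen by a point-like
adhesion rather than a bulk modulus; we document the conversion as roughly
1 pN/nm per kPa, so the ~0.4 kPa and ~25 kPa hydrogel classes map to 0.4 and
25 pN/nm. In state-space form the substrate carries deformation $x$ and the
Maxwell-arm force $f_m$, with $F = k_2 x + f_m$ and
$\dot f_m = k_1\dot x - f_m/\tau$.

**Numerics.** Within a time step the deformation is assumed linear, under
which the Maxwell update is exact for any step size:
$f_m' = a f_m + c\,(x'-x)$ with $a = e^{-\Delta t/\tau}$,
$c = \eta(1-a)/\Delta t$. This exponential update (rather than explicit
Euler) is unconditionally accurate on stiff $\tau$; the degenerate cases
fall out correctly ($k_1 \to 0$ gives a pure spring $k_2$;
$\eta \to \infty$ gives $c \to k_1$, a pure spring $k_1+k_2$). Force- and
displacement-controlled steppers share this update; the force-controlled
stepper additionally enforces $\Delta t \le \tau/10$, the regime in which
the quasi-static force-balance assumption below is sound.

### Clutch ensemble

Each of $n$ available clutches is unbound or bound; a bound clutch is a
spring $k_c$ anchored at actin position $x_i$ and loaded against the
substrate, $f_i = k_c (x_i - x_{sub})$. One fixed step of length
$\Delta t$ applies, in order:

1. unbound clutches bind with probability $1 - e^{-k_{on}\Delta t}$, at zero
   extension ($x_i = x_{sub}$);
2. bound clutches advance with the actin, $x_i \mathrel{+}= v\,\Delta t$;
3. the substrate deformation is updated by quasi-static force balance
   against the summed clutch load — substituting the Maxwell update into
   $k_2 x' + f_m' = k_c \sum_i (x_i - x')$ gives a closed-form $x'$;
4. bound clutches unbind with probability $1 - e^{-k_{off}(f_i)\Delta t}$,
   where $k_{off}(f) = \gamma\, k_{off,0}\, e^{f/f_{bond}}$ (slip bond;
   $\gamma$ is the genotype factor). Unbinding resets extension, refolds
   talin and releases vinculin — reinforcement is not remembered per
   clutch, but the recruited pool persists;
5. clutches at $f_i \ge f_{unfold}$ unfold talin;
6. unfolded, vinculin-free clutches acquire vinculin with probability
   $1 - e^{-k_{vin}\Delta t}$;
7. each vinculin event recruits $d_{recruit}$ clutches, up to
   $n_{max}$ — the model's focal-adhesion growth;
8. the retrograde velocity is recomputed from the substrate load via the
   linear motor law $v = v_0 \max(0,\, 1 - F/(N_m f_{stall}))$.

A transiently slack clutch (possible when the substrate creeps past a
recently bound neighbour) carries zero force rather than pushing. Piezo1
knockdown enters only as $\gamma = 1.15$ (control $\gamma = 1$): the
channel's integrin co-regulation is reduced to a scalar destabilisation of
the clutch. An optional catch-slip mixture
($k_{off} \propto (1-w)e^{f/f_{bond}} + w\,e^{-f/f_{catch}}$) is available
behind `catch_weight`; the default is the pure slip bond, the simplest law
consistent with a scalar knockdown effect.

**Time step.** $\Delta t = 0.1 / r_{max}$, where $r_{max}$ is the largest
rate the run is expected to visit — association, vinculin binding, and
dissociation evaluated at the unfolding force (beyond which a slip-bond
clutch is short-lived) — additionally capped at $\tau/10$. With the default
parameters this gives $\Delta t \approx 0.01$ s. Transition probabilities
use the exact exponential form, so probabilities stay in $[0,1]$ even for
force excursions above $f_{unfold}$. The engine runs on R's RNG
(`set.seed()` reproduces any trajectory bit for bit); an event-driven
Gillespie implementation of the same kinetics lives in the test suite as an
independent oracle, and the fixed-step engine matches its occupancy
statistics on a force-free toy ensemble.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_clutch_init` / `n_clutch_max` | 75 / 750 | – | initial pool / recruitment cap |
| `k_on` | 1 | 1/s | clutch association |
| `k_off0` | 0.8 | 1/s | force-free dissociation |
| `f_bond` | 2 | pN | slip-bond force scale |
| `k_clutch` | 5 | pN/nm | clutch spring |
| `f_unfold` | 5 | pN | talin unfolding threshold |
| `k_vin` | 0.3 | 1/s | vinculin binding to unfolded talin |
| `d_recruit` | 5 | – | integrins per reinforcement event |
| `n_myosin`, `f_stall`, `v_unloaded` | 75, 2, 110 | –, pN, nm/s | motor block |

These magnitudes come from the motor-clutch modelling literature, with
three values set by calibration rather than citation. `f_unfold = 5` pN is
at the low end of talin rod-domain unfolding forces; at 10 pN the soft
substrates never unfold talin (per-clutch force is capped near
$N_m f_{stall}/n_{bound} \approx 8$ pN by motor stall) and all soft
recruitment vanishes. `k_vin = 0.3`/s makes vinculin binding slower than
clutch cycling on stiff substrates but comparable to the loaded-clutch
lifetime on soft ones — the mechanism by which increasing stiffness can
*decrease* recruitment among fast-relaxing substrates. `k_off0 = 0.8`/s
sets the overall turnover so that a 15% dissociation increase lowers
recruitment in every condition. The calibration targeted the qualitative
trend pattern of the modelled experiment (see below) and was frozen before
the acceptance suite; none of these are fitted to any particular data set.

### The default condition grid

`make_default_grid()` encodes the 2 × 2 × 2 experiment: soft
($k_2 = 0.4$ pN/nm) and stiff ($k_2 = 25$ pN/nm) substrate pairs, each with
a slow-relaxing V− member (Maxwell share $k_1/k_2 = 0.5$, $\tau = 1$ s) and
a fast-relaxing V+ member ($k_1/k_2 = 2$, $\tau = 0.5$ s), crossed with
scRNA/siPiezo1. Within a pair the equilibrium stiffness is matched — the
pairs differ in *how fast* they relax, not in how stiff they end up. Two
constraints shaped the shares: the V− share must exceed 0.25 or its
normalised relaxation plateaus above 0.8 and t80 is undefined; and the V+
member must carry the larger share so that it also shows the larger
dissipation amplitude, as fast-relaxing hydrogels do. The closed-form t80
values are $\tau \ln(k_1 / (0.8(k_1{+}k_2) - k_2))$: 0.92 s for V− and
0.18 s for V+ — the V+ member both starts relaxing faster (smaller $\tau$)
and relaxes further.

Relaxation times are on the clutch timescale (seconds), not the hydrogel
bulk timescale: what matters to the model is the ratio of substrate
relaxation to clutch loading and vinculin binding times, and the grid is
specified directly in that regime.

## Observables and trend assertions

A run reports time series plus steady-state summaries averaged over the
last 50% of the run: integrin density (the recruited pool, in arbitrary
units), bound fraction, substrate force, retrograde flow. Integrin density
converts to focal-adhesion length via the fixed linear scaling
84.1 arb. units = 1 µm, applied to the *time-averaged* density. Because
recruitment is non-decreasing by construction, FA length is a property of
the 100 s adhesion-growth window the default `sim_config` specifies; this
window is part of the modelled conditions (much longer windows let the
stiff conditions' slow event accumulation overtake the soft V+ condition).

`run_condition_grid()` runs 26 replicates per condition, with each
replicate's seed derived deterministically from (root seed, condition,
replicate). `trend_check()` then evaluates six assertions on condition
means: (a) soft V+ > soft V− FA length in control cells; (b) stiff V− >
soft V−; (c) soft V+ > stiff V+; (d) knockdown never above control; (e)
flow ordering anti-parallel to FA ordering within each stiffness pair; (f)
the knockdown attenuates the soft viscous FA gain. Assertions a, b, c and e
compare raw means. Assertions d and f are directional claims that 26
stochastic replicates can invert by chance when the true difference is
near zero, so they are guarded: they fail only when a one-sided permutation
test (α = 0.05; Bonferroni-adjusted across the four conditions inside d,
since d is a joint claim) finds the data significantly contradicting the
claimed direction. A knockdown with `koff_factor = 1` therefore passes d
"with equality within noise", as it should.

The area-normalised nuclear/cytoplasmic YAP ratio,
$(\mathrm{nucYAP}/\mathrm{nucA}) / (\mathrm{cytoYAP}/\mathrm{cytoA})$ with
cytoplasmic quantities defined by subtraction, is provided as a standalone
metric; it is invariant to common rescaling of intensities and of areas.

## Relaxometry pipeline

Preprocessing of a raw force–time record follows the standard sequence:
shift to zero force when the baseline (median of the leading samples) is
negative; locate the force maximum $(t_0, F_0)$; shift time so the peak is
at 0; keep only the hold phase; normalise by $F_0$. The pipeline is
idempotent on already-normalised curves, and t80 and energy dissipation are
invariant to uniform force rescaling because they act on the normalised
curve. Averaging interpolates all curves linearly onto the first curve's
grid restricted to the shared window and reports a pointwise mean ± SD;
quantification runs on the averaged curve because single curves are noisy.

* **t80** — first crossing of 0.8, linearly interpolated between the
  bracketing samples; ties broken by the earliest crossing; a curve that
  never relaxes that far returns an explicit "not reached" flag, never a
  silent NaN; a curve already below 0.8 at its first hold sample returns 0.
* **Energy dissipation** — defined here as the relaxation amplitude of the
  normalised hold, $100\,(1 - F_{end})$ (0% purely elastic, 100% fully
  relaxing Maxwell limit, $100\,k_1/(k_1+k_2)$ for an SLS held $\gg \tau$).
  An integral alternative $100\,(1 - \overline{F})$ sits behind
  `method = "area"`. The operational definition varies between labs and
  instruments; neither variant claims to reproduce any specific published
  dissipation figure numerically.
* **Young's modulus** — Hertz spherical contact
  $F = \tfrac43 \tfrac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$ with $\nu = 0.5$
  (incompressible gel), fit by linear least squares in $\delta^{3/2}$,
  which is exact, fast and never returns a spurious negative modulus
  without raising a diagnostic.

## Synthetic data: what it does and does not emulate

Every analysis stage has a forward model with known ground truth.
`make_relaxation_curve()` mirrors the indentation protocol — spherical
probe R = 27.5 µm driven at 5 µm/s to h = 3 µm (a contact strain
$0.2\sqrt{h/R} \approx 6.6\%$), held 60 s by default — generating a
monotone Hertz-shaped approach ramp and an SLS hold phase with additive
i.i.d. Gaussian force noise. The hold is treated quasi-statically: the
0.6 s approach is two orders of magnitude shorter than the hold, so the
ramp correction to the relaxation function is neglected, matching an
analysis that discards the approach anyway. `make_indentation_curve()` is
the Hertz forward model with contact at depth 0 by construction.

The generators deliberately omit instrument drift, adhesion artefacts on
retraction, heteroscedastic noise and contact-point uncertainty. Passing
round-trip tests therefore demonstrates that the analysis inverts its own
forward model under realistic noise magnitudes — not that it is robust to
every artefact of real nanoindentation data.

## Problem sizes and runtime

Defaults were chosen so a full reproduction (fixture synthesis →
relaxometry → 8-condition grid at 26 replicates, 100 s each) runs in well
under a minute on one CPU: the compiled engine advances ~10,000 steps per
100 s replicate at $\Delta t \approx 0.01$ s. The acceptance script uses 20
curves per condition at 2% noise for relaxometry recovery, 50 noise seeds
per Hertz modulus, and $10^4$ events for the Gillespie comparison.

## Known limitations

* No spatial adhesion geometry, membrane tension, Ca²⁺ dynamics or Piezo1
  gating kinetics — the knockdown is a single scalar on $k_{off}$.
* Recruitment never decays, so adhesion size is window-relative; the model
  addresses growth trends across conditions, not adhesion turnover.
* The substrate is a single scalar SLS element per adhesion; no
  poroelasticity, plasticity or strain stiffening.
* Clutch parameters are calibrated defaults, not measurements; conclusions
  should rest on the qualitative orderings the trend report checks, not on
  absolute micrometre values.
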