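# viscoclutch

Stochastic molecular-clutch simulation on viscoelastic substrates, with the
companion nanoindentation stress-relaxation analysis pipeline.

## The problem

Mesenchymal stromal cells sense not only how *stiff* their extracellular
matrix is but how fast it *relaxes* under load, and the mechanosensitive
channel Piezo1 participates in that sensing. The mechanistic workhorse for
such questions is the **molecular clutch** model: integrin-based links
transiently couple the myosin-driven, rearward-flowing actin cytoskeleton to
the substrate, transmitting force. Force in an engaged clutch unfolds talin,
vinculin binds the unfolded talin, and that reinforcement event recruits
further integrins — the in-silico analogue of focal-adhesion (FA) growth.

`viscoclutch` implements this model for a **viscoelastic** substrate and the
measurement pipeline used to characterise such substrates:

* **Substrate** — a Standard Linear Solid (SLS): spring `k2` in parallel
  with a Maxwell arm (spring `k1` + dashpot `eta`, relaxation time
  `tau = eta/k1`), giving instantaneous stiffness `k1 + k2` that relaxes to
  `k2`.
* **Clutch kinetics** — association at `k_on`; slip-bond dissociation at
  `k_off0 * exp(f / f_bond)`; talin unfolding above `f_unfold`; vinculin
  binding to unfolded talin at finite rate `k_vin`, each binding event
  recruiting `d_recruit` integrins (up to a cap).
* **Motors** — linear force–velocity: `v = v0 * max(0, 1 - F/(N*f_stall))`;
  retrograde flow speed is the inverse readout of clutch engagement.
* **Piezo1 knockdown** (siPiezo1) — modelled purely as a 15% increase of the
  clutch dissociation rate, versus the scrambled-RNA control (scRNA).
* **Relaxometry** — spherical-probe stress-relaxation analysis: strain
  `0.2*sqrt(h/R)`, peak alignment and F0-normalisation, curve averaging,
  time to 80% force (t80), % energy dissipation, and Hertzian Young's
  modulus fits `F = (4/3) E/(1-nu^2) sqrt(R) d^(3/2)`.

The Monte Carlo engine (fixed-step tau-leaping with an exact exponential
update for the Maxwell arm and quasi-static force balance each step) is
written in C++ via Rcpp and driven by R's RNG, so every run is reproducible
from its seed. An event-driven (Gillespie) implementation exists in the test
suite as an independent oracle.

## Worked example

Simulate a control cell on the soft fast-relaxing substrate of the default
grid and read off the adhesion observables:

```r
library(viscoclutch)
sls <- make_default_grid()$substrates$soft_Vplus   # k1=0.8, k2=0.4 pN/nm, tau=0.5 s
res <- run_simulation(clutch_params(), motor_params(), sls,
                      genotype("scRNA"), sim_config(duration = 100, seed = 1))
res
#> Clutch simulation (scRNA, 100 s, dt = 0.01 s)
#>   steady-state integrin density: 248.7 arb.units
#>   steady-state bound fraction:   0.289
#>   steady-state substrate force:  120.5 pN
#>   steady-state retrograde flow:  21.6 nm/s
scale_to_fa_length(res$summary$integrin_density)
#> [1] 2.96   # um of focal adhesion, via 84.1 arb.units = 1 um
```

The integrin density is the time-averaged clutch pool over the last half of
the run; dividing by 84.1 converts it to a focal-adhesion length in
micrometres. The low flow (21.6 nm/s versus 110 nm/s unloaded) says the
clutch is strongly engaged on this substrate.

The full experiment grid — soft/stiff × slow (V−)/fast (V+) relaxing ×
scRNA/siPiezo1, 26 replicates each — and its qualitative trend report:

```r
grid <- run_condition_grid(make_default_grid(root_seed = 1))
trend_check(grid)
#> Trend report:
#>   [a] scRNA soft V+ FA length > soft V-                       PASS
#>   [b] scRNA stiff V- FA length > soft V-                      PASS
#>   [c] scRNA soft V+ FA length > stiff V+                      PASS
#>   [d] siPiezo1 FA length <= scRNA in every condition          PASS
#>   [e] flow ordering anti-parallel to FA ordering within each pair PASS
#>   [f] siPiezo1 soft V+/V- gap attenuated relative to scRNA    PASS
```

Synthetic relaxation curves analysed by the relaxometry pipeline recover
their generating SLS truths:

```r
d <- tempfile(); run_synth_job(d, seed = 5)
run_relax_analyze_job(d, file.path(d, "out"))
#>          group       F0   t80   t80_reached energy_dissipation_pct n_curves
#>    soft_Vminus 2.018    0.903  TRUE         33.7                   20
#>     soft_Vplus 1.996    0.184  TRUE         66.6                   20
#>    ...
```

(V+ reaches 80% force about five times sooner and dissipates twice the
energy — the fast-relaxing member of the matched pair.)

A thin command-line front end wraps the same functions:

```sh
exec/viscoclutch synth --outdir fixtures --seed 1
exec/viscoclutch relax-analyze --indir fixtures --outdir analysis
exec/viscoclutch grid --outdir gridout --seed 1
```

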