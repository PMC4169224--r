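# adsim — stochastic simulation of anaerobic digestion kinetics

Anaerobic digesters degrade organic matter to methane through a chain of
microbial groups: acidogens ferment glucose to volatile fatty acids and
hydrogen, acetogens oxidise butyrate and propionate to acetate, and two
methanogenic populations finish the job — acetoclastic methanogens from
acetate, hydrogenotrophic methanogens from hydrogen. Deterministic ODE
models of this cascade average away the fluctuations that matter when
species counts are low; `adsim` treats the same kinetics as a discrete
jump process and simulates it stochastically, for modellers who want to
see those fluctuations and check when the deterministic picture is safe.

## The model

Eleven species (six substrates/products, five degrader populations) and
five reactions. Reaction *j* consumes one particle of its substrate per
firing, releases fixed product fractions (e.g. r4: acetate → 0.95 methane
+ 0.05 biomass), and fires with Monod propensity

    a_j(x) = mu_max_j * S_j / (K_j + S_j) * X_j

where `S_j` is the substrate count, `X_j` the degrader count,
`mu_max = (1.25, 0.833, 0.542, 0.333, 0.35)` 1/d and
`K = (500, 200, 100, 150, 150)`. Product fractions (biomass yield
included) sum to 1 per reaction, so total particle count is conserved.
Concentrations map to particles through a system-size factor Ω (the
conventional scaling is 1:5, `omega = 5`), with `K` rescaled identically.

Three engines share one rate kernel: the exact **Gillespie direct
method**, the **explicit tau-leap** method (`k_j ~ Poisson(a_j * tau)` per
interval), and a **deterministic ODE reference** (`deSolve`, lsoda at
rtol 1e-8) used as the comparison baseline.

## Worked example

```r
library(adsim)
net  <- build_ad_network()
init <- ad_initial_state(omega = 5)   # glucose 2500 particles, degraders 500 each

cfg <- sim_config("tauleap", tau = 0.4, t_end = 20, record_dt = 1,
                  seed = 42, replicates = 50, omega = 5)
ens <- simulate_ensemble(net, init, cfg)
ref <- integrate_ode(net, init, sim_config("ode", t_end = 20, record_dt = 1,
                                           omega = 5))
compare_to_ode(ens, ref)
```

```
<ad_comparison> vs ODE reference (tau = 0.4, omega = 5, n = 50)
              species    rmsd    nrmsd
              glucose 23.0800 0.009256
             butyrate  1.6320 0.023130
           propionate  4.3900 0.032510
              acetate 15.9400 0.024340
             hydrogen  7.2400 0.026350
              methane 19.5900 0.010730
      sugar_degraders  2.3080 0.009256
   butyrate_degraders  0.1913 0.011040
 propionate_degraders  0.2819 0.011700
    acetate_degraders  0.6715 0.010670
   hydrogen_degraders  0.4598 0.011450
overall normalized RMS: 0.016403
```

Over 20 simulated days the 50-replicate tau-leap ensemble mean tracks the
deterministic reference to within ~1–3% of each species' dynamic range
(`rmsd` is in particles, `nrmsd` divides by the species' ODE range).
Shrinking `tau` through 1.0 → 0.1 drives the deviation down monotonically;
growing Ω does the same for the direct method.

Methane pathway attribution from the stoichiometric cascade:

```r
attribute_methane(cascade_totals(net, glucose_units = 1), net)
```

```
<ad_attribution>
  methane from acetate  : 0.560456
  methane from hydrogen : 0.275708
  acetoclastic share    : 67.03%
```

One fully converted glucose unit yields 0.590 units of acetate and 0.293
of hydrogen; weighted by the methane fractions this splits methane 67%
acetoclastic / 33% hydrogenotrophic, inside the 64–70% range reported for
digesters.

A command-line interface wrapping these functions ships at
`system.file("exec", "adsim.R", package = "adsim")` (subcommands
`simulate`, `compare`, `attribute`, `validate`, `fixture`), and the
default network is installed as an editable YAML config at
`system.file("extdata", "ad_network.yaml", package = "adsim")`.

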