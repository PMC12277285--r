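# hspsim

Spiking-network simulation of how transcranial direct-current stimulation
(tDCS) interacts with motor learning, under homeostatic structural
plasticity (HSP).

## The problem and the model

Human tDCS studies report inconsistent effects on motor learning: outcomes
flip with current polarity and intensity, electrode montage, and whether the
current is applied before, during, or after training. `hspsim` implements a
network model in which learning and stimulation act through one shared
mechanism, so these interactions can be simulated and dissected.

The model is an inhibition-dominated recurrent network of leaky
integrate-and-fire neurons (10000 excitatory + 2500 inhibitory at full
scale; delta synapses, weight J = 0.1 mV, inhibitory weight −gJ with g = 8;
independent Poisson background per neuron). Connections involving
inhibitory neurons are static; excitatory-to-excitatory (E-E) synapses are
grown and pruned by the HSP rule: each neuron tracks its activity with a
calcium trace Ca (mean β·τ_Ca·rate) and grows axonal boutons and dendritic
spines at

    dz/dt = ν_g (1 − Ca/ε),   z ≥ 0,

toward the setpoint ε (8 Hz). Deficits delete uniformly random synapses;
free boutons and spines pair uniformly at random into new synapses (no
autapses, multapses allowed). Grown from an empty E-E matrix, the network
settles at 8 Hz with ~9% E-E connection probability.

**Motor learning** = Poisson input (1.5 kHz, 0.1 mV; stationary mean
depolarization ν·τ_m·J = 1.50 mV) to a 10% engram for one phase.
**tDCS** = somatic polarization ΔV_m ∈ [−0.6, 0.6] mV (±2.8 mV strong
variant) to a montage-defined population — `uniform` (all E), `targeted`
(engram only), or `unfocused` (half engram + equal non-engram) — before,
during, or after learning. The memory readout is the within-engram
connectivity Γ_engram(t) = (1/n²)·Σ A_ij.

## Worked example

Grow a reduced-scale network to its structural equilibrium and apply
targeted anodal tDCS concurrently with learning:

```r
library(hspsim)

cfg <- default_config("test")          # 500 E + 125 I, accelerated profile
net <- grow_network(cfg, seed = 1)
net
#> hsp_network: 500 E + 125 I neurons, 21479 E-E synapses, t = 500 s
#>   growth: final E rate 8.00 Hz, E-E connectivity 0.0859 (converged)

sz      <- config_sizes(cfg)
montage <- build_montage("targeted", seq_len(sz$n_engram), sz$n_E, seed = 1)
plan    <- experiment_plan(cfg, timing = "during", delta_vm_mv = 0.6, seed = 1)
res     <- run_experiment(net, cfg, plan, montage)
res
#> hsp_result: montage 'targeted', timing 'during', dVm +0.60 mV, seed 1
#>   final engram connectivity: 0.0956

ctl <- run_experiment(net, cfg, experiment_plan(cfg, "none", seed = 1),
                      build_montage("none", seq_len(sz$n_engram), sz$n_E))
ctl$gamma_engram$gamma[1]   # engram block before learning
#> [1] 0.0732
final_gamma(ctl)            # after learning, no tDCS
#> [1] 0.0849
```

The grown network sits at the 8 Hz homeostatic setpoint with an E-E
connection probability near 9% (0.0859 here). Learning alone rewires the
engram: its internal connectivity rises from 0.0732 to 0.0849 while its
connectivity with the remaining excitatory neurons falls (to 0.0565 in this
run); concurrent anodal tDCS deepens the learning-induced synapse turnover
and ends with a stronger engram (0.0956) — the model's account of the
boosting effect of concurrent anodal stimulation. `run_sweep()` and `preset("fig8")`
tabulate the full montage × timing × amplitude grid; see
`vignettes/hsp-model.Rmd` for the model, its parameters, and the design of
the reduced-scale profiles.

A thin CLI covering grow/run/sweep/preset/analyze/dump-config lives at
`inst/cli/hspsim.R` (run it with `Rscript`).

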