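# kinetrax

Simulation and analysis of single-molecule kinesin motility on 2-D
microtubule networks.

Processive mitotic kinesins such as the tetrameric kinesin-12 move along
microtubules in runs interrupted by pauses and diffusive episodes, dwell at
plus ends, switch tracks at microtubule–microtubule intersections, step
against low loads in an optical trap, and bleach in discrete steps that
report their fluorophore stoichiometry. kinetrax is for biophysicists who
want to (a) generate realistic synthetic single-motor data from an explicit
stochastic state machine and (b) run the full quantitative analysis chain on
motor tracks — whether simulated or derived from kymographs — with every
threshold out in the open instead of a by-eye call.

## The model in brief

A motor attaches at a random lattice position and is plus-end directed with
probability *p₊*. Per run it draws a velocity *v* ~ TruncNormal(137.8, 60²)
nm/s on [30, 550] and a run length *L* ~ Exp with median 1.9 µm (rate =
ln 2 / median everywhere — the field reports medians). Pauses arrive at 0.30
µm⁻¹ of processive path with truncated-exponential durations (median 5.0 s,
max 20.5 s); plus-end arrival triggers a dwell (median 18.8 s) in 90% of
cases; after the run the motor lingers diffusively (D = 0.04 µm²/s) and
detaches at a rate calibrated so the median total residency equals 26.3 s.
At an intersection a moving motor passes, switches, pauses or dissociates
with configurable probabilities (equal by default); each switch starts an
independent run, so a motor's expected reach is
*median run length × (n_switches + 1)*.

The analysis half — track segmentation (processive / diffusive / paused /
end-dwelling), run metrics with median ± bootstrap SEM, four-way
intersection classification, change-point photobleaching step counting,
trap detachment-load detection, Poisson bead-binding and hyperbolic
co-sedimentation K_d fits — never sees the generator's internal state, and
the test suite validates the whole pipeline by parameter recovery.

## Worked example

```r
library(kinetrax)

params <- motility_params()                      # headline defaults
net    <- build_network(list(list(c(0, 0), c(60, 0))))  # one 60 um microtubule
ens    <- simulate_ensemble(params, net, 200, seed = 42)

an <- analyze_tracks(ens, net)                   # segment + per-track metrics
sm <- motility_summary(an, seed = 42)            # pooled statistics

print(sm$velocity)
#> gaussian fit: median 137.5 +/- 5.9 (bootstrap SEM), n = 283, max 507.2
print(sm$run_length)
#> exponential_decay fit: median 1.869 +/- 0.21 (bootstrap SEM), n = 159, max 10.85
print(sm$residency)
#> exponential_decay fit: median 24.5 +/- 2.3 (bootstrap SEM), n = 175, max 176
```

The medians printed are the recovered velocity (nm/s), run length (µm) and
lattice residency (s) of the simulated ensemble; at n = 200 tracks each sits
within a few percent of the generative values (137.8 nm/s, 1.9 µm, 26.3 s),
with the bootstrap SEM quantifying the sampling width. The same run gives
the pause statistics and directionality:

```r
sm$pause_frequency$mean   # 0.30 pauses per um of processive path
sm$pause_duration$median  # 5.5 s
sm$plus_fraction          # 0.891 plus-end-directed
```

Other entry points follow the same pattern: `classify_events()` for
intersection outcomes, `detect_steps()` for photobleaching step counts,
`simulate_trap_trace()` + `detect_detachments()` for trap loads,
`fit_poisson_binding()` / `fit_kd()` for binding statistics, and
`run_pipeline()` for a scenario-level report (`default`, `tpx2`, `trap`,
`bleach`, `binding`). A thin command-line wrapper lives at
`inst/cli/kinetrax` (subcommands `simulate`, `analyze`, `report`).

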