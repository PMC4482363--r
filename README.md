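# nfkbsim

A three-dimensional spatial agent-based simulator of IL-1 signalling to
NF-κB, built around the cytoskeletal sequestration and stimulated release
of the inhibitor IκBα.  It is aimed at systems biologists studying
inflammatory signal calibration: how the resting cell's cytoskeletal pool
of IκBα (about two thirds of the inhibitor, bound to actin/spectrin
sites) shapes NF-κB activation across stimulus levels, exchange-kinetic
regimes and TILRR co-receptor variants.

## The model in brief

Molecules are agents diffusing by Brownian motion (per-axis variance
2·D·Δt) inside a spherical cell with a nested nucleus; walls reflect, and
nuclear passage requires contact with import/export receptors.  Reactions
fire when partners meet within a calibrated interaction radius r — the
particle-level encoding of a bimolecular rate constant,
k ≈ (4/3)πr³/Δt for radii small against the mixing length, capped by the
Smoluchowski limit 4πDr.  The wired pathway is

    IL-1RI(+TILRR) → MyD88 → IRAK → TRAF → TAK → IKK ⊣ IκBα
    IL-1RI(+TILRR) → PI3K → Ras → Akt ⊣ Caspase-3

with IKK-phosphorylated IκBα degraded after a short lag, freed NF-κB
shuttling into the nucleus, and transcription sites producing IκBα
(delayed negative feedback) and IL-8 (the inflammatory readout) after a
fixed transcription time.  IκBα additionally binds immobile cytoskeletal
sites (Kon/Koff exchange at equal Ka across the fast/slow regimes);
sequestered inhibitor is never phosphorylated, and is released passively
(Koff) and actively, by dissociator agents switched on through repeated
receptor contacts (a multi-hit counter that gives a delayed, switch-like
onset).  Receptor variants differ only in adapter-recruitment radii:
wild-type TILRR = (High, High), D448 = (Low, High), R425 = (High, Low),
no TILRR = (Low, Low).

An independent well-mixed oracle (exact Gillespie simulation plus
mass-action rate equations) ships with the package and backs the engine's
kinetics on elementary networks in the test suite.

## A worked example

Relax the resting cell for two hours, then apply saturating IL-1
stimulation for one hour and look at the headline numbers:

```r
library(nfkbsim)

cfg <- default_config()            # desk scale: 0.1 x whole-cell counts
ss  <- run_steady_state(cfg, seed = 1)
ss$bound_fraction                  # 0.641  -- ~2/3 of IkBa cytoskeleton-bound
ss$drift                           # +0.024 -- stationary over the 2nd hour

sim <- run_stimulation(cfg, seed = 1, duration_min = 60,
                       warm_population = ss$population_raw)
glance(sim)
#> duration_min seed replicate ikb_total_end ikb_cyto_end bound_fraction_end
#>           60    1         1          2547         1718               0.67
#> nfkb_nuclear_peak il8_end caspase3_active_end
#>              1203     216                  65

ts <- tidy(sim)                    # per-minute observables + event log
1 - ts$ikb_cyto[ts$time == 30] / ts$ikb_cyto[1]   # 0.174 released by 30 min
1 - ts$ikb_cyto[ts$time == 60] / ts$ikb_cyto[1]   # 0.489 released by 60 min
autoplot(sim)                      # IkBa pools, nuclear NF-kB, IL-8 over time
```

The first two numbers are the resting sequestration and its
stationarity; the last two are the successive stimulated depletion of the
cytoskeletal pool — about one fifth released by 30 minutes and just under
half by 60 minutes under the fast-exchange regime with 40–50% active
release — and the one-hour summary row shows roughly half the total
inhibitor degraded with NF-κB flooding the nucleus.
Switching `binding = list(regime = "slow", release_level =
"active_90_100")` reproduces the slow-exchange signature instead: no
measurable release for about 30 minutes, then a rapid phase that empties
the pool within roughly 15 minutes.

Named scenario recipes (dissociation regimes, exchange regimes, variant
panels, TILRR expression and dose scans, sensitivity analysis) are listed
by `list_scenarios()` and run by `run_scenario()`; a thin command-line
wrapper lives at `inst/cli/nfkbsim.R`.

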