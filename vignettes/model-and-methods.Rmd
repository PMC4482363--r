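---
title: "The spatial model behind nfkbsim: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spatial model behind nfkbsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nfkbsim)
```

# The biological system

IL-1 binding to its type-1 receptor (IL-1RI), assisted by the co-receptor
TILRR, recruits the adapters MyD88 and PI3K and triggers two branches of
signalling: the canonical inflammatory cascade
(MyD88 → IRAK → TRAF → TAK → IKK) that phosphorylates the NF-κB inhibitor
IκBα and frees NF-κB to enter the nucleus and drive genes such as IL-8;
and a PI3K → Ras → Akt branch whose activity suppresses pro-apoptotic
Caspase-3.  NF-κB-driven resynthesis of IκBα closes a delayed negative
feedback: new inhibitor re-sequesters NF-κB and ends the transcription
wave, so continuous stimulation produces cyclic nuclear translocation.

The model's distinctive ingredient is a third pool of IκBα: in the
resting cell roughly two thirds of the inhibitor is sequestered on
cytoskeletal (actin/spectrin) binding sites.  This pool is invisible to
IKK — sequestered IκBα is never phosphorylated — and is released during
stimulation both passively (first-order Koff exchange) and actively,
through dedicated dissociator agents switched on downstream of the
receptor.  The released inhibitor joins the degradable cytoplasmic pool,
so the cytoskeleton acts as a stimulus-coupled reservoir that calibrates
how much inhibitor the signal must clear.

# The particle model

Every molecule (or binding site) is an agent with a type, a state, a 3-D
position and, where needed, a partner link and an event timer.  Agents
diffuse by discrete-time Brownian motion: each axis gains a Gaussian
increment of variance $2D\,\Delta t$, so the expected squared 3-D
displacement per step is $6D\,\Delta t$.  The cell is a sphere (radius 10
length units) with a concentric spherical nucleus (radius 4; the
cytoplasm:nucleus volume ratio ≈ 14.6:1 is typical of an adherent
epithelial cell).  Walls reflect: a particle that would overshoot a
boundary is mirrored back by its overshoot distance along the radial
direction.  NF-κB, IκBα and IL-8 cross the nuclear envelope only by
contacting import/export receptors fixed on the nuclear membrane; all
other proteins are confined to the cytoplasm.  Receptors, cytoskeletal
sites and transcription sites never move.  Agents have no physical size;
crowding is not modelled.

Reactions fire when matching agents meet within a rule-specific
interaction radius.  Each step, initiators are matched to their nearest
still-available partner (ties broken by the seeded random stream) and no
agent takes part in more than one reaction per step.  The radius is the
model's encoding of a macroscopic rate constant: for radii small against
the per-step diffusion length the per-pair per-step encounter probability
is the interaction ball over the domain volume, giving
$k \approx \tfrac{4}{3}\pi r^3/\Delta t$, saturating at the
diffusion-limited Smoluchowski rate $4\pi D r$ for large radii.
`calibrate_radius()` inverts the combined law; the engine's kinetics are
validated against an exact Gillespie implementation and mass-action rate
equations on elementary networks (association, catalytic activation,
reversible site binding) in the test suite.

## Time step and units

Lengths are dimensionless "µm-like" units and one simulated second is the
unit of time.  The default step is $\Delta t = 1$ s with $D = 1$
length²/s, so a protein traverses the cell interior in minutes, as a
cytoplasmic protein does.  Because motion is parameterised by a diffusion
coefficient and every rate is calibrated at the configured $\Delta t$,
halving or doubling the step does not change the macroscopic kinetics;
1 s was chosen as the coarsest step at which interaction radii stay small
against the mixing length, which also keeps a two-hour warm-up at desk
scale to seconds of wall time.  Observables are recorded once per
simulated minute.

## Populations and scale

Agent counts follow the canonical whole-cell numbers (600,000
cytoskeletal sites, 50,000 IκBα, 20,000 NF-κB, 70,000 actin:IκBα
dissociators, and so on; see `default_counts()`).  The shipped default
runs at `scale_factor = 0.1` — 60,000 sites, 5,000 IκBα, 2,000 NF-κB —
with rounding to the nearest integer and a floor of one for species that
would otherwise vanish.  All shipped interaction radii were calibrated at
this desk scale (concentrations change with scale while the geometry is
fixed, so radii are scale-specific).  The calibration procedure itself is
reproducible from `scripts/calibrate.R`.

# The resting cell

A simulation starts from the documented resting partition: two thirds of
IκBα bound to distinct cytoskeletal sites, the remainder paired 1:1 with
NF-κB until NF-κB is exhausted, everything signalling inactive.  A
two-hour unstimulated warm-up then relaxes this configured state into the
model's own steady state before any stimulation is applied.

The resting state is a dynamic equilibrium, not a frozen one.  Three slow
activities keep it honest: the NF-κB:IκBα dissociator occasionally splits
complexes; the basal IκBα phosphorylator gives the inhibitor a slow
resting turnover (half-life on the hour scale); and the small standing
population of free nuclear NF-κB that results drives a trickle of IκBα
resynthesis that balances the turnover.  Their interaction radii are the
tuning knobs of the resting steady state: they were set so that after
warm-up the cytoskeleton-bound fraction of total IκBα sits near 2/3 and
drifts by well under 5% over the second hour.  The passive
binding/unbinding exchange across the cytoskeletal pool is fast
(thousands of exchange events per hour) while the pool size stays
stationary — binding is transient, sequestration is an equilibrium.

# Cytoskeletal exchange and release

Binding parameters are Kon (encoded as the binding radius), Koff, and
their ratio Ka.  The fast regime uses a bound-state mean lifetime of
about 40 minutes; the slow regime divides both rates by 50 at identical
Ka, so the two regimes share the same resting equilibrium and differ only
kinetically.  A lifetime of a few minutes, the other candidate reading of
"transient" binding, was rejected during calibration: with realistic
rebinding it makes the printed 20%/45% net decreases of the bound pool
unreachable for any phosphorylation strength, because released inhibitor
rebinds faster than it can be cleared.

Active release is carried by the 70,000 (at scale 1) actin:IκBα
dissociator agents.  They start inactive and are switched on by repeated
contacts with active receptor complexes — a multi-hit counter (default 40
hits) that produces a Gamma-distributed, switch-like onset with mean near
30 minutes and a small coefficient of variation.  An active dissociator
that touches an occupied site releases its IκBα at the site position (no
teleporting, so rebinding competition is spatially honest).  The two
shipped release levels differ only in the dissociator's release radius,
pre-calibrated so that the bound pool falls by 40–50% (fast exchange) or
90–100% within 60 minutes of saturating stimulation.  Under the slow
regime the same machinery yields the characteristic signature: negligible
release for about half an hour, then a rapid dissociation phase that
empties most of the pool in roughly a quarter of an hour.

Master switches expose the dissociation regimes of the resting-cell
analysis: disabling release from the cytoskeleton and from NF-κB
("neither") gives a steady resting state; enabling both ("both") gives
the full model; enabling only NF-κB dissociation accumulates IκBα on the
cytoskeleton without ever reaching a steady state, since binding is then
a one-way street.

# Stimulation and the cascade

Stimulation activates a dosed fraction of the receptor complexes
(saturating dose = all of them, 3,000 at scale 1).  Receptor-adapter
recruitment is affinity-scaled: High affinity uses the base radius, Low
affinity scales it by `low_high_ratio` (default 0.32).  The TILRR variant
table maps wild type to (High, High), the D448 mutant to (Low, High), the
R425 mutant to (High, Low) and the TILRR-free complex to (Low, Low).

Every cascade step is catalytic and reversible at the agent level:
contact with an active upstream agent activates the target, and each
active kinase deactivates spontaneously (mean active lifetime five
minutes).  The per-tier gains were deliberately set so that each tier
runs far from saturation at saturating dose.  This is the design decision
that lets receptor-level affinity differences propagate: a saturated tier
flattens any upstream difference, whereas sub-saturated tiers transmit
the ratio essentially linearly down to IKK, which is what produces the
distinct degradation and IL-8 responses of the TILRR variants.  The cost
is that absolute active counts are modest (a few hundred active IKK at
scale 0.1); the TAK tier, which is ten times smaller than the others, was
given a higher occupancy to keep its relative fluctuations from
dominating downstream noise.

IKK phosphorylates free and NF-κB-bound IκBα on contact (releasing the
NF-κB partner); phosphorylated inhibitor is removed after a two-minute
lag.  Cytoskeleton-bound IκBα is never a substrate.  The engine counts
would-be violations; the counter is asserted to be exactly zero in the
test suite.

Under saturating stimulation the dominant route by which the
cytoskeletal pool shrinks is a relay: complexes are degraded, the freed
NF-κB recaptures free inhibitor, and the free pool is replenished from
the cytoskeleton through Koff.  Because the relay is driven by IKK
activity it inherits the variant dependence, which is why the bound-pool
decline, total degradation and IL-8 induction all discriminate the
receptor variants in the same direction.

# Dose response and the role of the reservoir

A stimulation dose activates an exact count of receptor complexes,
`round(dose * n)`, chosen by a seeded shuffle — a controlled stimulation
level rather than a per-receptor coin flip, which matters at the low
doses where the interesting behaviour lives.  Because the cascade tiers
are sub-saturated, pathway activity is nearly proportional to dose, and
the dose response of the model is steep: the dose scan's shipped
operating points are 1% (low), 2% (medium) and 25% (high) of the
receptor complement.

Removing cytoskeletal sequestration replaces the hidden reservoir with a
large free-inhibitor buffer, and the comparison across doses reproduces
the three qualitative regimes: at the low point the buffer absorbs every
freed NF-kB faster than the weak IKK flux can thin it while resynthesis
keeps it topped up, so the response is abrogated (the threshold property:
below it, inhibitor production outruns degradation indefinitely); at the
medium point the buffer only delays and damps the response; at the high
point the buffer is chewed through, after which the cell lacks any
reservoir-fed resequestration, and the delayed response overshoots the
sequestration-enabled pair within about two hours.  With sequestration
enabled the same comparison inverts: the hidden pool lets low doses
propagate (only the accessible third of the inhibitor must be cleared)
and the stimulated release feeds a sustained resequestration that caps
the high-dose response.  In this calibration the disabled high-dose curve
overtakes the enabled one between 90 and 120 minutes, slightly later
than the sharpest reported crossing.

# Transcription, feedback and IL-8

Transcription sites (500 at scale 1, half assigned to the IκBα gene and
half to IL-8) engage free nuclear NF-κB within a gene-specific radius,
stay busy for a fixed transcription time (20 minutes) and then release a
burst of product at the site.  New IκBα matures to the free state,
captures nuclear NF-κB (the complex is then exported — the negative
feedback) or is itself exported; IL-8 accumulates without a sink and is
the inflammatory readout.  With no free nuclear NF-κB there is no
synthesis at all: basal transcription is exactly zero, and the resting
trickle described above exists only because the resting state keeps a
small standing nuclear population.

The IκBα gene uses a generous engagement radius so that the scarce
nuclear NF-κB of the resting cell can sustain replacement synthesis,
while the IL-8 gene uses a deliberately small radius: its activity is
then approximately linear in nuclear NF-κB occupancy, which keeps the
IL-8 readout sensitive to variant- and dose-dependent differences rather
than saturating.  Burst size (16 for IκBα at scale 0.1) was calibrated so
that resynthesis restores the inhibitor over roughly one oscillation
period without cancelling the measured 60-minute degradation.

# What the synthetic conditions do and do not show

All shipped scenarios are generated by the package itself; there is no
external data.  The generator emulates the study-level experimental
design — a relaxed resting cell, saturating or graded continuous
stimulation, variant receptor complexes, enabled/disabled cytoskeletal
sequestration, three seeded replicates per condition — at one tenth of
the whole-cell molecule numbers.  It does not emulate cell-to-cell
variability, receptor trafficking, spatially structured cytoskeleton
(sites are uniform in the cytoplasm), molecular crowding, or any other
IκB isoform.  Passing tests therefore demonstrate that the mechanisms as
modelled reproduce the documented behaviours at desk scale, not that the
parameter values are the biological ones: the true rate constants behind
the published curves were never printed, and the radii here are the
package's own calibration against the printed summary numbers.

# Numerical choices and degenerate inputs

* Randomness: one xoshiro256++ stream per run, seeded from the master
  seed and the replicate index by counter-based splitting, so replicate
  *i* is bit-stable regardless of how many replicates run, and identical
  configurations with identical seeds give identical trajectories.
  Constant-hazard events (kinase deactivation, passive unbinding, basal
  Caspase-3 activation) draw geometric lifetimes at the state change —
  statistically identical to per-step coin flips, at a fraction of the
  random-number cost.
* Pair matching: initiators in index order take their nearest available
  partner on a uniform spatial hash; hashing is provably identical to the
  brute-force matcher (tested) and exact distance ties are broken by the
  seeded stream.
* Boundaries: radial mirror reflection, iterated (at most eight folds)
  for pathological jumps, then clamped to the band midpoint; membrane
  placement is exactly on-shell.
* Zero-size populations, zero radii, zero rates and koff = 0 are all
  legal and yield flat traces rather than errors; a scaled count that
  would round to zero is floored at one so every species stays present
  in tiny test runs.
* Synthesis capacity is pre-allocated from the configured burst sizes and
  duration; if a pathological configuration exhausts it the run continues
  and warns, dropping late bursts.

# Open wiring choices

Two places in the pathway topology are genuinely under-determined and are
exposed as configuration switches rather than silently fixed:

* Ras sits on the PI3K branch by default (`ras_on_branch = "pi3k"`,
  PI3K → Ras → Akt), consistent with its role in amplification of the
  anti-apoptotic branch; the alternative MyD88-side wiring is available
  as `"myd88"`.
* Free IκBα may enter the nucleus (`allow_ikb_import = TRUE`), which is
  required for nuclear re-sequestration of NF-κB; setting it to `FALSE`
  confines re-sequestration to the cytoplasm after export.

Caspase-3 is implemented with slow spontaneous (basal) activation and
contact suppression by active Akt, so higher PI3K-branch activity lowers
active Caspase-3 — the anti-apoptotic direction supported by the
simulated and cytometric endpoints, despite one Methods sentence reading
as induction.  A cold-started Caspase-3 pool rises towards its basal
level during warm-up.

# Known limitations

* Under continuous saturating stimulation the calibration reaches a
  low-inhibitor quasi-steady state with sustained nuclear NF-κB rather
  than pronounced relaxation oscillations: resynthesis (about twenty
  copies per minute at desk scale) engages strongly but stays below the
  sustained degradation flux, so total IκBα declines towards a floor
  instead of rebounding.  A burst size large enough to drive deep
  translocation cycling would cancel most of the measurable 60-minute
  net degradation, and the degradation phenotypes were prioritised.
  Cyclic behaviour is therefore not part of what the shipped tests
  demonstrate.

* The cascade's absolute active-kinase counts at desk scale are small, so
  tier-level noise is visible in single runs; shipped scenarios average
  three seeded replicates, matching the documented practice.
* The phospho-IκBα transient peaks five to fifteen minutes after
  stimulation onset — slightly later and broader than the sharpest
  reported in vitro peak, a consequence of the sub-saturated cascade
  gains chosen to preserve variant discrimination.
* The 18-hour long-run scenario is provided but not exercised by the
  default test suite; tests run the six-hour horizon.
* Interaction radii are calibrated at `scale_factor = 0.1`; runs at other
  scales keep qualitative behaviour (the sensitivity scan covers 1/10 to
  10-fold per-species changes) but the quantitative bands are guaranteed
  only at the calibrated scale.

# Problem sizes used by the shipped checks

The test-suite and acceptance runs use the default desk scale
(`scale_factor = 0.1`, about 86,000 agents), 120-minute warm-ups, 60- to
180-minute stimulated horizons, and three replicate streams per
condition; the dose scan uses 120-minute horizons with doses 5%, 25% and
100%.  These sizes were chosen as the smallest at which the documented
fractions and time constants are stable across seeds.
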