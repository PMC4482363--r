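#!/usr/bin/env Rscript
# Calibration pre-runs behind the shipped default configuration.
#
# The published system never printed its trained rate constants, so the
# interaction radii in default_config() were fixed by this procedure, in
# order, at the default desk scale (scale_factor = 0.1, dt = 1 s):
#
#   1. resting steady state  - NFkB:IkBa dissociator, basal phosphorylator,
#      association and IkBa-gene radii tuned until the 120-min warm-up ends
#      near 2/3 cytoskeleton-bound with <5% second-hour drift;
#   2. stimulated release    - kon/koff and the phosphorylation radius
#      tuned to ~20% bound-pool depletion at 30 min and ~45% at 60 min
#      (fast exchange, 40-50% active release), and the dissociator release
#      radii to the 40-50% / 90-100% bands at 60 min;
#   3. onset kinetics        - receptor-priming radius and hit count tuned
#      to a ~30-min activation lag with a small CV (slow-exchange
#      signature: rapid phase ~15 min);
#   4. regimes               - the no-dissociation regime checked to give
#      about half the full-regime degradation at 60 min;
#   5. variants              - cascade gains kept sub-saturated so the
#      D448/WT IL-8 ratio lands near 0.4 at a 3-h horizon.
#
# Running this script re-measures every target under the shipped defaults
# and prints the comparison table.  Usage:
#   Rscript scripts/calibrate.R [--seed <int>]

suppressPackageStartupMessages(library(nfkbsim))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

cfg <- default_config()
row <- function(name, value, target)
  cat(sprintf("  %-34s %8.3f   (target %s)\n", name, value, target))

cat("1) resting steady state\n")
ss <- run_steady_state(cfg, seed = seed)
row("bound fraction after warm-up", ss$bound_fraction, "~0.667 +/- 0.05")
row("second-hour drift", ss$drift, "|drift| < 0.05")

cat("2) stimulated release (fast, 40-50%)\n")
sim <- run_stimulation(cfg, seed = seed, duration_min = 60,
                       warm_population = ss$population)
ts <- sim$timeseries
row("bound depletion at 30 min",
    1 - ts$ikb_cyto[ts$time == 30] / ts$ikb_cyto[1], "~0.20")
row("bound depletion at 60 min",
    1 - ts$ikb_cyto[ts$time == 60] / ts$ikb_cyto[1], "0.40-0.50")

cat("3) slow-exchange onset (slow, 90-100%)\n")
cfg_s <- default_config(binding = list(regime = "slow",
                                       release_level = "active_90_100"))
ss_s <- run_steady_state(cfg_s, seed = seed)
ts_s <- run_stimulation(cfg_s, seed = seed, duration_min = 120,
                        warm_population = ss_s$population)$timeseries
rel <- 1 - ts_s$ikb_cyto / ts_s$ikb_cyto[1]
lag <- ts_s$time[which(rel >= 0.05)[1]]
t95 <- ts_s$time[which(rel >= 0.95 * rel[length(rel)])[1]]
row("release lag (5% of pool)", lag, "30 +/- 10 min")
row("rapid phase (5% -> 95%)", t95 - lag, "15 +/- 10 min")

cat("4) dissociation-disabled degradation deficit\n")
cfg_d <- dissociation_regime(cfg, "neither")
ss_d <- run_steady_state(cfg_d, seed = seed)
ts_d <- run_stimulation(cfg_d, seed = seed, duration_min = 60,
                        warm_population = ss_d$population)$timeseries
deg <- function(f) 1 - f$ikb_total[f$time == 60] / f$ikb_total[1]
row("degradation ratio D:E", deg(ts_d) / deg(ts), "~0.5")

cat("5) variant discrimination (3-h IL-8)\n")
il8 <- function(variant) {
  cfgv <- cfg; cfgv$pathway$variant <- variant
  f <- run_stimulation(cfgv, seed = seed, duration_min = 180)$timeseries
  f$il8[nrow(f)] - f$il8[1]
}
row("IL-8 D448 / WT", il8("d448") / il8("wt"), "~0.40")
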