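#' Unstimulated steady-state warm-up
#'
#' Simulates the resting cell (dose 0) for `duration_min` minutes and
#' reports the relaxed population together with a stationarity check on
#' the cytoskeleton-bound IkBa fraction: the relative drift over the
#' second half of the warm-up.  Regimes expected to be stationary
#' ("neither" and "both" dissociation) should show |drift| below a few
#' percent; the "NF-kB only" regime accumulates IkBa on the cytoskeleton
#' and is flagged non-stationary rather than raising an error.
#'
#' @param config an [default_config()] object.
#' @param seed master seed.
#' @param replicate replicate index.
#' @param duration_min warm-up length (default 120 minutes).
#' @return List with `sim` (the `nfkb_sim`), `population` (relaxed
#'   population tibble), `population_raw` (engine-format arrays for fast
#'   warm-start chaining), `bound_fraction` (at the end), `drift`
#'   (relative change of the bound fraction over the second half) and
#'   `stationary` (|drift| < 0.05).
#' @export
run_steady_state <- function(config, seed = NULL, replicate = 1L,
                             duration_min = 120) {
  cfg <- config
  cfg$protocol$dose <- 0
  sim <- simulate_cell(cfg, duration_min = duration_min, seed = seed,
                       replicate = replicate)
  ts <- sim$timeseries
  half <- ts[ts$time >= duration_min / 2, ]
  f0 <- if (half$ikb_total[1] > 0) half$ikb_cyto[1] / half$ikb_total[1] else 0
  f1 <- if (half$ikb_total[nrow(half)] > 0)
    half$ikb_cyto[nrow(half)] / half$ikb_total[nrow(half)] else 0
  drift <- if (f0 > 0) (f1 - f0) / f0 else 0
  last <- ts[nrow(ts), ]
  list(
    sim = sim,
    population = sim$population,
    population_raw = sim$population_raw,
    bound_fraction = ifelse(last$ikb_total > 0,
                            last$ikb_cyto / last$ikb_total, NA_real_),
    drift = drift,
    stationary = abs(drift) < 0.05
  )
}

#' Stimulated run from a relaxed steady state
#'
#' Warm-starts from [run_steady_state()] (unless a population is given)
#' and applies the configuration's stimulation protocol for
#' `duration_min` minutes.  Time in the returned series is measured from
#' stimulation onset.
#'
#' @inheritParams run_steady_state
#' @param duration_min stimulated duration (60 minutes to 18 h).
#' @param warm_population optional pre-relaxed population tibble.
#' @param warmup_min warm-up length when no population is given.
#' @return An `nfkb_sim` object.
#' @export
run_stimulation <- function(config, seed = NULL, replicate = 1L,
                            duration_min = 60, warm_population = NULL,
                            warmup_min = 120) {
  if (is.null(warm_population)) {
    ss <- run_steady_state(config, seed = seed, replicate = replicate,
                           duration_min = warmup_min)
    warm_population <- ss$population_raw
  }
  cfg <- config
  cfg$protocol$stim_start_min <- 0
  simulate_cell(cfg, duration_min = duration_min, seed = seed,
                replicate = replicate, population = warm_population)
}

#' Pointwise mean and spread of replicate runs
#'
#' @param frames list of time-series tibbles on the same grid.
#' @return Tibble with `time`, `observable`, `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(frames) {
  stopifnot(length(frames) >= 2)
  t0 <- frames[[1]]$time
  for (f in frames)
    if (nrow(f) != length(t0) || any(abs(f$time - t0) > 1e-9))
      stop("replicate frames are on different time grids", call. = FALSE)
  long <- dplyr::bind_rows(frames, .id = "replicate")
  long <- tidyr::pivot_longer(long, -c("replicate", "time"),
                              names_to = "observable")
  dplyr::summarise(
    dplyr::group_by(long, .data$time, .data$observable),
    mean = mean(.data$value), sd = sd(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
}

#' Welch's unpaired t statistic per time point
#'
#' Compares one observable between two replicate sets at each time point
#' using the unequal-variance (Welch) form of the two-sample t statistic,
#' returning the statistic and its Welch-Satterthwaite degrees of freedom.
#'
#' @param frames_a,frames_b lists of time-series tibbles on the same grid.
#' @param observable column to compare.
#' @return Tibble with `time`, `statistic`, `df`.
#' @export
welch_t <- function(frames_a, frames_b, observable) {
  va <- vapply(frames_a, function(f) f[[observable]],
               numeric(nrow(frames_a[[1]])))
  vb <- vapply(frames_b, function(f) f[[observable]],
               numeric(nrow(frames_b[[1]])))
  na <- ncol(va); nb <- ncol(vb)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sa2 <- apply(va, 1, stats::var); sb2 <- apply(vb, 1, stats::var)
  se2 <- sa2 / na + sb2 / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
  tibble::tibble(time = frames_a[[1]]$time, statistic = stat, df = df)
}

# run n replicate stimulations and return their time-series frames
.replicate_frames <- function(config, seed, replicates, duration_min,
                              warmup_min = 120) {
  purrr::map(seq_len(replicates), function(r) {
    run_stimulation(config, seed = seed, replicate = r,
                    duration_min = duration_min,
                    warmup_min = warmup_min)$timeseries
  })
}

#' TILRR variant panel
#'
#' Runs matched stimulations for a set of receptor-complex variants under
#' identical conditions and reports, per variant: MyD88 recruitment at 20
#' minutes, IL-8 activity at the horizon, peak active Akt and the active
#' Caspase-3 endpoint (mean and sd over replicates).
#'
#' @param variants character vector of variants (`"wt"`, `"d448"`,
#'   `"r425"`, `"none"`).
#' @inheritParams run_steady_state
#' @param duration_min stimulated horizon (IL-8 endpoint time).
#' @param replicates replicate count per variant.
#' @return Tibble with one row per variant and endpoint summaries.
#' @export
run_variant_panel <- function(variants = c("wt", "d448", "r425", "none"),
                              config = default_config(), seed = NULL,
                              duration_min = 360, replicates = 3) {
  purrr::map_dfr(variants, function(v) {
    cfg <- config
    cfg$pathway$variant <- v
    frames <- .replicate_frames(cfg, seed, replicates, duration_min)
    endpoint <- function(f) f[nrow(f), ]
    at20 <- function(f) f[which.min(abs(f$time - 20)), ]
    tibble::tibble(
      variant = v,
      myd88_20min_mean = mean(purrr::map_dbl(frames,
                                             ~ at20(.x)$myd88_active)),
      myd88_20min_sd = sd(purrr::map_dbl(frames, ~ at20(.x)$myd88_active)),
      il8_end_mean = mean(purrr::map_dbl(frames, ~ endpoint(.x)$il8)),
      il8_end_sd = sd(purrr::map_dbl(frames, ~ endpoint(.x)$il8)),
      akt_peak_mean = mean(purrr::map_dbl(frames, ~ max(.x$akt_active))),
      akt_peak_sd = sd(purrr::map_dbl(frames, ~ max(.x$akt_active))),
      caspase3_end_mean = mean(purrr::map_dbl(frames,
                                              ~ endpoint(.x)$caspase3_active)),
      caspase3_end_sd = sd(purrr::map_dbl(frames,
                                          ~ endpoint(.x)$caspase3_active)),
      ikb_deg_60min_mean = mean(purrr::map_dbl(frames, function(f) {
        i60 <- which.min(abs(f$time - 60))
        (f$ikb_total[1] - f$ikb_total[i60]) / f$ikb_total[1]
      })),
      replicates = replicates
    )
  })
}

#' Dose-response scan with and without cytoskeletal sequestration
#'
#' Pairs of runs per stimulation dose with cytoskeletal binding/release
#' enabled and disabled.  Derived per run: activation lag (time for
#' cumulative IL-8 to reach 5% of the enabled high-dose endpoint), IL-8
#' at 90 minutes and at the horizon.
#'
#' @param doses numeric vector of receptor-activation fractions (at least
#'   two levels).
#' @inheritParams run_variant_panel
#' @return Tibble with one row per (dose, cytoskeleton) condition.
#' @export
run_dose_response <- function(doses = c(0.01, 0.02, 0.25),
                              config = default_config(), seed = NULL,
                              duration_min = 120, replicates = 3) {
  stopifnot(length(doses) >= 2)
  grid <- tidyr::expand_grid(dose = doses, cytoskeleton = c(TRUE, FALSE))
  runs <- purrr::pmap(grid, function(dose, cytoskeleton) {
    cfg <- config
    cfg$protocol$dose <- dose
    cfg$binding$cytoskeleton_binding <- cytoskeleton
    if (!cytoskeleton) {
      cfg$binding$dissociate_from_cytoskeleton <- FALSE
      cfg$binding$release_level <- "passive_only"
    }
    .replicate_frames(cfg, seed, replicates, duration_min)
  })
  # lag reference: enabled run at the highest dose
  ref_idx <- which(grid$dose == max(doses) & grid$cytoskeleton)[1]
  ref_il8 <- mean(purrr::map_dbl(runs[[ref_idx]], ~ .x$il8[nrow(.x)]))
  lag_of <- function(f) {
    thr <- 0.05 * ref_il8
    i <- which(f$il8 >= thr)
    if (length(i) == 0) NA_real_ else f$time[i[1]]
  }
  at <- function(f, t) f$il8[which.min(abs(f$time - t))]
  out <- purrr::map2_dfr(seq_len(nrow(grid)), runs, function(i, frames) {
    tibble::tibble(
      dose = grid$dose[i], cytoskeleton = grid$cytoskeleton[i],
      il8_end_mean = mean(purrr::map_dbl(frames, ~ .x$il8[nrow(.x)])),
      il8_end_sd = sd(purrr::map_dbl(frames, ~ .x$il8[nrow(.x)])),
      il8_90min_mean = mean(purrr::map_dbl(frames, at, t = 90)),
      lag_min_mean = mean(purrr::map_dbl(frames, lag_of)),
      replicates = length(frames)
    )
  })
  out
}

#' IL-8 response across TILRR expression levels
#'
#' Scales the fraction of receptor complexes that carry TILRR by the
#' expression level (relative to endogenous: level 1 maps to the
#' configured endogenous fraction, level 0 is full knockdown) and reports
#' the IL-8 endpoint per level.
#'
#' @param levels expression ratios (>= 0).
#' @inheritParams run_variant_panel
#' @return Tibble with one row per level.
#' @export
run_tilrr_expression_scan <- function(levels = c(0, 0.3, 1, 2, 10),
                                      config = default_config(),
                                      seed = NULL, duration_min = 120,
                                      replicates = 3) {
  stopifnot(all(levels >= 0))
  purrr::map_dfr(levels, function(lv) {
    cfg <- config
    cfg$counts$tilrr_fraction <-
      min(1, lv * cfg$counts$endogenous_tilrr_fraction)
    frames <- .replicate_frames(cfg, seed, replicates, duration_min)
    tibble::tibble(
      level = lv,
      tilrr_fraction = cfg$counts$tilrr_fraction,
      il8_end_mean = mean(purrr::map_dbl(frames, ~ .x$il8[nrow(.x)])),
      il8_end_sd = sd(purrr::map_dbl(frames, ~ .x$il8[nrow(.x)])),
      replicates = replicates
    )
  })
}

#' Robustness of the cascade to agent-concentration changes
#'
#' Scales one agent type's count by each factor (1/10 to 10-fold) and
#' checks that the pathway stays qualitatively functional: stimulation
#' clearly raises the IkBa-phosphorylation event rate above its resting
#' value (cascade functional) and the inhibitor resynthesis rate rises
#' with the extra degradation (feedback functional - the negative
#' feedback loop tracks its input).
#'
#' @param types agent types to perturb.
#' @param factors scale factors within `[0.1, 10]`.
#' @inheritParams run_variant_panel
#' @return Tibble with one row per (type, factor).
#' @export
run_sensitivity_scan <- function(types = c("IKK", "IKB"),
                                 factors = c(0.1, 1, 10),
                                 config = default_config(), seed = NULL,
                                 duration_min = 120, replicates = 1) {
  stopifnot(all(factors >= 0.1), all(factors <= 10))
  purrr::map_dfr(types, function(tp) {
    purrr::map_dfr(factors, function(fc) {
      counts <- scale_counts(default_counts(), config$counts$scale_factor)
      i <- match(tp, counts$type)
      counts$count[i] <- max(1L, as.integer(round(counts$count[i] * fc)))
      geom <- cell_geometry(config$geometry$cell_radius,
                            config$geometry$nucleus_radius,
                            config$geometry$membrane_thickness)
      run_one <- function(rep) {
        set.seed((seed %||% config$run$seed) + 1000003L * (rep - 1L))
        pop <- build_initial_population(
          counts, geom, bound_fraction = config$counts$bound_fraction,
          tx_ikb_fraction = config$pathway$tx_ikb_fraction)
        ss_cfg <- config
        ss_cfg$protocol$dose <- 0
        relaxed <- simulate_cell(ss_cfg, duration_min = 120, seed = seed,
                                 replicate = rep, population = pop)
        warm <- relaxed$timeseries
        stim <- simulate_cell(config, duration_min = duration_min,
                              seed = seed, replicate = rep,
                              population = relaxed$population_raw)$timeseries
        list(warm = warm, stim = stim)
      }
      runs <- purrr::map(seq_len(replicates), run_one)
      # resting rates from the second warm-up hour
      rate_basal <- function(col) mean(purrr::map_dbl(runs, function(r) {
        w <- r$warm
        (w[[col]][nrow(w)] - w[[col]][w$time == 60]) / 60
      }))
      rate_stim <- function(col) mean(purrr::map_dbl(runs, function(r) {
        s <- r$stim
        (s[[col]][nrow(s)] - s[[col]][1]) / max(s$time)
      }))
      # the cascade's defining output is IkB phosphorylation: functional
      # when the stimulated event rate clearly exceeds the resting one
      phos_basal <- rate_basal("ev_phospho")
      phos_stim <- rate_stim("ev_phospho")
      # feedback: the loop engages - degradation drives nuclear NF-kB,
      # which drives inhibitor resynthesis well above its resting rate
      syn_basal <- rate_basal("ev_syn_ikb")
      syn_stim <- rate_stim("ev_syn_ikb")
      peak_nfkb <- mean(purrr::map_dbl(runs, ~ max(.x$stim$nfkb_nuclear)))
            tibble::tibble(
        type = tp, factor = fc,
        phospho_rate_basal = phos_basal, phospho_rate_stimulated = phos_stim,
        il8_rate_basal = rate_basal("il8"),
        il8_rate_stimulated = rate_stim("il8"),
        peak_nuclear_nfkb = peak_nfkb,
        ikb_syn_rate_basal = syn_basal,
        ikb_syn_rate_stimulated = syn_stim,
        cascade_functional = phos_stim > 1.1 * phos_basal,
        feedback_functional =
          syn_stim > syn_basal + 0.05 * (phos_stim - phos_basal)
      )
    })
  })
}

#' Named, seeded scenario definitions
#'
#' The shipped in-silico experiments, each a named configuration recipe
#' plus runner.  `run_scenario()` executes one by name and returns its
#' tidy result table (and writes per-run CSVs when `out_dir` is given).
#'
#' @return `list_scenarios()` returns the scenario names.
#' @export
list_scenarios <- function() {
  c("dissociation_regimes", "exchange_regimes", "longrun_18h", "variant_panel",
    "tilrr_expression", "dose_response", "variant_dose_grid", "sensitivity")
}

#' @rdname list_scenarios
#' @param name scenario name (see [list_scenarios()]).
#' @param config base configuration.
#' @param seed master seed.
#' @param out_dir optional directory for per-run CSV output.
#' @param replicates replicates per condition.
#' @export
run_scenario <- function(name, config = default_config(), seed = 1,
                         out_dir = NULL, replicates = 3) {
  name <- match.arg(name, list_scenarios())
  res <- switch(name,
    dissociation_regimes = {
      purrr::map_dfr(c("nfkb_only", "neither", "both"), function(rg) {
        cfg <- dissociation_regime(config, rg)
        ss <- purrr::map(seq_len(replicates), function(r)
          run_steady_state(cfg, seed = seed, replicate = r))
        tibble::tibble(
          regime = rg,
          bound_fraction = mean(purrr::map_dbl(ss, "bound_fraction")),
          drift = mean(purrr::map_dbl(ss, "drift")),
          stationary = all(purrr::map_lgl(ss, "stationary"))
        )
      })
    },
    exchange_regimes = {
      grid <- tidyr::expand_grid(
        regime = c("fast", "slow"),
        release = c("passive_only", "active_40_50", "active_90_100"))
      purrr::pmap_dfr(grid, function(regime, release) {
        cfg <- config
        cfg$binding$regime <- regime
        cfg$binding$release_level <- release
        frames <- .replicate_frames(cfg, seed, replicates, 60)
        rel <- function(f, t) {
          i <- which.min(abs(f$time - t))
          1 - f$ikb_cyto[i] / f$ikb_cyto[1]
        }
        tibble::tibble(
          regime = regime, release = release,
          bound_drop_30min = mean(purrr::map_dbl(frames, rel, t = 30)),
          bound_drop_60min = mean(purrr::map_dbl(frames, rel, t = 60))
        )
      })
    },
    longrun_18h = {
      cfg <- config
      frames <- .replicate_frames(cfg, seed, replicates, 1080)
      summarize_replicates(frames)
    },
    variant_panel = run_variant_panel(config = config, seed = seed,
                                      replicates = replicates),
    tilrr_expression = run_tilrr_expression_scan(config = config,
                                                seed = seed,
                                                replicates = replicates),
    dose_response = run_dose_response(config = config, seed = seed,
                                  replicates = replicates),
    variant_dose_grid = {
      purrr::map_dfr(c("wt", "r425", "d448"), function(v) {
        purrr::map_dfr(c(TRUE, FALSE), function(cs) {
          cfg <- config
          cfg$pathway$variant <- v
          cfg$binding$cytoskeleton_binding <- cs
          if (!cs) {
            cfg$binding$dissociate_from_cytoskeleton <- FALSE
            cfg$binding$release_level <- "passive_only"
          }
          frames <- .replicate_frames(cfg, seed, replicates, 120)
          tibble::tibble(
            variant = v, cytoskeleton = cs,
            il8_end_mean = mean(purrr::map_dbl(frames,
                                               ~ .x$il8[nrow(.x)])))
        })
      })
    },
    sensitivity = run_sensitivity_scan(config = config, seed = seed)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res, file.path(out_dir, paste0(name, "_summary.csv")))
    write_config(config, file.path(out_dir, paste0(name, "_config.yml")))
  }
  res
}

#' Count oscillation peaks in a trace
#'
#' Smooths the series with a centred running mean and counts local maxima
#' whose prominence (height above the higher of the two flanking minima)
#' exceeds `min_prominence` times the trace range.  Used to count nuclear
#' NF-kB translocation waves under continuous stimulation.
#'
#' @param x numeric series (e.g. nuclear NF-kB per minute).
#' @param smooth_window running-mean window (odd, in samples).
#' @param min_prominence minimum prominence as a fraction of the range.
#' @return Integer peak count.
#' @export
count_oscillation_peaks <- function(x, smooth_window = 9,
                                    min_prominence = 0.1) {
  k <- max(1L, as.integer(smooth_window))
  if (k %% 2 == 0) k <- k + 1L
  s <- stats::filter(x, rep(1 / k, k), sides = 2)
  s <- as.numeric(s)
  s[is.na(s)] <- x[is.na(s)]
  rng <- diff(range(s))
  if (rng <= 0) return(0L)
  n <- length(s)
  peaks <- 0L
  i <- 2L
  last_min <- s[1]
  candidate <- NA_real_
  for (i in 2:n) {
    if (!is.na(candidate)) {
      # close the candidate peak when we fall far enough below it
      if (candidate - s[i] >= min_prominence * rng) {
        peaks <- peaks + 1L
        candidate <- NA_real_
        last_min <- s[i]
      } else {
        candidate <- max(candidate, s[i])
      }
    } else {
      last_min <- min(last_min, s[i])
      if (s[i] - last_min >= min_prominence * rng) candidate <- s[i]
    }
  }
  if (!is.na(candidate)) peaks <- peaks + 1L
  peaks
}
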