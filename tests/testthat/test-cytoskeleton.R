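test_that("binding parameters keep Ka equal across exchange regimes", {
  fast <- binding_params(default_config())
  slow <- binding_params(default_config(binding = list(regime = "slow")))
  expect_equal(fast$ka, slow$ka, tolerance = 0.02)
  expect_gt(fast$kon, slow$kon)
  expect_gt(fast$koff_per_min, slow$koff_per_min)
  expect_equal(fast$koff_per_min / slow$koff_per_min, 50)
})

test_that("rule emission follows the release level and switches", {
  cfg <- default_config()
  bp <- binding_params(cfg)
  expect_identical(nrow(binding_rule(bp, cfg)), 1L)
  expect_identical(nrow(active_release_rule(bp, cfg)), 2L)
  cfg_p <- default_config(binding = list(release_level = "passive_only"))
  expect_identical(nrow(active_release_rule(binding_params(cfg_p), cfg_p)),
                   0L)
  cfg_off <- set_master_switch(cfg, dissociate_from_cytoskeleton = FALSE)
  bp_off <- binding_params(cfg_off)
  expect_identical(passive_release_rule(bp_off)$koff_per_min, 0)
  expect_identical(nrow(active_release_rule(bp_off, cfg_off)), 0L)
  # occupied sites accept no further binding: pattern targets unoccupied
  br <- binding_rule(bp, cfg)
  expect_identical(br$states_b[[1]], "ACTIVE_UNOCCUPIED")
})

test_that("unbinding times are exponential with mean 1/koff", {
  # isolated bound pairs, no rebinding (binding radius zero)
  cfg <- quiet_config()
  koff <- 0.2 # per minute
  cfg$binding$koff_per_min <- koff
  geom <- cell_geometry()
  n <- 4000
  sites <- one_species_pop(n, "CYTOSKELETON_SITE", "ACTIVE_IKB_BOUND", geom)
  ikb <- sites
  ikb$type <- "IKB"; ikb$state <- "BOUND_CYTOSKELETON"
  pop <- dplyr::bind_rows(sites, ikb)
  pop$id <- seq_len(2L * n)
  pop$partner_id <- c(n + seq_len(n), seq_len(n))
  sim <- simulate_cell(cfg, duration_min = 30, seed = 77, population = pop,
                       record_every_min = 1)
  bound <- sim$timeseries$ikb_cyto
  t_grid <- sim$timeseries$time
  # survival curve vs exp(-koff t): compare at quartile times
  surv <- bound / n
  for (tq in c(5, 10, 20))
    expect_equal(surv[t_grid == tq], exp(-koff * tq), tolerance = 0.05)
  # Kolmogorov-Smirnov on interval-censored release times against the
  # exponential law (1-minute bins)
  rel <- -diff(bound)
  cdf_emp <- cumsum(rel) / sum(rel)
  tt <- t_grid[-1]
  cdf_th <- (1 - exp(-koff * tt)) / (1 - exp(-koff * max(tt)))
  dks <- max(abs(cdf_emp - cdf_th))
  n_ev <- sum(rel)
  expect_lt(dks, 1.63 / sqrt(n_ev)) # alpha = 0.01
  # koff = 0 never releases
  cfg0 <- cfg; cfg0$binding$koff_per_min <- 0
  sim0 <- simulate_cell(cfg0, duration_min = 10, seed = 78,
                        population = pop)
  expect_true(all(sim0$timeseries$ikb_cyto == n))
})

test_that("equilibrium bound fraction matches the site-limited closed form", {
  # IkB + site <-> bound, well-mixed box; compare against the Langmuir-type
  # equilibrium of the deterministic rate equations
  cfg <- quiet_config()
  geom <- cell_geometry()
  vol <- compartment_volumes(geom)$cytoplasm
  kon <- 1.2; koff_s <- 1 / 60 # per second
  cfg$binding$kon_radius <- calibrate_radius(kon, cfg$motion$D,
                                             cfg$motion$dt, vol)
  cfg$binding$koff_per_min <- koff_s * 60
  n_i <- 400; n_s <- 1200
  set.seed(31)
  pop <- dplyr::bind_rows(
    one_species_pop(n_i, "IKB", "FREE", geom),
    one_species_pop(n_s, "CYTOSKELETON_SITE", "ACTIVE_UNOCCUPIED", geom))
  pop$id <- seq_len(nrow(pop))
  sims <- purrr::map_dbl(1:3, function(rep) {
    ts <- simulate_cell(cfg, duration_min = 30, seed = 31,
                        replicate = rep, population = pop,
                        record_every_min = 1)$timeseries
    mean(ts$ikb_cyto[ts$time >= 20])
  })
  net <- reaction_network(
    c("A", "S", "AS"),
    list(list(reactants = c(A = 1, S = 1), products = c(AS = 1),
              rate = kon),
         list(reactants = c(AS = 1), products = c(A = 1, S = 1),
              rate = koff_s)),
    c(A = n_i, S = n_s), volume = vol)
  eq <- integrate_deterministic(net, c(0, 5000))$AS[2]
  expect_equal(mean(sims) / n_i, eq / n_i, tolerance = 0.05)
})

test_that("the no-dissociation regime only accumulates bound IkBa", {
  cfg <- dissociation_regime(
    default_config(counts = list(scale_factor = 0.02)), "nfkb_only")
  ss <- run_steady_state(cfg, seed = 9, duration_min = 60)
  ts <- ss$sim$timeseries
  # monotone (smoothed) growth, no release events of any kind
  expect_identical(ts$ev_passive_release[nrow(ts)], 0)
  expect_identical(ts$ev_active_release[nrow(ts)], 0)
  expect_gt(ts$ikb_cyto[nrow(ts)], ts$ikb_cyto[1])
  sm <- stats::filter(ts$ikb_cyto, rep(1 / 5, 5), sides = 2)
  d <- diff(sm[!is.na(sm)])
  expect_gt(mean(d >= 0), 0.9)
})
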