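test_that("identical config and seed give a bit-identical trajectory", {
  cfg <- tiny_config(run = list(duration_min = 5))
  a <- simulate_cell(cfg, seed = 42)
  b <- simulate_cell(cfg, seed = 42)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$population, b$population)
  # a different replicate stream diverges
  c2 <- simulate_cell(cfg, seed = 42, replicate = 2L)
  expect_false(identical(a$timeseries, c2$timeseries))
})

test_that("engine Brownian motion has MSD slope 6D", {
  # huge empty cell, no reactions: free diffusion of one species
  cfg <- quiet_config(geometry = list(cell_radius = 200,
                                      nucleus_radius = 1e-3))
  geom <- cell_geometry(200, 1e-3)
  n <- 3000
  pop <- one_species_pop(n, "IL8", "IL8_ACTIVE", geom)
  # start everyone mid-shell so walls are never reached within the run
  set.seed(1)
  pop$x <- 100 + rnorm(n, 0, 0.1); pop$y <- 0; pop$z <- 0
  t_min <- 1
  sim <- simulate_cell(cfg, duration_min = t_min, seed = 9,
                       population = pop, record_every_min = t_min)
  fin <- sim$population
  d2 <- (fin$x - pop$x)^2 + (fin$y - pop$y)^2 + (fin$z - pop$z)^2
  D <- cfg$motion$D
  expect_equal(mean(d2), 6 * D * t_min * 60, tolerance = 0.05)
})

test_that("mobile agents never escape their compartment", {
  cfg <- tiny_config(run = list(duration_min = 10))
  sim <- simulate_cell(cfg, seed = 3)
  fin <- sim$population
  r <- sqrt(fin$x^2 + fin$y^2 + fin$z^2)
  expect_true(all(r <= 10 + 1e-9))
  # cytoplasm-only types stay out of the nucleus
  cyto_only <- fin$type %in% c("MYD88", "IRAK", "TRAF", "TAK", "RAS",
                               "PI3K", "AKT", "IKK",
                               "ACTIN_IKB_DISSOCIATOR",
                               "IKB_PHOSPHORYLATOR",
                               "NFKB_IKB_DISSOCIATOR")
  expect_true(all(r[cyto_only] >= 4 - 1e-9))
})

test_that("membrane agents are immobile", {
  cfg <- tiny_config(run = list(duration_min = 5))
  set.seed(cfg$run$seed)
  pop <- build_population_from_config(cfg)
  sim <- simulate_cell(cfg, seed = 1, population = pop)
  fixed <- c("IL1RI_TILRR", "IL1RI", "NUCLEAR_IMPORT", "NUCLEAR_EXPORT",
             "CYTOSKELETON_SITE", "TRANSCRIPTION_SITE")
  a <- pop[pop$type %in% fixed, c("type", "x", "y", "z")]
  b <- sim$population[sim$population$type %in% fixed,
                      c("type", "x", "y", "z")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("NFkB is conserved and partitions sum to the total", {
  cfg <- tiny_config(run = list(duration_min = 20))
  sim <- simulate_cell(cfg, seed = 8)
  ts <- sim$timeseries
  n0 <- ts$nfkb_free[1] + ts$nfkb_complex[1]
  expect_true(all(ts$nfkb_free + ts$nfkb_complex == n0))
  expect_identical(sum(sim$population$type == "NFKB"), as.integer(n0))
})

test_that("states and pair links stay consistent over a run", {
  cfg <- tiny_config(run = list(duration_min = 20))
  sim <- simulate_cell(cfg, seed = 13)
  pop <- sim$population
  # state legality for every live agent
  states <- agent_states()
  ok <- vapply(seq_len(nrow(pop)),
               function(i) pop$state[i] %in% states[[pop$type[i]]] ||
                 (pop$type[i] == "IKB" &&
                    pop$state[i] == "PHOSPHO_PENDING_DEGRADATION"),
               logical(1))
  expect_true(all(ok))
  # partner symmetry and co-location
  linked <- pop[!is.na(pop$partner_id), ]
  j <- match(linked$partner_id, pop$id)
  expect_identical(pop$partner_id[j], linked$id)
  expect_equal(linked$x, pop$x[j])
  expect_equal(linked$y, pop$y[j])
  # cytoskeleton sites conserved; occupied + unoccupied = total
  sites <- pop[pop$type == "CYTOSKELETON_SITE", ]
  counts0 <- scale_counts(default_counts(), 0.01)
  expect_identical(nrow(sites),
                   counts0$count[counts0$type == "CYTOSKELETON_SITE"])
  expect_identical(sum(sites$state %in% c("ACTIVE_UNOCCUPIED",
                                          "ACTIVE_IKB_BOUND")),
                   nrow(sites))
})

test_that("cytoskeleton-bound IkBa is never phosphorylated", {
  cfg <- default_config(counts = list(scale_factor = 0.05),
                        run = list(duration_min = 30))
  sim <- simulate_cell(cfg, seed = 2)
  expect_identical(
    sim$timeseries$ev_phospho_cytobound[nrow(sim$timeseries)], 0)
})

test_that("release accounting balances the event log", {
  cfg <- default_config(counts = list(scale_factor = 0.05),
                        run = list(duration_min = 30))
  sim <- simulate_cell(cfg, seed = 6)
  ts <- sim$timeseries
  last <- ts[nrow(ts), ]
  b0 <- ts$ikb_cyto[1]
  # initial bound - bound(t) = passive + active releases - rebindings
  expect_identical(
    b0 - last$ikb_cyto,
    last$ev_passive_release + last$ev_active_release - last$ev_rebind)
})

test_that("zero-agent degenerate populations run flat without crashing", {
  cfg <- tiny_config(run = list(duration_min = 3))
  geom <- cell_geometry()
  pop <- one_species_pop(1, "IL8", "IL8_ACTIVE", geom)
  sim <- simulate_cell(quiet_config(), duration_min = 3, seed = 1,
                       population = pop)
  expect_true(all(sim$timeseries$il8 == 1))
  expect_true(all(sim$timeseries$ikb_total == 0))
})
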