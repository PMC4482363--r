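test_that("deterministic integrator reproduces closed forms", {
  # A -> B first-order decay
  net <- reaction_network(
    c("A", "B"),
    list(list(reactants = c(A = 1), products = c(B = 1), rate = 1)),
    c(A = 100), volume = 1)
  tr <- integrate_deterministic(net, seq(0, 1, by = 0.25))
  expect_equal(tr$A[tr$time == 1], 100 * exp(-1), tolerance = 1e-6)
  # conservation along the trajectory
  expect_equal(tr$A + tr$B, rep(100, nrow(tr)), tolerance = 1e-6)
  # A + B <-> AB detailed balance: AB / (A B / V) = kon / koff
  kon <- 0.2; koff <- 0.05; vol <- 50
  net2 <- reaction_network(
    c("A", "B", "AB"),
    list(list(reactants = c(A = 1, B = 1), products = c(AB = 1),
              rate = kon),
         list(reactants = c(AB = 1), products = c(A = 1, B = 1),
              rate = koff)),
    c(A = 200, B = 150), volume = vol)
  tr2 <- integrate_deterministic(net2, seq(0, 2000, by = 100))
  last <- tr2[nrow(tr2), ]
  expect_equal(last$AB / (last$A * last$B / vol), kon / koff,
               tolerance = 1e-4)
})

test_that("SSA agrees with closed form and the rate equations", {
  net <- reaction_network(
    c("A", "B"),
    list(list(reactants = c(A = 1), products = c(B = 1), rate = 0.5)),
    c(A = 200), volume = 1)
  # zero-rate network produces no events
  net0 <- reaction_network(
    c("A", "B"),
    list(list(reactants = c(A = 1), products = c(B = 1), rate = 0)),
    c(A = 200), volume = 1)
  still <- simulate_ssa(net0, t_end = 5)
  expect_true(all(still$A == 200))
  set.seed(4)
  runs <- purrr::map_dbl(1:500, function(i)
    simulate_ssa(net, t_end = 1, record_every = 1)$A[2])
  expected <- 200 * exp(-0.5)
  sem <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - expected), 3 * sem + 1e-9)
  # binding network: SSA mean near deterministic at moderate counts
  kon <- 0.3; koff <- 0.1; vol <- 30
  net2 <- reaction_network(
    c("A", "S", "AS"),
    list(list(reactants = c(A = 1, S = 1), products = c(AS = 1),
              rate = kon),
         list(reactants = c(AS = 1), products = c(A = 1, S = 1),
              rate = koff)),
    c(A = 300, S = 300), volume = vol)
  det <- integrate_deterministic(net2, c(0, 50))$AS[2]
  set.seed(14)
  ssa_mean <- mean(purrr::map_dbl(1:30, function(i)
    simulate_ssa(net2, t_end = 50, record_every = 50)$AS[2]))
  expect_equal(ssa_mean, det, tolerance = 0.02)
})

test_that("engine matches the oracle on elementary reaction classes", {
  # catalytic activation
  act <- compare_abm_to_oracle("activation", k = 0.3, n_a = 200,
                               n_b = 400, duration_min = 4,
                               replicates = 3, seed = 11)
  expect_true(act$pass)
  # association
  asc <- compare_abm_to_oracle("association", k = 0.4, n_a = 250,
                               n_b = 250, duration_min = 4,
                               replicates = 3, seed = 12)
  expect_true(asc$pass)
  # reversible site binding reaches the mass-action equilibrium
  bnd <- compare_abm_to_oracle("binding", k = 0.4, koff = 1 / 120,
                               n_a = 300, n_b = 600, duration_min = 12,
                               replicates = 3, seed = 13)
  expect_true(bnd$pass)
})

test_that("a mis-calibrated radius is detected (negative control)", {
  cfg <- quiet_config()
  geom <- cell_geometry()
  vol <- compartment_volumes(geom)$cytoplasm
  k <- 0.4
  r_wrong <- 2^(1 / 3) * calibrate_radius(k, cfg$motion$D, cfg$motion$dt,
                                          vol) # doubles the rate
  cfg$pathway$r_assoc <- r_wrong
  set.seed(15)
  pop <- dplyr::bind_rows(
    one_species_pop(250, "NFKB", "NFKB_FREE", geom),
    one_species_pop(250, "IKB", "FREE", geom))
  pop$id <- seq_len(nrow(pop))
  sims <- purrr::map(1:3, function(rep)
    simulate_cell(cfg, duration_min = 4, seed = 15, replicate = rep,
                  population = pop,
                  record_every_min = 0.2)$timeseries$nfkb_complex)
  abm <- Reduce(`+`, sims) / 3
  net <- reaction_network(
    c("A", "B", "C"),
    list(list(reactants = c(A = 1, B = 1), products = c(C = 1), rate = k)),
    c(A = 250, B = 250), volume = vol)
  ref <- integrate_deterministic(
    net, seq(0, 240, length.out = length(abm)))$C
  disc <- max(abs(abm - ref)) / max(ref)
  expect_gt(disc, 0.1)
})
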