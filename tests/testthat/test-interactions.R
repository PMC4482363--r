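test_that("pair finding respects the radius", {
  pop <- tibble::tibble(
    id = 1:2, type = c("IKK", "IKB"), state = c("ACTIVE", "FREE"),
    x = c(0, 0.9), y = 0, z = 0, partner_id = NA_integer_, timer = 0,
    hits = 0L)
  rule <- reaction_rule("phospho", "IKK", "ACTIVE", "IKB", "FREE",
                        radius = 1)
  expect_identical(nrow(find_pairs(pop, rule)), 1L)
  pop$x[2] <- 1.1
  expect_identical(nrow(find_pairs(pop, rule)), 0L)
})

test_that("hashed matcher equals the brute-force nearest-available matcher", {
  set.seed(99)
  geom <- cell_geometry()
  for (rep in 1:5) {
    pop <- dplyr::bind_rows(
      one_species_pop(25, "IKK", "ACTIVE", geom),
      one_species_pop(25, "IKB", "FREE", geom))
    pop$id <- seq_len(nrow(pop))
    rule <- reaction_rule("phospho", "IKK", "ACTIVE", "IKB", "FREE",
                          radius = 1.5)
    fast <- find_pairs(pop, rule, seed = rep)
    slow <- .find_pairs_bruteforce(pop, rule)
    expect_equal(fast, slow)
    # one pair per agent
    expect_identical(anyDuplicated(fast$id_a), 0L)
    expect_identical(anyDuplicated(fast$id_b), 0L)
  }
})

test_that("reactions fire with the rule's contact probability", {
  n <- 10000L
  pop <- tibble::tibble(
    id = seq_len(2 * n),
    type = rep(c("IKK", "IKB"), each = n),
    state = rep(c("ACTIVE", "FREE"), each = n),
    x = c(seq_len(n) * 10, seq_len(n) * 10 + 0.1),
    y = 0, z = 0, partner_id = NA_integer_, timer = 0, hits = 0L)
  rule1 <- reaction_rule("p", "IKK", "ACTIVE", "IKB", "FREE", radius = 1,
                         prob = 1, event_b = "phosphorylate")
  pairs <- tibble::tibble(id_a = seq_len(n), id_b = n + seq_len(n),
                          distance = 0.1)
  out <- apply_reactions(pop, pairs, rule1)
  expect_identical(nrow(out$applied), n)
  expect_true(all(out$population$state[n + seq_len(n)] ==
                    "PHOSPHO_PENDING_DEGRADATION"))
  rule0 <- rule1; rule0$prob <- 0
  expect_identical(nrow(apply_reactions(pop, pairs, rule0)$applied), 0L)
  rule3 <- rule1; rule3$prob <- 0.3
  set.seed(1)
  frac <- nrow(apply_reactions(pop, pairs, rule3)$applied) / n
  expect_equal(frac, 0.3, tolerance = 0.07)
})

test_that("radius calibration inverts the rate law and is monotone", {
  D <- 1; dt <- 1; vol <- 4000
  expect_identical(calibrate_radius(0, D, dt, vol), 0)
  ks <- c(1e-4, 1e-3, 1e-2, 0.1, 1)
  rs <- vapply(ks, calibrate_radius, numeric(1), D = D, dt = dt,
               volume = vol)
  expect_true(all(diff(rs) > 0))
  # round trip
  for (i in seq_along(ks))
    expect_equal(radius_to_rate(rs[i], D, dt), ks[i], tolerance = 1e-8)
  # small radii follow the geometric law
  r <- calibrate_radius(1e-4, D, dt, vol)
  expect_equal(4 / 3 * pi * r^3 / dt, 1e-4, tolerance = 0.01)
  # unrepresentable rates error
  expect_error(calibrate_radius(1e6, D, dt, vol, max_radius = 2),
               "not representable")
})

test_that("calibrated kinetics match a stochastic simulation oracle", {
  # A + B -> C decay compared against the well-mixed SSA on the half-life
  k <- 0.4
  cfg <- quiet_config()
  geom <- cell_geometry()
  vol <- compartment_volumes(geom)$cytoplasm
  r <- calibrate_radius(k, cfg$motion$D, cfg$motion$dt, vol)
  cfg$pathway$r_assoc <- r
  set.seed(21)
  pop <- dplyr::bind_rows(
    one_species_pop(250, "NFKB", "NFKB_FREE", geom),
    one_species_pop(250, "IKB", "FREE", geom))
  pop$id <- seq_len(nrow(pop))
  abm <- purrr::map(1:4, function(rep) {
    simulate_cell(cfg, duration_min = 4, seed = 21, replicate = rep,
                  population = pop,
                  record_every_min = 0.2)$timeseries$nfkb_complex
  })
  abm_mean <- Reduce(`+`, abm) / length(abm)
  net <- reaction_network(
    c("A", "B", "C"),
    list(list(reactants = c(A = 1, B = 1), products = c(C = 1), rate = k)),
    c(A = 250, B = 250), volume = vol)
  set.seed(31)
  ssa <- purrr::map(1:20, function(i)
    simulate_ssa(net, t_end = 240, record_every = 12)$C)
  ssa_mean <- Reduce(`+`, ssa) / length(ssa)
  # half-life: first time C reaches half of its final SSA value
  t_grid <- seq(0, 240, by = 12)
  half <- 0.5 * ssa_mean[length(ssa_mean)]
  t_abm <- approx(abm_mean, t_grid, xout = half)$y
  t_ssa <- approx(ssa_mean, t_grid, xout = half)$y
  expect_equal(t_abm, t_ssa, tolerance = 0.1)
})

test_that("affinity scaling orders effective rates Low < High", {
  expect_identical(affinity_to_radius_scaling(0.3, "High", 0.5), 0.3)
  expect_identical(affinity_to_radius_scaling(0.3, "Low", 0.5), 0.15)
  # two-condition simulation: High-affinity recruitment runs faster
  cfg <- quiet_config()
  geom <- cell_geometry()
  run_with_radius <- function(r) {
    cfg$pathway$r_cascade <- r
    set.seed(77)
    pop <- dplyr::bind_rows(
      one_species_pop(150, "TAK", "ACTIVE", geom),
      one_species_pop(300, "IKK", "INACTIVE", geom))
    pop$id <- seq_len(nrow(pop))
    # r_cascade drives MyD88->IRAK; use the TAK->IKK channel instead
    cfg$pathway$r_cascade <- 0
    cfg$pathway$r_ikk_activation <- r
    simulate_cell(cfg, duration_min = 3, seed = 5, population = pop,
                  record_every_min = 1)$timeseries$ikk_active
  }
  high <- run_with_radius(0.4)
  low <- run_with_radius(affinity_to_radius_scaling(0.4, "Low", 0.5))
  expect_gt(high[length(high)], low[length(low)])
})
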