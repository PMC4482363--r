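#' Define a well-mixed reaction network
#'
#' A small mass-action network used as independent ground truth for the
#' particle engine's kinetics.  Rate constants follow the deterministic
#' convention: unimolecular rates in 1/time, bimolecular rates in
#' volume/time (per-pair stochastic propensity `k / volume`).
#'
#' @param species character vector of species names.
#' @param reactions list of reactions; each a list with `reactants` and
#'   `products` (named integer vectors of stoichiometries) and `rate`.
#' @param init named integer vector of initial copy numbers.
#' @param volume domain volume.
#' @return A `reaction_network` object.
#' @examples
#' net <- reaction_network(
#'   c("A", "B"), list(list(reactants = c(A = 1), products = c(B = 1),
#'   rate = 1)), c(A = 100, B = 0), volume = 1)
#' @export
reaction_network <- function(species, reactions, init, volume = 1) {
  stopifnot(length(species) > 0, all(names(init) %in% species))
  init_full <- setNames(rep(0, length(species)), species)
  init_full[names(init)] <- init
  for (rx in reactions) {
    stopifnot(all(names(rx$reactants) %in% species),
              all(names(rx$products) %in% species), rx$rate >= 0,
              sum(rx$reactants) <= 2)
  }
  structure(list(species = species, reactions = reactions,
                 init = init_full, volume = volume),
            class = "reaction_network")
}

# propensity of reaction rx at counts n (stochastic mass action)
.propensity <- function(rx, n, volume) {
  r <- rx$reactants
  if (sum(r) == 0) return(rx$rate)
  if (sum(r) == 1) return(rx$rate * n[[names(r)]])
  if (length(r) == 2) {
    nm <- names(r)
    return(rx$rate / volume * n[[nm[1]]] * n[[nm[2]]])
  }
  # homodimerisation 2A -> ...
  nm <- names(r)
  rx$rate / volume * n[[nm]] * (n[[nm]] - 1) / 2
}

.stoich_change <- function(rx, species) {
  ch <- setNames(rep(0, length(species)), species)
  for (s in names(rx$reactants)) ch[s] <- ch[s] - rx$reactants[[s]]
  for (s in names(rx$products)) ch[s] <- ch[s] + rx$products[[s]]
  ch
}

#' Deterministic mass-action solution
#'
#' Integrates the network's rate equations (on mean copy numbers) over a
#' time grid with `deSolve`.
#'
#' @param net a [reaction_network()].
#' @param t_grid numeric vector of output times (must include the start).
#' @return Tibble with `time` and one column per species.
#' @export
integrate_deterministic <- function(net, t_grid) {
  changes <- lapply(net$reactions, .stoich_change, species = net$species)
  deriv <- function(t, y, parms) {
    dy <- setNames(rep(0, length(y)), net$species)
    for (i in seq_along(net$reactions)) {
      a <- .propensity(net$reactions[[i]], as.list(y), net$volume)
      dy <- dy + a * changes[[i]]
    }
    list(dy)
  }
  out <- deSolve::ode(y = net$init, times = t_grid, func = deriv,
                      parms = NULL, method = "lsoda")
  if (attr(out, "istate")[1] < 0)
    stop("stiff integration failure: ",
         paste(attr(out, "istate"), collapse = " "), call. = FALSE)
  tibble::as_tibble(as.data.frame(out))
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Generates a statistically exact sample path of the chemical master
#' equation for the network, recorded on a regular grid.
#'
#' @param net a [reaction_network()].
#' @param t_end end time.
#' @param record_every grid spacing for the returned trajectory.
#' @return Tibble with `time` and one column per species (counts at the
#'   grid times; piecewise-constant interpolation of the jump process).
#' @export
simulate_ssa <- function(net, t_end, record_every = t_end / 50) {
  n <- net$init
  t <- 0
  grid <- seq(0, t_end, by = record_every)
  out <- matrix(NA_real_, nrow = length(grid), ncol = length(n))
  gi <- 1
  changes <- lapply(net$reactions, .stoich_change, species = net$species)
  repeat {
    a <- vapply(net$reactions, .propensity, numeric(1), n = as.list(n),
                volume = net$volume)
    a0 <- sum(a)
    t_next <- if (a0 <= 0) Inf else t + stats::rexp(1, a0)
    while (gi <= length(grid) && grid[gi] < min(t_next, t_end) + 1e-12) {
      out[gi, ] <- n
      gi <- gi + 1
    }
    if (t_next > t_end || gi > length(grid)) break
    t <- t_next
    j <- sample.int(length(a), 1, prob = a)
    n <- n + changes[[j]]
  }
  while (gi <= length(grid)) { out[gi, ] <- n; gi <- gi + 1 }
  colnames(out) <- net$species
  dplyr::bind_cols(tibble::tibble(time = grid),
                   tibble::as_tibble(as.data.frame(out)))
}

#' A configuration with every reaction channel switched off
#'
#' Starting point for engine validation: all interaction radii zero, no
#' passive exchange, no deactivation, no stimulation.  Individual channels
#' are then re-enabled with calibrated radii to compare the engine against
#' the well-mixed references on elementary networks.
#'
#' @param D,dt motion constants.
#' @param ... further overrides passed to [default_config()].
#' @return An `nfkb_config`.
#' @export
bare_config <- function(D = 4, dt = 1.0, ...) {
  zero_pathway <- list(
    r_myd88 = 1e-9, r_pi3k = 1e-9, r_cascade = 0, r_tak_activation = 0, r_ikk_activation = 0,
    r_ras = 0, r_akt = 0,
    r_caspase = 0, r_phospho = 0, r_basal_phospho = 0, r_assoc = 0,
    r_nfkb_dissociator = 0, r_import = 0, r_export = 0, r_tx_ikb = 0,
    r_tx_il8 = 0, k_deact_per_min = 0, k_caspase_basal_per_min = 0
  )
  default_config(
    motion = list(D = D, dt = dt),
    counts = list(scale_factor = 0.001),
    binding = list(kon_radius = 1e-9, koff_per_min = 0,
                   release_level = "passive_only",
                   priming_radius = 0, k_deact_adiss_per_min = 0),
    pathway = zero_pathway,
    protocol = list(dose = 0),
    ...
  )
}

# a population holding only the requested (type, state) groups, uniformly
# in the cytoplasm
.well_mixed_population <- function(groups, geometry) {
  rows <- purrr::map(groups, function(g) {
    pos <- place_in_compartment(g$n, "CYTOPLASM", geometry)
    tibble::tibble(type = g$type, state = g$state, x = pos$x, y = pos$y,
                   z = pos$z, partner_id = NA_integer_, timer = 0,
                   hits = 0L)
  })
  pop <- dplyr::bind_rows(rows)
  pop$id <- seq_len(nrow(pop))
  dplyr::relocate(pop, "id")
}

#' Compare the particle engine against the well-mixed references
#'
#' Runs one of the elementary sub-networks on both the particle engine
#' (radius calibrated from the target rate with [calibrate_radius()]) and
#' the deterministic reference, and reports the discrepancy of the mean
#' trajectory over replicates.  Valid in the well-mixed regime: the
#' calibrated radius must stay well below the per-step diffusion length,
#' otherwise a regime warning is attached.
#'
#' @param setup `"association"` (A + B -> C), `"activation"` (catalytic
#'   A* + B -> A* + B*) or `"binding"` (site-limited A + S <-> AS
#'   equilibrium).
#' @param k bimolecular rate constant (volume/time).
#' @param koff unbinding rate (1/time), used by `"binding"`.
#' @param n_a,n_b initial copy numbers.
#' @param duration_min simulated minutes.
#' @param replicates engine replicates averaged before comparison.
#' @param seed master seed.
#' @return List with the engine and reference trajectories, the relative
#'   discrepancy summary and `pass` at the given `tolerance`.
#' @param tolerance maximum acceptable relative discrepancy.
#' @export
compare_abm_to_oracle <- function(setup = c("association", "activation",
                                            "binding"),
                                  k = 0.5, koff = 0.01, n_a = 300,
                                  n_b = 300, duration_min = 5,
                                  replicates = 4, seed = 1,
                                  tolerance = 0.1) {
  setup <- match.arg(setup)
  cfg <- bare_config()
  geom <- cell_geometry(cfg$geometry$cell_radius,
                        cfg$geometry$nucleus_radius,
                        cfg$geometry$membrane_thickness)
  vol <- compartment_volumes(geom)$cytoplasm
  D <- cfg$motion$D; dt <- cfg$motion$dt
  r <- calibrate_radius(k, D, dt, vol)
  mix_len <- sqrt(2 * D * dt)
  regime_ok <- r < 0.5 * mix_len
  if (!regime_ok)
    warning("calibrated radius ", signif(r, 3),
            " is not small against the mixing length ", signif(mix_len, 3),
            "; well-mixed comparison is unreliable", call. = FALSE)

  if (setup == "association") {
    cfg$pathway$r_assoc <- r
    pop <- .well_mixed_population(list(
      list(type = "NFKB", state = "NFKB_FREE", n = n_a),
      list(type = "IKB", state = "FREE", n = n_b)), geom)
    net <- reaction_network(
      c("A", "B", "C"),
      list(list(reactants = c(A = 1, B = 1), products = c(C = 1),
                rate = k)),
      c(A = n_a, B = n_b), volume = vol)
    col <- "nfkb_complex"; ref_col <- "C"
  } else if (setup == "activation") {
    cfg$pathway$r_ikk_activation <- r
    pop <- .well_mixed_population(list(
      list(type = "TAK", state = "ACTIVE", n = n_a),
      list(type = "IKK", state = "INACTIVE", n = n_b)), geom)
    net <- reaction_network(
      c("A", "B", "Bstar"),
      list(list(reactants = c(A = 1, B = 1),
                products = c(A = 1, Bstar = 1), rate = k)),
      c(A = n_a, B = n_b), volume = vol)
    col <- "ikk_active"; ref_col <- "Bstar"
  } else {
    cfg$binding$kon_radius <- r
    cfg$binding$koff_per_min <- koff * 60
    pop <- .well_mixed_population(list(
      list(type = "IKB", state = "FREE", n = n_a),
      list(type = "CYTOSKELETON_SITE", state = "ACTIVE_UNOCCUPIED",
           n = n_b)), geom)
    net <- reaction_network(
      c("A", "S", "AS"),
      list(list(reactants = c(A = 1, S = 1), products = c(AS = 1),
                rate = k),
           list(reactants = c(AS = 1), products = c(A = 1, S = 1),
                rate = koff)),
      c(A = n_a, S = n_b), volume = vol)
    col <- "ikb_cyto"; ref_col <- "AS"
  }

  sims <- purrr::map(seq_len(replicates), function(rep) {
    s <- simulate_cell(cfg, duration_min = duration_min, seed = seed,
                       replicate = rep, population = pop,
                       record_every_min = duration_min / 20)
    s$timeseries[[col]]
  })
  abm_mean <- Reduce(`+`, sims) / replicates
  t_grid <- seq(0, duration_min * 60, length.out = length(abm_mean))
  ref <- integrate_deterministic(net, t_grid)[[ref_col]]

  scale0 <- max(abs(ref), 1)
  disc <- max(abs(abm_mean - ref)) / scale0
  list(setup = setup, radius = r, regime_ok = regime_ok,
       discrepancy = disc, tolerance = tolerance,
       pass = regime_ok && disc <= tolerance,
       abm = tibble::tibble(time = t_grid, value = abm_mean),
       reference = tibble::tibble(time = t_grid, value = ref))
}
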