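.record_cols <- c(
  "time", "ikb_total", "ikb_cyto", "ikb_phospho", "ikb_free", "ikb_nfkb",
  "ikb_nuclear", "nfkb_free", "nfkb_nuclear", "nfkb_complex", "il8",
  "caspase3_active", "receptors_active", "myd88_active", "irak_active",
  "ikk_active", "akt_active", "dissociator_active",
  "ev_phospho", "ev_degraded", "ev_passive_release", "ev_active_release",
  "ev_rebind", "ev_import", "ev_export", "ev_transcription", "ev_syn_ikb",
  "ev_syn_il8", "ev_nfkb_dissoc", "ev_assoc", "ev_phospho_cytobound"
)

# population tibble -> flat arrays for the engine, with pre-typed spare
# slots appended for synthesis.  A raw engine array list (carried inside
# an nfkb_sim for warm-start chaining) passes straight through.
.pop_to_arrays <- function(population, spare_ikb = 0L, spare_il8 = 0L) {
  if (is.list(population) && !is.data.frame(population) &&
      !is.null(population$type) && is.integer(population$type)) {
    n_extra <- spare_ikb + spare_il8
    if (n_extra == 0L) return(population)
    pad_i <- function(v, fill) c(v, rep(fill, n_extra))
    spare_types <- c(rep(.type_code("IKB"), spare_ikb),
                     rep(.type_code("IL8"), spare_il8))
    return(list(
      type = c(population$type, spare_types),
      state = pad_i(population$state, .state_code("DEAD")),
      partner = pad_i(population$partner, -1L),
      hits = pad_i(population$hits, 0L),
      alive = pad_i(population$alive, 0L),
      x = pad_i(population$x, 0), y = pad_i(population$y, 0),
      z = pad_i(population$z, 0),
      timer = pad_i(population$timer, 0)
    ))
  }
  n <- nrow(population)
  partner_idx <- match(population$partner_id, population$id)
  spare <- function(type, k) {
    if (k == 0) return(NULL)
    list(type = rep(.type_code(type), k),
         state = rep(.state_code("DEAD"), k))
  }
  si <- spare("IKB", spare_ikb)
  s8 <- spare("IL8", spare_il8)
  list(
    type = c(.type_code(population$type), si$type, s8$type),
    state = c(.state_code(population$state), si$state, s8$state),
    partner = c(ifelse(is.na(partner_idx), -1L, partner_idx),
                rep(-1L, spare_ikb + spare_il8)),
    hits = c(as.integer(population$hits %||% rep(0L, n)),
             rep(0L, spare_ikb + spare_il8)),
    alive = c(rep(1L, n), rep(0L, spare_ikb + spare_il8)),
    x = c(population$x, rep(0, spare_ikb + spare_il8)),
    y = c(population$y, rep(0, spare_ikb + spare_il8)),
    z = c(population$z, rep(0, spare_ikb + spare_il8)),
    timer = c(as.numeric(population$timer %||% rep(0, n)),
              rep(0, spare_ikb + spare_il8))
  )
}

.arrays_to_pop <- function(arr) {
  keep <- arr$alive == 1L
  ids <- seq_along(arr$type)
  pop <- tibble::tibble(
    id = ids[keep],
    type = .type_name(arr$type[keep]),
    state = .state_name(arr$state[keep]),
    x = arr$x[keep], y = arr$y[keep], z = arr$z[keep],
    partner_id = ifelse(is.na(arr$partner[keep]) | arr$partner[keep] < 0,
                        NA_integer_, arr$partner[keep]),
    timer = arr$timer[keep],
    hits = arr$hits[keep]
  )
  # reindex ids (and partner references) to a dense 1..n
  remap <- match(pop$partner_id, pop$id)
  pop$id <- seq_len(nrow(pop))
  pop$partner_id <- pop$id[remap]
  class(pop) <- c("nfkb_population", class(pop))
  pop
}

#' Run the spatial simulation
#'
#' Simulates `duration_min` minutes of cell time under a configuration:
#' Brownian motion of every mobile agent, radius-gated reactions, nuclear
#' transport, delayed transcription and the stimulation protocol.  The run
#' is a pure function of `(config, population, seed, replicate)`; the
#' replicate index selects an independent, stable random substream of the
#' master seed.
#'
#' @param config an [default_config()] object.
#' @param duration_min simulated minutes (default from `config$run`).
#' @param seed master seed (default from `config$run`).
#' @param replicate replicate index (>= 1); replicate `i` is identical
#'   regardless of how many other replicates run.
#' @param population warm-start population tibble; by default the initial
#'   resting population is built from the configuration.
#' @param record_every_min observable output cadence in minutes.
#' @return An `nfkb_sim` object with elements `timeseries` (per-interval
#'   observable counts and cumulative event counters), `population` (final
#'   state), `config`, `seed`, `replicate`.
#' @examples
#' \donttest{
#' cfg <- default_config(counts = list(scale_factor = 0.01),
#'                       run = list(duration_min = 10))
#' sim <- simulate_cell(cfg, seed = 1)
#' tidy(sim)
#' }
#' @export
simulate_cell <- function(config, duration_min = NULL, seed = NULL,
                          replicate = 1L, population = NULL,
                          record_every_min = NULL) {
  stopifnot(inherits(config, "nfkb_config"))
  duration_min <- duration_min %||% config$run$duration_min
  seed <- as.integer(seed %||% config$run$seed)
  record_every_min <- record_every_min %||% config$run$record_every_min

  if (is.null(population)) {
    set.seed(seed + 1000003L * (replicate - 1L))
    population <- build_population_from_config(config)
  }

  params <- .compile_params(config)
  dt <- config$motion$dt
  n_steps <- as.integer(round(duration_min * 60 / dt))
  record_every <- max(1L, as.integer(round(record_every_min * 60 / dt)))

  # synthesis headroom
  raw <- is.list(population) && !is.data.frame(population) &&
    is.integer(population$type)
  if (raw) {
    tx_code <- .type_code("TRANSCRIPTION_SITE")
    n_tx <- sum(population$type == tx_code & population$alive == 1L)
    n_tx_ikb <- sum(population$type == tx_code & population$alive == 1L &
                      population$hits == 0L)
  } else {
    n_tx <- sum(population$type == "TRANSCRIPTION_SITE")
    n_tx_ikb <- sum(population$type == "TRANSCRIPTION_SITE" &
                      population$hits == 0)
  }
  waves <- ceiling(duration_min / config$pathway$tx_time_min) + 2
  spare_ikb <- as.integer(n_tx_ikb * config$pathway$burst_ikb * waves + 64)
  spare_il8 <- as.integer((n_tx - n_tx_ikb) * config$pathway$burst_il8 *
                            waves + 64)
  if (raw) {
    # spare capacity already present in the carried arrays counts towards
    # the headroom
    free_ikb <- sum(population$type == .type_code("IKB") &
                      population$alive == 0L)
    free_il8 <- sum(population$type == .type_code("IL8") &
                      population$alive == 0L)
    spare_ikb <- max(0L, spare_ikb - free_ikb)
    spare_il8 <- max(0L, spare_il8 - free_il8)
  }

  arr <- .pop_to_arrays(population, spare_ikb, spare_il8)
  arr$partner[is.na(arr$partner)] <- -1L
  res <- abm_run_cpp(arr, config$geometry, params, n_steps, record_every,
                     seed, as.integer(replicate))
  if (isTRUE(res$overflow))
    warning("synthesis capacity exhausted; late bursts were dropped",
            call. = FALSE)

  ts <- tibble::as_tibble(as.data.frame(res$record))
  names(ts) <- .record_cols
  ts <- ts[seq_len(res$n_recorded), ]

  structure(
    list(timeseries = ts, population = .arrays_to_pop(res$population),
         population_raw = res$population,
         config = config, seed = seed, replicate = as.integer(replicate),
         duration_min = duration_min),
    class = "nfkb_sim"
  )
}

#' Build the initial population described by a configuration
#'
#' Applies the scale factor to the canonical counts, splits the receptor
#' pool into TILRR-bearing and bare complexes by `counts$tilrr_fraction`,
#' and constructs the resting population (cytoskeleton-bound fraction,
#' NF-kB:IkBa pairing, placements).
#'
#' @param config an `nfkb_config`.
#' @return A population tibble.
#' @export
build_population_from_config <- function(config) {
  counts <- scale_counts(default_counts(), config$counts$scale_factor)
  n_rec <- counts$count[counts$type == "IL1RI_TILRR"] +
    counts$count[counts$type == "IL1RI"]
  f <- if (config$pathway$variant == "none") 0 else
    config$counts$tilrr_fraction
  n_til <- as.integer(round(n_rec * f))
  counts$count[counts$type == "IL1RI_TILRR"] <- n_til
  counts$count[counts$type == "IL1RI"] <- n_rec - n_til
  geom <- cell_geometry(config$geometry$cell_radius,
                        config$geometry$nucleus_radius,
                        config$geometry$membrane_thickness)
  bf <- if (config$binding$cytoskeleton_binding)
    config$counts$bound_fraction else 0
  build_initial_population(counts, geom, bound_fraction = bf,
                           tx_ikb_fraction = config$pathway$tx_ikb_fraction)
}

#' @export
print.nfkb_sim <- function(x, ...) {
  last <- x$timeseries[nrow(x$timeseries), ]
  cat("<nfkb_sim>", x$duration_min, "min | seed", x$seed,
      "| replicate", x$replicate, "\n")
  cat("  final: IkB", last$ikb_total, "| cyto-bound", last$ikb_cyto,
      "| nuclear NF-kB", last$nfkb_nuclear, "| IL-8", last$il8, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' @param x an `nfkb_sim` object.
#' @param ... unused.
#' @return The per-minute observable tibble, one row per output interval.
#' @export
tidy.nfkb_sim <- function(x, ...) x$timeseries

#' One-row summary of a simulation
#'
#' @param x an `nfkb_sim` object.
#' @param ... unused.
#' @return A one-row tibble with the endpoint observables and the
#'   bound-fraction summary.
#' @export
glance.nfkb_sim <- function(x, ...) {
  ts <- x$timeseries
  last <- ts[nrow(ts), ]
  tibble::tibble(
    duration_min = x$duration_min,
    seed = x$seed,
    replicate = x$replicate,
    ikb_total_end = last$ikb_total,
    ikb_cyto_end = last$ikb_cyto,
    bound_fraction_end = ifelse(last$ikb_total > 0,
                                last$ikb_cyto / last$ikb_total, NA_real_),
    nfkb_nuclear_peak = max(ts$nfkb_nuclear),
    il8_end = last$il8,
    caspase3_active_end = last$caspase3_active
  )
}

#' Plot the main observables of a run
#'
#' @param object an `nfkb_sim` object.
#' @param vars observable columns to draw.
#' @param ... unused.
#' @return A ggplot object (observable counts over simulated minutes).
#' @export
autoplot.nfkb_sim <- function(object,
                              vars = c("ikb_total", "ikb_cyto",
                                       "nfkb_nuclear", "il8"), ...) {
  long <- tidyr::pivot_longer(object$timeseries[, c("time", vars)],
                              -"time", names_to = "observable")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (simulated min)", y = "agent count",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
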