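#' Default simulation configuration
#'
#' The fully-resolved configuration is a nested named list mirroring the
#' structured-text (YAML) config file: geometry, motion constants, agent
#' counts (with scale factor), cytoskeleton binding parameters, pathway
#' radii and kinetic constants, the stimulation protocol and run settings.
#' Interaction radii are the model's calibrated encoding of macroscopic
#' rates (see [calibrate_radius()]); the shipped defaults were produced by
#' the calibration script under `scripts/` at the default desk scale
#' (`scale_factor = 0.1`).
#'
#' @param ... named overrides, e.g. `default_config(run = list(seed = 7))`;
#'   nested lists are merged key-wise.
#' @return A `nfkb_config` object (nested named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    geometry = list(
      cell_radius = 10, nucleus_radius = 4, membrane_thickness = 0.2
    ),
    motion = list(D = 1.0, dt = 1.0),
    counts = list(
      scale_factor = 0.1,
      bound_fraction = 2 / 3,
      tilrr_fraction = 1.0,
      endogenous_tilrr_fraction = 0.1
    ),
    binding = list(
      regime = "fast",
      kon_radius = 0.065,
      koff_per_min = 1 / 40,
      slow_factor = 50,
      release_level = "active_40_50",
      dissociator_radius_40 = 0.034,
      dissociator_radius_90 = 0.10,
      priming_radius = 0.56,
      priming_hits = 40,
      k_deact_adiss_per_min = 0.05,
      dissociate_from_cytoskeleton = TRUE,
      dissociate_from_nfkb = TRUE,
      cytoskeleton_binding = TRUE
    ),
    pathway = list(
      variant = "wt",
      low_high_ratio = 0.32,
      r_myd88 = 0.39,
      r_pi3k = 0.39,
      r_cascade = 0.067,
      r_cascade_mid = 0.121,
      r_tak_activation = 0.235,
      r_ikk_activation = 0.162,
      r_ras = 0.067,
      r_akt = 0.121,
      r_caspase = 0.235,
      r_phospho = 0.184,
      r_basal_phospho = 0.15,
      r_assoc = 0.34,
      r_nfkb_dissociator = 0.20,
      r_import = 0.215,
      r_export = 0.28,
      r_tx_ikb = 0.12,
      r_tx_il8 = 0.03,
      allow_ikb_import = TRUE,
      ras_on_branch = "pi3k",
      k_deact_per_min = 0.2,
      k_caspase_basal_per_min = 1 / 30,
      tx_time_min = 20,
      burst_ikb = 16,
      burst_il8 = 12,
      tx_ikb_fraction = 0.5,
      pikb_lag_min = 2
    ),
    protocol = list(
      stim_start_min = 0,
      stim_duration_min = 1e6,   # continuous unless shortened
      dose = 1.0
    ),
    run = list(
      duration_min = 60,
      record_every_min = 1,
      replicates = 3,
      seed = 1
    )
  )
  over <- list(...)
  if (length(over)) cfg <- .merge_config(cfg, over)
  .validate_config(cfg)
}

.merge_config <- function(base, over) {
  for (k in names(over)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", k, call. = FALSE)
    if (is.list(base[[k]]) && is.list(over[[k]]))
      base[[k]] <- .merge_config(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (geometry$nucleus_radius >= geometry$cell_radius)
      stop("nucleus must fit inside the cell", call. = FALSE)
    if (counts$scale_factor <= 0)
      stop("counts.scale_factor must be positive", call. = FALSE)
    if (counts$bound_fraction < 0 || counts$bound_fraction > 1)
      stop("counts.bound_fraction must lie in [0, 1]", call. = FALSE)
    if (counts$tilrr_fraction < 0 || counts$tilrr_fraction > 1)
      stop("counts.tilrr_fraction must lie in [0, 1]", call. = FALSE)
    if (!binding$regime %in% c("fast", "slow"))
      stop("binding.regime must be 'fast' or 'slow'", call. = FALSE)
    if (!binding$release_level %in%
          c("passive_only", "active_40_50", "active_90_100"))
      stop("binding.release_level must be one of passive_only, ",
           "active_40_50, active_90_100", call. = FALSE)
    if (!pathway$variant %in% c("wt", "d448", "r425", "none"))
      stop("pathway.variant must be one of wt, d448, r425, none",
           call. = FALSE)
    if (!pathway$ras_on_branch %in% c("pi3k", "myd88"))
      stop("pathway.ras_on_branch must be 'pi3k' or 'myd88'", call. = FALSE)
    if (protocol$dose < 0 || protocol$dose > 1)
      stop("protocol.dose must lie in [0, 1]", call. = FALSE)
    if (motion$dt <= 0 || motion$D < 0)
      stop("motion constants must be positive", call. = FALSE)
  })
  structure(cfg, class = "nfkb_config")
}

#' @export
print.nfkb_config <- function(x, ...) {
  cat("<nfkb_config> scale", x$counts$scale_factor,
      "| regime", x$binding$regime,
      "| release", x$binding$release_level,
      "| variant", x$pathway$variant,
      "| dose", x$protocol$dose, "\n")
  invisible(x)
}

#' Load / write a configuration file
#'
#' Configurations are YAML; unknown keys are rejected, missing keys filled
#' with defaults, and cross-field checks run.  An empty file yields the
#' full default configuration.  `write_config()` dumps the fully-resolved
#' configuration (round-trips through `load_config()`).
#'
#' @param path file path.
#' @return `load_config` returns a validated `nfkb_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(default_config, raw)
}

#' @rdname load_config
#' @param config an `nfkb_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

# engine-facing flat parameter list -----------------------------------------
.compile_params <- function(config) {
  p <- config$pathway
  b <- config$binding
  aff <- variant_affinities(p$variant)
  r_my <- affinity_to_radius_scaling(p$r_myd88, aff$myd88, p$low_high_ratio)
  r_pi <- affinity_to_radius_scaling(p$r_pi3k, aff$pi3k, p$low_high_ratio)
  # the bare IL-1RI complex (no TILRR) recruits both adapters weakly
  r_my_plain <- affinity_to_radius_scaling(p$r_myd88, "Low", p$low_high_ratio)
  r_pi_plain <- affinity_to_radius_scaling(p$r_pi3k, "Low", p$low_high_ratio)

  slow <- b$regime == "slow"
  koff <- if (slow) b$koff_per_min / b$slow_factor else b$koff_per_min
  r_kon <- if (slow) b$kon_radius / b$slow_factor^(1 / 3) else b$kon_radius

  level <- match(b$release_level,
                 c("passive_only", "active_40_50", "active_90_100")) - 1L
  r_arel <- switch(b$release_level,
    passive_only = 0,
    active_40_50 = b$dissociator_radius_40,
    active_90_100 = b$dissociator_radius_90
  )

  list(
    D = config$motion$D, dt = config$motion$dt,
    r_myd88_tilrr = r_my, r_myd88_plain = r_my_plain,
    r_pi3k_tilrr = r_pi, r_pi3k_plain = r_pi_plain,
    r_cascade = p$r_cascade, r_cascade_mid = p$r_cascade_mid,
    r_tak_act = p$r_tak_activation, r_ikk_act = p$r_ikk_activation,
    r_ras = p$r_ras, r_akt = p$r_akt,
    r_casp = p$r_caspase, r_phospho = p$r_phospho,
    r_basal = p$r_basal_phospho, r_assoc = p$r_assoc,
    r_ndiss = p$r_nfkb_dissociator, r_kon = r_kon, r_arel = r_arel,
    r_adiss = b$priming_radius, r_import = p$r_import,
    r_export = p$r_export, r_tx_ikb = p$r_tx_ikb, r_tx_il8 = p$r_tx_il8,
    koff_per_min = koff,
    k_deact_per_min = p$k_deact_per_min,
    k_deact_adiss_per_min = b$k_deact_adiss_per_min,
    k_casp_basal_per_min = p$k_caspase_basal_per_min,
    m_hits = as.integer(b$priming_hits),
    pikb_lag_min = p$pikb_lag_min, tx_time_min = p$tx_time_min,
    burst_ikb = as.integer(p$burst_ikb), burst_il8 = as.integer(p$burst_il8),
    dissociate_from_cytoskeleton = isTRUE(b$dissociate_from_cytoskeleton),
    dissociate_from_nfkb = isTRUE(b$dissociate_from_nfkb),
    cytoskeleton_binding = isTRUE(b$cytoskeleton_binding),
    allow_ikb_import = isTRUE(p$allow_ikb_import),
    release_level = level,
    stim_start_min = config$protocol$stim_start_min,
    stim_end_min = config$protocol$stim_start_min +
      config$protocol$stim_duration_min,
    dose = config$protocol$dose,
    ras_source_type = if (p$ras_on_branch == "pi3k")
      .type_code("PI3K") else .type_code("MYD88")
  )
}

#' Write / read an observable time series as CSV
#'
#' One row per output interval, stable column order, deterministic bytes
#' for a given frame.
#'
#' @param frame a time-series tibble (from a simulation result).
#' @param path file path.
#' @return `write_timeseries` returns `path` invisibly.
#' @export
write_timeseries <- function(frame, path) {
  readr::write_csv(frame, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = "d"),
                  progress = FALSE)
}
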