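#' Adapter affinities of the IL-1RI receptor complex variants
#'
#' Recruitment strength of the two adapters by the receptor complex:
#' without TILRR both are Low; with wild-type TILRR both are High; the
#' D448 mutant lowers MyD88 recruitment only (inflammatory branch), the
#' R425 mutant lowers PI3K recruitment only (anti-apoptotic branch).
#'
#' @param variant `"none"`, `"wt"`, `"d448"` or `"r425"`.
#' @return List with ordinal `myd88` and `pi3k` affinities.
#' @examples
#' variant_affinities("d448")
#' @export
variant_affinities <- function(variant = c("wt", "d448", "r425", "none")) {
  variant <- match.arg(variant)
  switch(variant,
    none = list(variant = "none", myd88 = "Low", pi3k = "Low"),
    wt = list(variant = "wt", myd88 = "High", pi3k = "High"),
    d448 = list(variant = "d448", myd88 = "Low", pi3k = "High"),
    r425 = list(variant = "r425", myd88 = "High", pi3k = "Low")
  )
}

#' Stimulation protocol
#'
#' IL-1 stimulation is modelled by switching a dosed fraction of the
#' receptor complexes to their active state at `start_min`; under
#' continuous stimulation they stay active until `start_min +
#' duration_min`, after which all receptors revert and the cell relaxes
#' back towards its resting state.
#'
#' @param dose fraction of receptor agents activated, in `[0, 1]`.
#' @param start_min stimulation onset (simulated minutes).
#' @param duration_min stimulation window length.
#' @return A `nfkb_protocol` list.
#' @export
stimulation_protocol <- function(dose = 1, start_min = 0,
                                 duration_min = 1e6) {
  if (dose < 0 || dose > 1)
    stop("dose must lie in [0, 1]", call. = FALSE)
  structure(list(dose = dose, start_min = start_min,
                 duration_min = duration_min), class = "nfkb_protocol")
}

#' Apply a stimulation protocol to a population at a time point
#'
#' Sets the dosed fraction of receptor agents active when `t_min` falls
#' inside the protocol window and deactivates all receptors outside it.
#' (Inside a run the engine applies the same protocol at the window
#' boundaries; this function is the inspectable single-step form.)
#'
#' @param population a population tibble.
#' @param protocol a [stimulation_protocol()].
#' @param t_min current simulated time in minutes.
#' @return The updated population tibble.
#' @export
stimulate <- function(population, protocol, t_min = 0) {
  rec <- population$type %in% c("IL1RI_TILRR", "IL1RI")
  inside <- t_min >= protocol$start_min &&
    t_min < protocol$start_min + protocol$duration_min
  if (inside) {
    idx <- which(rec)
    n_on <- round(protocol$dose * length(idx))
    on <- sample(idx, n_on)
    population$state[on] <- "ACTIVE"
  } else {
    population$state[rec] <- "INACTIVE"
  }
  population
}

.rule_row <- function(name, type_a, states_a, type_b, states_b, radius,
                      event_a = NA_character_, event_b = NA_character_) {
  reaction_rule(name, type_a, states_a, type_b, states_b, radius,
                prob = 1, event_a = event_a, event_b = event_b)
}

#' The receptor-to-kinase cascade as a rule table
#'
#' Emits the activation rules wired by the configuration: the active
#' receptor complex recruits MyD88 (radius scaled by the variant's MyD88
#' affinity) and PI3K (scaled by its PI3K affinity); MyD88 activates IRAK,
#' then TRAF, TAK and IKK in sequence; the PI3K branch runs through Ras to
#' Akt (Ras placement is configurable between the two branches).  Every
#' activation is catalytic: the upstream agent stays active and each tier
#' requires contact with an active member of the tier above.
#'
#' @param config an [default_config()] object.
#' @return A rule-table tibble (one row per reaction channel).
#' @export
cascade_rules <- function(config = default_config()) {
  p <- .compile_params(config)
  act <- c("ACTIVE")
  myd_act <- c("ACTIVE_TILRR", "ACTIVE_ACP")
  ras_src <- if (config$pathway$ras_on_branch == "pi3k") "PI3K" else "MYD88"
  dplyr::bind_rows(
    .rule_row("receptor_tilrr_recruits_myd88", "IL1RI_TILRR", act,
              "MYD88", "INACTIVE", p$r_myd88_tilrr,
              event_b = "activate_by_tilrr"),
    .rule_row("receptor_plain_recruits_myd88", "IL1RI", act,
              "MYD88", "INACTIVE", p$r_myd88_plain,
              event_b = "activate_by_acp"),
    .rule_row("receptor_tilrr_recruits_pi3k", "IL1RI_TILRR", act,
              "PI3K", "INACTIVE", p$r_pi3k_tilrr, event_b = "activate"),
    .rule_row("receptor_plain_recruits_pi3k", "IL1RI", act,
              "PI3K", "INACTIVE", p$r_pi3k_plain, event_b = "activate"),
    .rule_row("myd88_activates_irak", "MYD88", myd_act,
              "IRAK", "INACTIVE", p$r_cascade, event_b = "activate"),
    .rule_row("irak_activates_traf", "IRAK", act,
              "TRAF", "INACTIVE", p$r_cascade_mid, event_b = "activate"),
    .rule_row("traf_activates_tak", "TRAF", act,
              "TAK", "INACTIVE", p$r_tak_act, event_b = "activate"),
    .rule_row("tak_activates_ikk", "TAK", act,
              "IKK", "INACTIVE", p$r_ikk_act, event_b = "activate"),
    .rule_row("ras_activation", ras_src,
              if (ras_src == "MYD88") myd_act else act,
              "RAS", "INACTIVE", p$r_ras, event_b = "activate"),
    .rule_row("ras_activates_akt", "RAS", act,
              "AKT", "INACTIVE", p$r_akt, event_b = "activate")
  )
}

#' IKK phosphorylation of IkBa
#'
#' Active IKK phosphorylates free and NF-kB-bound IkBa on contact; a bound
#' complex releases its NF-kB partner.  Phosphorylated IkBa (pIkB) is
#' terminal and removed after a short degradation lag.
#' Cytoskeleton-bound IkBa is not a substrate: the sequestered pool stays
#' un-phosphorylated throughout stimulation.
#'
#' @inheritParams cascade_rules
#' @return A rule-table tibble.
#' @export
ikk_phosphorylation_rule <- function(config = default_config()) {
  p <- .compile_params(config)
  dplyr::bind_rows(
    .rule_row("ikk_phosphorylates_ikb", "IKK", "ACTIVE",
              "IKB", c("FREE", "BOUND_NFKB"), p$r_phospho,
              event_b = "phosphorylate"),
    .rule_row("basal_ikb_turnover", "IKB_PHOSPHORYLATOR", "ACTIVE",
              "IKB", c("FREE", "BOUND_NFKB"), p$r_basal,
              event_b = "phosphorylate")
  )
}

#' Nuclear transport rules
#'
#' Translocation between cytoplasm and nucleus requires contact with a
#' transport receptor on the nuclear membrane; otherwise the envelope
#' reflects.  Import carries free NF-kB (and, by default, free IkBa, which
#' enables nuclear re-sequestration); export carries NF-kB:IkBa complexes
#' (the negative feedback that ends a transcription wave), free IkBa and
#' IL-8.
#'
#' @param direction `"import"` or `"export"`.
#' @inheritParams cascade_rules
#' @return A rule-table tibble.
#' @export
nuclear_transport_rule <- function(direction = c("import", "export"),
                                   config = default_config()) {
  direction <- match.arg(direction)
  p <- .compile_params(config)
  if (direction == "import") {
    out <- .rule_row("import_free_nfkb", "NUCLEAR_IMPORT", "ACTIVE",
                     "NFKB", "NFKB_FREE", p$r_import)
    if (p$allow_ikb_import)
      out <- dplyr::bind_rows(
        out, .rule_row("import_free_ikb", "NUCLEAR_IMPORT", "ACTIVE",
                       "IKB", "FREE", p$r_import))
    out
  } else {
    dplyr::bind_rows(
      .rule_row("export_nfkb_ikb_complex", "NUCLEAR_EXPORT", "ACTIVE",
                "NFKB", "NFKB_BOUND_IKB", p$r_export),
      .rule_row("export_free_ikb", "NUCLEAR_EXPORT", "ACTIVE",
                "IKB", "FREE", p$r_export),
      .rule_row("export_il8", "NUCLEAR_EXPORT", "ACTIVE",
                "IL8", "IL8_ACTIVE", p$r_export)
    )
  }
}

#' Transcription rule parameters
#'
#' A non-busy transcription site that contacts free nuclear NF-kB becomes
#' busy for the fixed transcription time, after which a burst of its gene
#' product (IkBa or IL-8) appears at the site, matures and becomes
#' exportable.  Without nuclear NF-kB there is no synthesis (basal
#' transcription is zero).
#'
#' @inheritParams cascade_rules
#' @return A list with the engagement radii, transcription time and burst
#'   sizes.
#' @export
transcription_rule <- function(config = default_config()) {
  p <- .compile_params(config)
  list(
    r_engage_ikb = p$r_tx_ikb, r_engage_il8 = p$r_tx_il8,
    transcription_time_min = p$tx_time_min,
    burst_ikb = p$burst_ikb, burst_il8 = p$burst_il8
  )
}

#' The PI3K / Akt / Caspase-3 branch
#'
#' Active PI3K drives Akt activation (through Ras on the default wiring);
#' active Akt deactivates Caspase-3 agents on contact, the anti-apoptotic
#' suppression.  The branch has no dependence on IkBa state, so
#' perturbing cytoskeletal sequestration leaves Caspase-3 trajectories
#' unchanged.
#'
#' @inheritParams cascade_rules
#' @return A rule-table tibble.
#' @export
akt_caspase_rules <- function(config = default_config()) {
  p <- .compile_params(config)
  .rule_row("akt_suppresses_caspase3", "AKT", "ACTIVE",
            "CASPASE3", "ACTIVE", p$r_casp, event_b = "suppress_by_akt")
}

#' Full rule table of a configuration
#'
#' Concatenates every reaction channel the engine will run under `config`,
#' for inspection and rule-by-rule testing.
#'
#' @inheritParams cascade_rules
#' @return A rule-table tibble.
#' @export
pathway_rules <- function(config = default_config()) {
  bp <- binding_params(config)
  dplyr::bind_rows(
    cascade_rules(config),
    ikk_phosphorylation_rule(config),
    akt_caspase_rules(config),
    nuclear_transport_rule("import", config),
    nuclear_transport_rule("export", config),
    binding_rule(bp, config),
    passive_release_rule(bp),
    active_release_rule(bp, config)
  )
}
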