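#' Cytoskeleton:IkBa binding parameters
#'
#' Sequestration of IkBa on cytoskeletal (actin/spectrin) sites is a
#' reversible bimolecular binding with association rate Kon (encoded as
#' the binding radius) and first-order dissociation rate Koff.  The fast
#' and slow exchange regimes share the same equilibrium constant
#' `ka = kon / koff`: the slow regime scales both rates down by
#' `slow_factor` (default 50), so only the kinetics differ.  On top of the
#' passive Koff exchange, stimulated "active release" is mediated by
#' actin:IkBa dissociator agents switched on downstream of the receptor;
#' its two shipped levels are calibrated so that the bound pool falls by
#' 40-50% or 90-100% within 60 minutes of saturating stimulation in the
#' regime's own kinetics.
#'
#' @param config an [default_config()] object (regime, radii and switches
#'   are read from its `binding` block).
#' @return A `nfkb_binding_params` list: `kon` (volume/time), `koff`
#'   (per minute), `ka`, `regime`, `release_level`, switches.
#' @export
binding_params <- function(config = default_config()) {
  b <- config$binding
  slow <- b$regime == "slow"
  koff_min <- if (slow) b$koff_per_min / b$slow_factor else b$koff_per_min
  r_kon <- if (slow) b$kon_radius / b$slow_factor^(1 / 3) else b$kon_radius
  kon <- radius_to_rate(r_kon, config$motion$D, config$motion$dt)
  structure(list(
    regime = toupper(b$regime),
    kon = kon,
    kon_radius = r_kon,
    koff_per_min = koff_min,
    ka = kon / (koff_min / 60),
    release_level = toupper(b$release_level),
    dissociation_enabled = isTRUE(b$dissociate_from_cytoskeleton),
    nfkb_dissociation_enabled = isTRUE(b$dissociate_from_nfkb),
    binding_enabled = isTRUE(b$cytoskeleton_binding)
  ), class = "nfkb_binding_params")
}

#' @export
print.nfkb_binding_params <- function(x, ...) {
  cat("<binding params>", x$regime, "regime | kon", signif(x$kon, 3),
      "| koff/min", signif(x$koff_per_min, 3), "| Ka", signif(x$ka, 3),
      "|", x$release_level, "\n")
  invisible(x)
}

#' Cytoskeletal binding rule
#'
#' Free cytoplasmic IkBa binds an unoccupied cytoskeletal site within the
#' Kon-calibrated radius; the pair is immobile (sites are fixed).  An
#' occupied site accepts no further IkBa.
#'
#' @param params a [binding_params()] object.
#' @param config the configuration the radius is read from.
#' @return A rule-table tibble (empty if binding is disabled).
#' @export
binding_rule <- function(params, config = default_config()) {
  if (!params$binding_enabled) {
    out <- reaction_rule("ikb_binds_cytoskeleton", "IKB", "FREE",
                         "CYTOSKELETON_SITE", "ACTIVE_UNOCCUPIED", 0,
                         event_a = "bind_cytoskeleton", event_b = "bind_ikb")
    return(out[0, ])
  }
  reaction_rule("ikb_binds_cytoskeleton", "IKB", "FREE",
                "CYTOSKELETON_SITE", "ACTIVE_UNOCCUPIED",
                params$kon_radius,
                event_a = "bind_cytoskeleton", event_b = "bind_ikb")
}

#' Passive release rule
#'
#' Each bound pair unbinds with per-step probability
#' `1 - exp(-koff * dt)`, independent of stimulation; the released IkBa
#' re-enters the free state at the site position.  Under the slow regime
#' this passive exchange is negligible on the one-hour scale.
#'
#' @inheritParams binding_rule
#' @param dt time step used for the per-step probability (seconds).
#' @return List with the per-minute rate and the per-step probability at
#'   the configured time step.
#' @export
passive_release_rule <- function(params, dt = NULL) {
  dt <- dt %||% 1.0
  list(
    name = "passive_release",
    koff_per_min = if (params$dissociation_enabled) params$koff_per_min
                   else 0,
    prob_per_step = if (params$dissociation_enabled)
      1 - exp(-params$koff_per_min * dt / 60) else 0
  )
}

#' Active release rule
#'
#' Actin:IkBa dissociator agents are switched on downstream of receptor
#' signalling (multi-hit priming by repeated contacts with active
#' receptor complexes, giving a delayed, switch-like onset); an active
#' dissociator contacting an occupied site
#' releases its IkBa.  The dissociator radius per release level is
#' pre-calibrated so the cumulative stimulated depletion of the initially
#' bound pool reaches the level's band by 60 minutes under saturating
#' dose.  At `PASSIVE_ONLY` no rule is emitted.
#'
#' @inheritParams binding_rule
#' @return A rule-table tibble (zero rows for `PASSIVE_ONLY`).
#' @export
active_release_rule <- function(params, config = default_config()) {
  template <- reaction_rule("active_release", "ACTIN_IKB_DISSOCIATOR",
                            "ACTIVE", "CYTOSKELETON_SITE",
                            "ACTIVE_IKB_BOUND", 0, event_b = "release")
  if (params$release_level == "PASSIVE_ONLY" || !params$dissociation_enabled)
    return(template[0, ])
  radius <- switch(params$release_level,
    ACTIVE_40_50 = config$binding$dissociator_radius_40,
    ACTIVE_90_100 = config$binding$dissociator_radius_90
  )
  dplyr::bind_rows(
    reaction_rule("dissociator_priming_by_receptor", "IL1RI_TILRR",
                  "ACTIVE", "ACTIN_IKB_DISSOCIATOR", "INACTIVE",
                  config$binding$priming_radius,
                  event_b = "primed_by_receptor"),
    reaction_rule("active_release", "ACTIN_IKB_DISSOCIATOR", "ACTIVE",
                  "CYTOSKELETON_SITE", "ACTIVE_IKB_BOUND", radius,
                  event_b = "release")
  )
}

#' Set the dissociation master switches
#'
#' The two unstimulated dissociation regimes of the resting-cell analysis
#' are expressed through two switches: whether IkBa can leave the
#' cytoskeleton (passive Koff plus active release) and whether it can
#' leave NF-kB (spontaneous dissociator-mediated unbinding).  Disabling a
#' switch removes the corresponding rules.  "NF-kB only" accumulates IkBa
#' on the cytoskeleton without reaching a steady state; "neither" and
#' "both" are stationary at rest.
#'
#' @param config an `nfkb_config`.
#' @param dissociate_from_cytoskeleton,dissociate_from_nfkb logical
#'   switches.
#' @return The modified configuration.
#' @export
set_master_switch <- function(config, dissociate_from_cytoskeleton = TRUE,
                              dissociate_from_nfkb = TRUE) {
  config$binding$dissociate_from_cytoskeleton <-
    isTRUE(dissociate_from_cytoskeleton)
  config$binding$dissociate_from_nfkb <- isTRUE(dissociate_from_nfkb)
  .validate_config(unclass(config))
}

#' Named dissociation regimes of the resting-cell analysis
#'
#' Convenience constructor for the three regimes: `"nfkb_only"` (C),
#' `"neither"` (D) and `"both"` (E).
#'
#' @param config an `nfkb_config`.
#' @param regime regime name.
#' @return The modified configuration.
#' @export
dissociation_regime <- function(config,
                                regime = c("both", "neither", "nfkb_only")) {
  regime <- match.arg(regime)
  switch(regime,
    both = set_master_switch(config, TRUE, TRUE),
    neither = set_master_switch(config, FALSE, FALSE),
    nfkb_only = set_master_switch(config, FALSE, TRUE)
  )
}
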