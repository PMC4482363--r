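#' Define a reaction rule
#'
#' A rule names two reactant patterns (agent type plus a set of acceptable
#' states), an interaction radius, a contact probability and the event
#' labels applied to each reactant when the rule fires.  Rules are plain
#' one-row tibbles so a full rule set is an inspectable table.
#'
#' @param name rule label.
#' @param type_a,states_a initiating reactant pattern.
#' @param type_b,states_b partner pattern.
#' @param radius interaction radius (length units), `>= 0`.
#' @param prob probability of firing on contact, in `[0, 1]`.
#' @param event_a,event_b event labels applied to the reactants (see
#'   [transition_table()]); `NA` leaves a reactant's state unchanged
#'   (catalytic side).
#' @return One-row tibble of class `nfkb_rule_table`.
#' @export
reaction_rule <- function(name, type_a, states_a, type_b, states_b,
                          radius, prob = 1, event_a = NA_character_,
                          event_b = NA_character_) {
  stopifnot(radius >= 0, prob >= 0, prob <= 1)
  for (ev in list(c(type_a, states_a[1], event_a),
                  c(type_b, states_b[1], event_b))) {
    if (!is.na(ev[3])) legal_transition(ev[1], ev[2], ev[3]) # validates
  }
  out <- tibble::tibble(
    name = name, type_a = type_a, states_a = list(states_a),
    type_b = type_b, states_b = list(states_b), radius = radius,
    prob = prob, event_a = event_a, event_b = event_b
  )
  class(out) <- c("nfkb_rule_table", class(out))
  out
}

#' Find reacting pairs within a rule's radius
#'
#' Matches initiating reactants (pattern A) to partners (pattern B) within
#' the rule's interaction radius.  Initiators are processed in id order;
#' each takes its nearest still-available partner; exact distance ties are
#' broken by the seeded stream; every agent appears in at most one pair.
#' Matching runs on a uniform spatial hash whose result is identical to the
#' brute-force nearest-available matcher.
#'
#' @param population a population tibble.
#' @param rule a one-row rule table from [reaction_rule()].
#' @param seed integer seed for tie-breaks.
#' @return Tibble with columns `id_a`, `id_b`, `distance`.
#' @export
find_pairs <- function(population, rule, seed = 1L) {
  sel_a <- population$type == rule$type_a &
    population$state %in% rule$states_a[[1]]
  sel_b <- population$type == rule$type_b &
    population$state %in% rule$states_b[[1]]
  a <- population[sel_a, ]
  b <- population[sel_b, ]
  if (nrow(a) == 0 || nrow(b) == 0 || rule$radius <= 0)
    return(tibble::tibble(id_a = integer(0), id_b = integer(0),
                          distance = numeric(0)))
  dom <- max(abs(c(a$x, a$y, a$z, b$x, b$y, b$z)), 1) * 1.01
  m <- match_pairs_cpp(a$x, a$y, a$z, b$x, b$y, b$z, rule$radius, dom,
                       as.integer(seed), 0L)
  if (nrow(m) == 0)
    return(tibble::tibble(id_a = integer(0), id_b = integer(0),
                          distance = numeric(0)))
  ia <- m[, 1]; ib <- m[, 2]
  tibble::tibble(
    id_a = a$id[ia], id_b = b$id[ib],
    distance = sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2 +
                      (a$z[ia] - b$z[ib])^2)
  )
}

# brute-force O(n^2) nearest-available matcher: the reference the hashed
# matcher must reproduce (used by the test suite)
.find_pairs_bruteforce <- function(population, rule) {
  sel_a <- population$type == rule$type_a &
    population$state %in% rule$states_a[[1]]
  sel_b <- population$type == rule$type_b &
    population$state %in% rule$states_b[[1]]
  a <- population[sel_a, ]
  b <- population[sel_b, ]
  used <- rep(FALSE, nrow(b))
  out <- list()
  for (i in seq_len(nrow(a))) {
    if (nrow(b) == 0) break
    d2 <- (b$x - a$x[i])^2 + (b$y - a$y[i])^2 + (b$z - a$z[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && is.finite(d2[j]) && d2[j] <= rule$radius^2) {
      used[j] <- TRUE
      out[[length(out) + 1]] <- tibble::tibble(
        id_a = a$id[i], id_b = b$id[j], distance = sqrt(d2[j]))
    }
  }
  if (!length(out))
    return(tibble::tibble(id_a = integer(0), id_b = integer(0),
                          distance = numeric(0)))
  dplyr::bind_rows(out)
}

#' Apply a rule's effects to matched pairs
#'
#' Each candidate pair fires independently with the rule's contact
#' probability; fired pairs apply `event_a` / `event_b` atomically to both
#' reactants through the state machine (illegal resulting transitions
#' error, flagging a malformed rule).
#'
#' @param population a population tibble.
#' @param pairs output of [find_pairs()].
#' @param rule the rule that produced `pairs`.
#' @return List with the updated `population` and a tibble of `applied`
#'   pair ids.
#' @export
apply_reactions <- function(population, pairs, rule) {
  fire <- runif(nrow(pairs)) < rule$prob
  fired <- pairs[fire, ]
  for (k in seq_len(nrow(fired))) {
    ia <- match(fired$id_a[k], population$id)
    ib <- match(fired$id_b[k], population$id)
    if (!is.na(rule$event_a))
      population$state[ia] <-
        legal_transition(population$type[ia], population$state[ia],
                         rule$event_a)
    if (!is.na(rule$event_b))
      population$state[ib] <-
        legal_transition(population$type[ib], population$state[ib],
                         rule$event_b)
  }
  list(population = population, applied = fired)
}

#' Calibrate an interaction radius against a macroscopic rate
#'
#' Returns the radius at which a pair of well-mixed populations reacting on
#' contact (probability 1) reproduces the bimolecular rate constant `k`
#' (volume per time, per reactant pair the propensity is `k / volume`).
#' For radii small against the per-step diffusion length the per-step
#' encounter probability is the radius ball volume over the domain volume,
#' giving `k_geom = (4/3) pi r^3 / dt`; large radii saturate at the
#' diffusion-limited Smoluchowski rate `k_smol = 4 pi D r`.  The two are
#' combined in series (`1/k = 1/k_geom + 1/k_smol`) and inverted
#' numerically; the resulting rate law is validated against stochastic
#' simulation in the test suite.
#'
#' @param k target bimolecular rate constant (length^3 / time), `>= 0`.
#' @param D diffusion coefficient, `> 0`.
#' @param dt time step, `> 0`.
#' @param volume domain volume (length^3), `> 0`.
#' @param max_radius largest representable radius (default a fifth of the
#'   default cell radius); a `k` demanding more raises a calibration error.
#' @return Radius (length units); 0 when `k = 0`.
#' @examples
#' calibrate_radius(k = 0.01, D = 1, dt = 0.5, volume = 4000)
#' @export
calibrate_radius <- function(k, D, dt, volume, max_radius = 2) {
  stopifnot(k >= 0, D > 0, dt > 0, volume > 0)
  if (k == 0) return(0)
  f <- function(r) radius_to_rate(r, D, dt) - k
  if (f(max_radius) < 0)
    stop("rate k = ", k, " is not representable at this scale ",
         "(radius would exceed ", max_radius, ")", call. = FALSE)
  uniroot(f, c(1e-9, max_radius), tol = 1e-12)$root
}

#' @rdname calibrate_radius
#' @param r interaction radius.
#' @return `radius_to_rate` returns the effective bimolecular rate constant
#'   for a radius.
#' @export
radius_to_rate <- function(r, D, dt) {
  if (r <= 0) return(0)
  k_geom <- 4 / 3 * pi * r^3 / dt
  k_smol <- 4 * pi * D * r
  1 / (1 / k_geom + 1 / k_smol)
}

#' Scale an interaction radius by an ordinal affinity
#'
#' Adapter recruitment strength is encoded as the interaction radius: a
#' High-affinity receptor complex uses the base radius, a Low-affinity one
#' a radius reduced by `low_high_ratio`.
#'
#' @param base_radius radius at High affinity, `> 0`.
#' @param affinity `"Low"` or `"High"`.
#' @param low_high_ratio Low:High radius ratio in `(0, 1]`.
#' @return The scaled radius.
#' @export
affinity_to_radius_scaling <- function(base_radius,
                                       affinity = c("High", "Low"),
                                       low_high_ratio = 0.5) {
  affinity <- match.arg(affinity)
  stopifnot(base_radius > 0, low_high_ratio > 0, low_high_ratio <= 1)
  if (affinity == "High") base_radius else base_radius * low_high_ratio
}
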