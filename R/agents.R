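#' Agent taxonomy
#'
#' The simulator tracks 21 agent kinds: membrane receptors (the IL-1RI
#' complex with or without the TILRR co-receptor), nuclear transport
#' receptors, immobile cytoskeletal binding sites and transcription sites,
#' the cytoplasmic signalling cascade (MyD88, IRAK, TRAF, TAK, IKK and the
#' PI3K/Ras/Akt branch), the NF-kB / IkBa / IL-8 / Caspase-3 readouts and
#' three auxiliary activities (spontaneous NF-kB:IkBa dissociation,
#' stimulated actin:IkBa dissociation, basal IkBa phosphorylation).
#'
#' @return Character vector of the agent type names.
#' @export
agent_types <- function() names(.agent_type_codes)

#' Legal states per agent type
#'
#' @param type an agent type name (see [agent_types()]); `NULL` returns the
#'   full named list.
#' @return Character vector of legal state names (or a named list of them).
#' @export
agent_states <- function(type = NULL) {
  tbl <- list(
    NUCLEAR_IMPORT = "ACTIVE",
    NUCLEAR_EXPORT = "ACTIVE",
    IL1RI_TILRR = c("ACTIVE", "INACTIVE"),
    IL1RI = c("ACTIVE", "INACTIVE"),
    CYTOSKELETON_SITE = c("ACTIVE_UNOCCUPIED", "ACTIVE_IKB_BOUND",
                          "CYTO_INACTIVE"),
    TRANSCRIPTION_SITE = "ACTIVE",
    MYD88 = c("ACTIVE_TILRR", "ACTIVE_ACP", "INACTIVE"),
    IRAK = c("ACTIVE", "INACTIVE"),
    TRAF = c("ACTIVE", "INACTIVE"),
    TAK = c("ACTIVE", "INACTIVE"),
    RAS = c("ACTIVE", "INACTIVE"),
    PI3K = c("ACTIVE", "INACTIVE"),
    AKT = c("ACTIVE", "INACTIVE"),
    IKK = c("ACTIVE", "INACTIVE"),
    IKB = c("FREE", "BOUND_NFKB", "BOUND_CYTOSKELETON", "BEING_TRANSCRIBED",
            "PHOSPHO_PENDING_DEGRADATION"),
    NFKB = c("NFKB_FREE", "NFKB_BOUND_IKB"),
    IL8 = c("IL8_ACTIVE", "IL8_BEING_TRANSCRIBED"),
    CASPASE3 = c("ACTIVE", "INACTIVE"),
    NFKB_IKB_DISSOCIATOR = "ACTIVE",
    # the stimulated dissociator switches on downstream of the receptor,
    # so it carries an INACTIVE state in addition to the resting taxonomy
    ACTIN_IKB_DISSOCIATOR = c("ACTIVE", "INACTIVE"),
    IKB_PHOSPHORYLATOR = "ACTIVE"
  )
  if (is.null(type)) return(tbl)
  out <- tbl[[type]]
  if (is.null(out)) stop("unknown agent type: ", type, call. = FALSE)
  out
}

#' Default starting population counts
#'
#' The canonical starting numbers for every agent type at scale factor 1:
#' 600,000 cytoskeletal binding sites, 50,000 IkBa, 20,000 NF-kB, 70,000
#' actin:IkBa dissociators, 2,500 nuclear import and 200 nuclear export
#' receptors, 500 transcription sites, 3,000 receptor complexes, and the
#' signalling intermediates (MyD88/IRAK/TRAF/Ras/PI3K/IKK 20,000 each,
#' Akt 10,000, TAK 2,000, Caspase-3 2,500).  IL-8 starts at zero.
#'
#' @return A `nfkb_counts` object: tibble with `type`, `count` and a
#'   `scale_factor` attribute of 1.
#' @export
default_counts <- function() {
  counts <- c(
    NUCLEAR_IMPORT = 2500, NUCLEAR_EXPORT = 200,
    IL1RI_TILRR = 3000, IL1RI = 0,
    CYTOSKELETON_SITE = 600000, TRANSCRIPTION_SITE = 500,
    MYD88 = 20000, IRAK = 20000, TRAF = 20000, TAK = 2000, RAS = 20000,
    PI3K = 20000, AKT = 10000, IKK = 20000,
    IKB = 50000, NFKB = 20000, IL8 = 0, CASPASE3 = 2500,
    NFKB_IKB_DISSOCIATOR = 500, ACTIN_IKB_DISSOCIATOR = 70000,
    IKB_PHOSPHORYLATOR = 250
  )
  out <- tibble::tibble(type = names(counts), count = as.integer(counts))
  attr(out, "scale_factor") <- 1
  class(out) <- c("nfkb_counts", class(out))
  out
}

#' Scale a population down (or up) for desk-scale runs
#'
#' Multiplies every count by `scale_factor` and rounds to the nearest
#' integer; counts that were zero stay zero and non-zero counts never round
#' below one, so every species stays represented in tiny test populations.
#'
#' @param counts a [default_counts()] tibble.
#' @param scale_factor positive ratio.
#' @return The scaled `nfkb_counts` tibble.
#' @examples
#' scale_counts(default_counts(), 0.1)
#' @export
scale_counts <- function(counts, scale_factor) {
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      is.na(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be a single positive number", call. = FALSE)
  out <- dplyr::mutate(
    counts,
    count = dplyr::if_else(
      .data$count == 0L, 0L,
      pmax(1L, as.integer(round(.data$count * scale_factor)))
    )
  )
  attr(out, "scale_factor") <-
    (attr(counts, "scale_factor") %||% 1) * scale_factor
  class(out) <- unique(c("nfkb_counts", class(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.count_of <- function(counts, type) {
  i <- match(type, counts$type)
  if (is.na(i)) 0L else counts$count[i]
}

#' Build the initial resting-cell population
#'
#' All signalling proteins start inactive.  A configurable fraction of IkBa
#' (default 2/3, the resting cytoskeletal pool) starts bound to distinct
#' cytoskeletal sites; the remaining IkBa is paired 1:1 with NF-kB until
#' NF-kB is exhausted (any surplus IkBa is free), reflecting cytoplasmic
#' sequestration of NF-kB in the resting cell.  Membrane agents are placed
#' uniformly on their shells, cytoplasmic agents uniformly in the
#' cytoplasm, transcription sites uniformly in the nucleus (split between
#' the IkBa and IL-8 genes by `tx_ikb_fraction`).
#'
#' @param counts an `nfkb_counts` tibble.
#' @param geometry a [cell_geometry()] object.
#' @param bound_fraction fraction of IkBa bound to the cytoskeleton at t=0.
#' @param tx_ikb_fraction fraction of transcription sites assigned to the
#'   IkBa gene (the rest drive IL-8).
#' @return A population tibble: `id`, `type`, `state`, `x`, `y`, `z`,
#'   `partner_id`, `timer`, `hits`.
#' @export
build_initial_population <- function(counts, geometry,
                                     bound_fraction = 2 / 3,
                                     tx_ikb_fraction = 0.5) {
  stopifnot(bound_fraction >= 0, bound_fraction <= 1)
  n_ikb <- .count_of(counts, "IKB")
  n_nfkb <- .count_of(counts, "NFKB")
  n_sites <- .count_of(counts, "CYTOSKELETON_SITE")
  n_bound <- round(bound_fraction * n_ikb)
  if (n_bound > n_sites)
    stop("cytoskeleton-bound IkBa (", n_bound,
         ") exceeds available cytoskeleton sites (", n_sites, ")",
         call. = FALSE)

  rows <- list()
  add <- function(type, state, pos, timer = 0, hits = 0L) {
    if (nrow(pos) == 0) return(invisible(NULL))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      type = type, state = state, x = pos$x, y = pos$y, z = pos$z,
      partner_id = NA_integer_, timer = timer, hits = hits
    )
    invisible(NULL)
  }

  # membrane agents
  add("NUCLEAR_IMPORT", "ACTIVE",
      place_on_membrane(.count_of(counts, "NUCLEAR_IMPORT"),
                        "NUCLEAR_MEMBRANE", geometry))
  add("NUCLEAR_EXPORT", "ACTIVE",
      place_on_membrane(.count_of(counts, "NUCLEAR_EXPORT"),
                        "NUCLEAR_MEMBRANE", geometry))
  add("IL1RI_TILRR", "INACTIVE",
      place_on_membrane(.count_of(counts, "IL1RI_TILRR"),
                        "CELL_MEMBRANE", geometry))
  add("IL1RI", "INACTIVE",
      place_on_membrane(.count_of(counts, "IL1RI"),
                        "CELL_MEMBRANE", geometry))

  # transcription sites: gene carried in `hits` (0 = IkBa, 1 = IL-8)
  n_tx <- .count_of(counts, "TRANSCRIPTION_SITE")
  n_tx_ikb <- round(tx_ikb_fraction * n_tx)
  add("TRANSCRIPTION_SITE", "ACTIVE",
      place_in_compartment(n_tx, "NUCLEUS", geometry),
      hits = rep(c(0L, 1L), c(n_tx_ikb, n_tx - n_tx_ikb)))

  # cytoskeleton sites
  add("CYTOSKELETON_SITE", "ACTIVE_UNOCCUPIED",
      place_in_compartment(n_sites, "CYTOPLASM", geometry))

  # cytoplasmic signalling proteins, all inactive at rest
  for (tp in c("MYD88", "IRAK", "TRAF", "TAK", "RAS", "PI3K", "AKT", "IKK",
               "CASPASE3"))
    add(tp, "INACTIVE",
        place_in_compartment(.count_of(counts, tp), "CYTOPLASM", geometry))

  # auxiliary activities
  add("NFKB_IKB_DISSOCIATOR", "ACTIVE",
      place_in_compartment(.count_of(counts, "NFKB_IKB_DISSOCIATOR"),
                           "CYTOPLASM", geometry))
  add("ACTIN_IKB_DISSOCIATOR", "INACTIVE",
      place_in_compartment(.count_of(counts, "ACTIN_IKB_DISSOCIATOR"),
                           "CYTOPLASM", geometry))
  add("IKB_PHOSPHORYLATOR", "ACTIVE",
      place_in_compartment(.count_of(counts, "IKB_PHOSPHORYLATOR"),
                           "CYTOPLASM", geometry))

  # IkBa / NF-kB partition
  n_cplx <- min(n_ikb - n_bound, n_nfkb)
  n_free_ikb <- n_ikb - n_bound - n_cplx
  n_free_nfkb <- n_nfkb - n_cplx

  cplx_pos <- place_in_compartment(n_cplx, "CYTOPLASM", geometry)
  add("NFKB", "NFKB_BOUND_IKB", cplx_pos)
  add("IKB", "BOUND_NFKB", cplx_pos)
  add("NFKB", "NFKB_FREE",
      place_in_compartment(n_free_nfkb, "CYTOPLASM", geometry))
  add("IKB", "FREE",
      place_in_compartment(n_free_ikb, "CYTOPLASM", geometry))
  # bound IkBa sits on its site; positions assigned after ids below
  add("IKB", "BOUND_CYTOSKELETON",
      tibble::tibble(x = rep(0, n_bound), y = 0, z = 0))
  add("IL8", "IL8_ACTIVE",
      place_in_compartment(.count_of(counts, "IL8"), "CYTOPLASM", geometry))

  pop <- dplyr::bind_rows(rows)
  pop$id <- seq_len(nrow(pop))
  pop <- dplyr::relocate(pop, "id")

  # partner links: NFkB:IkB complexes (built in matching order above)
  idx_nfkb_b <- which(pop$type == "NFKB" & pop$state == "NFKB_BOUND_IKB")
  idx_ikb_b <- which(pop$type == "IKB" & pop$state == "BOUND_NFKB")
  pop$partner_id[idx_nfkb_b] <- pop$id[idx_ikb_b]
  pop$partner_id[idx_ikb_b] <- pop$id[idx_nfkb_b]

  # cytoskeleton-bound IkBa on distinct random sites
  idx_sites <- which(pop$type == "CYTOSKELETON_SITE")
  idx_cyto_ikb <- which(pop$type == "IKB" & pop$state == "BOUND_CYTOSKELETON")
  host <- sample(idx_sites, length(idx_cyto_ikb))
  pop$state[host] <- "ACTIVE_IKB_BOUND"
  pop$partner_id[host] <- pop$id[idx_cyto_ikb]
  pop$partner_id[idx_cyto_ikb] <- pop$id[host]
  pop$x[idx_cyto_ikb] <- pop$x[host]
  pop$y[idx_cyto_ikb] <- pop$y[host]
  pop$z[idx_cyto_ikb] <- pop$z[host]

  class(pop) <- c("nfkb_population", class(pop))
  pop
}

# ---------------------------------------------------------------------------
# state machine
# ---------------------------------------------------------------------------

# transition table as data: one row per legal (type, from, event) triple
.transitions <- function() {
  tribble <- tibble::tribble(
    ~type, ~from, ~event, ~to,
    "IL1RI_TILRR", "INACTIVE", "stimulate", "ACTIVE",
    "IL1RI_TILRR", "ACTIVE", "stimulation_end", "INACTIVE",
    "IL1RI", "INACTIVE", "stimulate", "ACTIVE",
    "IL1RI", "ACTIVE", "stimulation_end", "INACTIVE",
    "MYD88", "INACTIVE", "activate_by_tilrr", "ACTIVE_TILRR",
    "MYD88", "INACTIVE", "activate_by_acp", "ACTIVE_ACP",
    "MYD88", "ACTIVE_TILRR", "deactivate", "INACTIVE",
    "MYD88", "ACTIVE_ACP", "deactivate", "INACTIVE",
    "IKB", "FREE", "bind_nfkb", "BOUND_NFKB",
    "IKB", "FREE", "bind_cytoskeleton", "BOUND_CYTOSKELETON",
    "IKB", "FREE", "phosphorylate", "PHOSPHO_PENDING_DEGRADATION",
    "IKB", "BOUND_NFKB", "phosphorylate", "PHOSPHO_PENDING_DEGRADATION",
    "IKB", "BOUND_NFKB", "dissociate", "FREE",
    "IKB", "BOUND_CYTOSKELETON", "release", "FREE",
    "IKB", "BEING_TRANSCRIBED", "mature", "FREE",
    "NFKB", "NFKB_FREE", "bind_ikb", "NFKB_BOUND_IKB",
    "NFKB", "NFKB_BOUND_IKB", "dissociate", "NFKB_FREE",
    "NFKB", "NFKB_BOUND_IKB", "partner_degraded", "NFKB_FREE",
    "CYTOSKELETON_SITE", "ACTIVE_UNOCCUPIED", "bind_ikb",
      "ACTIVE_IKB_BOUND",
    "CYTOSKELETON_SITE", "ACTIVE_IKB_BOUND", "release",
      "ACTIVE_UNOCCUPIED",
    "IL8", "IL8_BEING_TRANSCRIBED", "mature", "IL8_ACTIVE",
    "CASPASE3", "INACTIVE", "basal_activate", "ACTIVE",
    "CASPASE3", "ACTIVE", "suppress_by_akt", "INACTIVE",
    "ACTIN_IKB_DISSOCIATOR", "INACTIVE", "primed_by_receptor", "ACTIVE",
    "ACTIN_IKB_DISSOCIATOR", "ACTIVE", "deactivate", "INACTIVE"
  )
  kin <- tibble::tibble(
    type = rep(c("IRAK", "TRAF", "TAK", "RAS", "PI3K", "AKT", "IKK"),
               each = 2),
    from = rep(c("INACTIVE", "ACTIVE"), 7),
    event = rep(c("activate", "deactivate"), 7),
    to = rep(c("ACTIVE", "INACTIVE"), 7)
  )
  dplyr::bind_rows(tribble, kin)
}

#' The per-type state transition table
#'
#' The complete set of legal `(type, from_state, event) -> to_state`
#' transitions, as data, so it can be enumerated in tests.  The
#' phosphorylated state is terminal: no event leads out of it (the agent is
#' removed after its degradation lag).
#'
#' @return A tibble with columns `type`, `from`, `event`, `to`.
#' @export
transition_table <- function() .transitions()

#' Apply a state-machine event
#'
#' Looks up the unique successor state for `(type, from_state, event)` and
#' errors on illegal combinations (for instance, any event on
#' phosphorylation-tagged IkBa, which is terminal).
#'
#' @param type agent type name.
#' @param from_state current state name.
#' @param event event label (see [transition_table()]).
#' @return The successor state name.
#' @examples
#' legal_transition("IKB", "FREE", "bind_nfkb")
#' @export
legal_transition <- function(type, from_state, event) {
  if (!from_state %in% agent_states(type))
    stop("state ", from_state, " is not legal for type ", type,
         call. = FALSE)
  tt <- .transitions()
  hit <- tt[tt$type == type & tt$from == from_state & tt$event == event, ]
  if (nrow(hit) != 1)
    stop("illegal transition: ", type, "[", from_state, "] --", event, "-->",
         call. = FALSE)
  hit$to
}

#' Write / read a population snapshot as CSV
#'
#' @param population a population tibble.
#' @param path file path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns the population tibble.
#' @export
write_population <- function(population, path) {
  readr::write_csv(
    population[, c("id", "type", "state", "x", "y", "z", "partner_id",
                   "timer", "hits")], path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_integer(), type = readr::col_character(),
      state = readr::col_character(), x = readr::col_double(),
      y = readr::col_double(), z = readr::col_double(),
      partner_id = readr::col_integer(), timer = readr::col_double(),
      hits = readr::col_integer()
    )
  )
  class(pop) <- c("nfkb_population", class(pop))
  pop
}
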