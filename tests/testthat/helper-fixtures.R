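# tiny configurations and populations used across the suite

tiny_config <- function(...) {
  default_config(counts = list(scale_factor = 0.01), ...)
}

# a quiet configuration with every channel off (engine harness)
quiet_config <- function(...) bare_config(...)

# uniform random population of one type/state in the cytoplasm
one_species_pop <- function(n, type, state, geometry, nucleus = FALSE) {
  pos <- if (nucleus) place_in_compartment(n, "NUCLEUS", geometry)
         else place_in_compartment(n, "CYTOPLASM", geometry)
  pop <- tibble::tibble(
    id = seq_len(n), type = type, state = state,
    x = pos$x, y = pos$y, z = pos$z,
    partner_id = NA_integer_, timer = 0, hits = 0L
  )
  pop
}

geom_default <- function() cell_geometry()
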