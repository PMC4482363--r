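#' Cell geometry: two concentric spheres
#'
#' The simulated cell is a sphere of radius `cell_radius` containing a
#' concentric spherical nucleus of radius `nucleus_radius`.  Membranes are
#' thin spherical shells of thickness `membrane_thickness` used to place
#' immobile membrane agents (receptors, nuclear pores) and to classify
#' positions into compartments.  Lengths are dimensionless simulation units;
#' with the defaults (10 and 4) the cytoplasm:nucleus volume ratio is about
#' 14.6:1, typical of an adherent epithelial cell.
#'
#' @param cell_radius outer cell radius (length units).
#' @param nucleus_radius nucleus radius; must be smaller than `cell_radius`.
#' @param membrane_thickness thickness of the membrane shells used for
#'   compartment classification and membrane placement.
#' @return An object of class `nfkb_geometry` (a named list).
#' @examples
#' geom <- cell_geometry()
#' compartment_of(data.frame(x = 0, y = 0, z = 0), geom)
#' @export
cell_geometry <- function(cell_radius = 10, nucleus_radius = 4,
                          membrane_thickness = 0.2) {
  stopifnot(is.numeric(cell_radius), cell_radius > 0,
            is.numeric(nucleus_radius), nucleus_radius > 0,
            is.numeric(membrane_thickness), membrane_thickness > 0)
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius", call. = FALSE)
  structure(
    list(cell_radius = cell_radius, nucleus_radius = nucleus_radius,
         membrane_thickness = membrane_thickness),
    class = "nfkb_geometry"
  )
}

#' @export
print.nfkb_geometry <- function(x, ...) {
  cat("<nfkb_geometry> cell R =", x$cell_radius,
      "| nucleus R =", x$nucleus_radius,
      "| membrane shell =", x$membrane_thickness, "\n")
  invisible(x)
}

#' Cytoplasmic and nuclear volumes of a geometry
#' @param geometry an [cell_geometry()] object.
#' @return Named list with `cell`, `nucleus` and `cytoplasm` volumes.
#' @export
compartment_volumes <- function(geometry) {
  vc <- 4 / 3 * pi * geometry$cell_radius^3
  vn <- 4 / 3 * pi * geometry$nucleus_radius^3
  list(cell = vc, nucleus = vn, cytoplasm = vc - vn)
}

#' One Brownian displacement step
#'
#' Displaces each position by an isotropic Gaussian step with per-axis
#' variance `2 * D * dt`, the discrete-time realisation of Brownian motion:
#' the expected squared 3-D displacement is `6 * D * dt`.
#'
#' @param positions data frame with columns `x`, `y`, `z`.
#' @param D diffusion coefficient (length^2 / time), `>= 0`.
#' @param dt time step, `> 0`.
#' @return A tibble with displaced `x`, `y`, `z`.
#' @examples
#' p <- tibble::tibble(x = 0, y = 0, z = 0)
#' brownian_step(p, D = 1, dt = 0.5)
#' @export
brownian_step <- function(positions, D, dt) {
  stopifnot(is.data.frame(positions),
            all(c("x", "y", "z") %in% names(positions)))
  if (!is.numeric(D) || length(D) != 1 || is.na(D) || D < 0)
    stop("D must be a single non-negative number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || is.na(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  n <- nrow(positions)
  sdv <- sqrt(2 * D * dt)
  tibble::tibble(
    x = positions$x + rnorm(n, 0, sdv),
    y = positions$y + rnorm(n, 0, sdv),
    z = positions$z + rnorm(n, 0, sdv)
  )
}

#' Reflect positions that stepped beyond a compartment wall
#'
#' Mirrors the overshoot: a point that would land a distance `d` beyond the
#' wall is returned `d` inside it, along the radial direction.  Confinement
#' regions are radial bands: the whole cell (`"CELL"`), the cytoplasm
#' (`"CYTOPLASM"`, between nuclear envelope and cell wall) or the nucleus
#' (`"NUCLEUS"`).
#'
#' @param pos_old,pos_new data frames with `x`, `y`, `z`; `pos_old` must lie
#'   inside the confinement region.
#' @param geometry an [cell_geometry()] object.
#' @param confinement `"CELL"`, `"CYTOPLASM"` or `"NUCLEUS"`.
#' @return A tibble of positions, all inside the confinement region.
#' @export
reflect <- function(pos_old, pos_new, geometry,
                    confinement = c("CYTOPLASM", "NUCLEUS", "CELL")) {
  confinement <- match.arg(confinement)
  band <- switch(confinement,
    CELL = c(0, geometry$cell_radius),
    CYTOPLASM = c(geometry$nucleus_radius, geometry$cell_radius),
    NUCLEUS = c(0, geometry$nucleus_radius)
  )
  r_old <- sqrt(pos_old$x^2 + pos_old$y^2 + pos_old$z^2)
  eps <- 1e-9
  if (any(r_old < band[1] - eps | r_old > band[2] + eps))
    stop("pos_old lies outside the confinement region", call. = FALSE)
  x <- pos_new$x; y <- pos_new$y; z <- pos_new$z
  r <- sqrt(x^2 + y^2 + z^2)
  for (it in seq_len(8)) {
    out_hi <- r > band[2]
    out_lo <- r < band[1]
    if (!any(out_hi | out_lo)) break
    target <- r
    target[out_hi] <- 2 * band[2] - r[out_hi]
    target[out_lo] <- 2 * band[1] - r[out_lo]
    bad <- target < band[1] | target > band[2]
    target[bad] <- mean(band)
    f <- ifelse(r > 1e-12, target / r, 0)
    x <- x * f; y <- y * f; z <- z * f
    zero <- r <= 1e-12 & (out_lo | out_hi)
    z[zero] <- target[zero]
    r <- sqrt(x^2 + y^2 + z^2)
  }
  tibble::tibble(x = x, y = y, z = z)
}

#' Compartment label of positions
#'
#' Classifies positions by radial distance: within `membrane_thickness` of
#' the cell wall is `CELL_MEMBRANE`, within it of the nuclear envelope is
#' `NUCLEAR_MEMBRANE`, strictly inside the envelope is `NUCLEUS`, the rest
#' of the cell is `CYTOPLASM`.
#'
#' @inheritParams reflect
#' @param positions data frame with `x`, `y`, `z` columns, inside the cell.
#' @return Character vector of compartment labels.
#' @export
compartment_of <- function(positions, geometry) {
  r <- sqrt(positions$x^2 + positions$y^2 + positions$z^2)
  sh <- geometry$membrane_thickness
  if (any(r > geometry$cell_radius + sh / 2))
    stop("position outside the cell", call. = FALSE)
  dplyr::case_when(
    abs(r - geometry$cell_radius) <= sh / 2 ~ "CELL_MEMBRANE",
    abs(r - geometry$nucleus_radius) <= sh / 2 ~ "NUCLEAR_MEMBRANE",
    r < geometry$nucleus_radius ~ "NUCLEUS",
    TRUE ~ "CYTOPLASM"
  )
}

# uniform points on a sphere of radius r (Marsaglia normal trick)
.runif_sphere <- function(n, r) {
  if (n == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0)))
  m <- matrix(rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < 1e-12] <- 1
  tibble::tibble(x = r * m[, 1] / nrm, y = r * m[, 2] / nrm,
                 z = r * m[, 3] / nrm)
}

# uniform points in a radial band [r0, r1] (inverse-CDF on r^3)
.runif_shell_volume <- function(n, r0, r1) {
  if (n == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0)))
  u <- runif(n)
  r <- (r0^3 + u * (r1^3 - r0^3))^(1 / 3)
  p <- .runif_sphere(n, 1)
  tibble::tibble(x = p$x * r, y = p$y * r, z = p$z * r)
}

#' Place immobile agents on a membrane shell
#'
#' Draws `n` positions uniformly on the named spherical membrane.  Membrane
#' agents (receptors, nuclear transport receptors) never move afterwards.
#'
#' @param n number of positions.
#' @param which `"CELL_MEMBRANE"` or `"NUCLEAR_MEMBRANE"`.
#' @inheritParams reflect
#' @return Tibble of `n` positions with radial distance equal to the
#'   membrane radius.
#' @export
place_on_membrane <- function(n, which = c("CELL_MEMBRANE",
                                           "NUCLEAR_MEMBRANE"),
                              geometry) {
  which <- match.arg(which)
  stopifnot(n >= 0)
  r <- switch(which,
    CELL_MEMBRANE = geometry$cell_radius,
    NUCLEAR_MEMBRANE = geometry$nucleus_radius
  )
  .runif_sphere(n, r)
}

#' Place mobile agents uniformly inside a compartment
#'
#' @param n number of positions.
#' @param which `"CYTOPLASM"` or `"NUCLEUS"`.
#' @inheritParams reflect
#' @return Tibble of `n` positions.
#' @export
place_in_compartment <- function(n, which = c("CYTOPLASM", "NUCLEUS"),
                                 geometry) {
  which <- match.arg(which)
  stopifnot(n >= 0)
  if (which == "CYTOPLASM")
    .runif_shell_volume(n, geometry$nucleus_radius, geometry$cell_radius)
  else
    .runif_shell_volume(n, 0, geometry$nucleus_radius)
}
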