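test_that("brownian displacement follows the diffusion law", {
  set.seed(42)
  n <- 1e5
  p0 <- tibble::tibble(x = rep(0, n), y = 0, z = 0)
  D <- 1; dt <- 1
  p1 <- brownian_step(p0, D = D, dt = dt)
  msd <- mean(p1$x^2 + p1$y^2 + p1$z^2)
  expect_equal(msd, 6 * D * dt, tolerance = 0.02)
  expect_equal(var(p1$x), 2 * D * dt, tolerance = 0.02)
  expect_equal(var(p1$y), 2 * D * dt, tolerance = 0.02)
  # zero diffusion: identical positions
  expect_equal(brownian_step(p0, D = 0, dt = 1), p0)
  # parameter errors
  expect_error(brownian_step(p0, D = -1, dt = 1), "non-negative")
  expect_error(brownian_step(p0, D = 1, dt = 0), "positive")
})

test_that("reflection mirrors the overshoot and always stays inside", {
  geom <- cell_geometry(cell_radius = 10, nucleus_radius = 4)
  # 1-D analogue along x: wall at 10, move 9 -> 12 reflects to 8
  out <- reflect(tibble::tibble(x = 9, y = 0, z = 0),
                 tibble::tibble(x = 12, y = 0, z = 0), geom, "CELL")
  expect_equal(out$x, 8)
  # inside moves pass through unchanged
  inside <- tibble::tibble(x = 5, y = 1, z = 1)
  expect_equal(reflect(tibble::tibble(x = 6, y = 0, z = 0), inside,
                       geom, "CYTOPLASM"), inside)
  # pos_old outside the region is a consistency error
  expect_error(reflect(tibble::tibble(x = 1, y = 0, z = 0),
                       tibble::tibble(x = 5, y = 0, z = 0),
                       geom, "CYTOPLASM"), "outside")
  # brute-force containment: long random steps from random interior points
  set.seed(7)
  n <- 1e5
  old <- place_in_compartment(n, "CYTOPLASM", geom)
  prop <- brownian_step(old, D = 4, dt = 2)
  new <- reflect(old, prop, geom, "CYTOPLASM")
  r <- sqrt(new$x^2 + new$y^2 + new$z^2)
  expect_true(all(r >= geom$nucleus_radius - 1e-9))
  expect_true(all(r <= geom$cell_radius + 1e-9))
})

test_that("compartment labels agree with direct radial comparison", {
  geom <- cell_geometry()
  expect_equal(compartment_of(tibble::tibble(x = 0, y = 0, z = 1), geom),
               "NUCLEUS")
  expect_equal(compartment_of(tibble::tibble(x = 10, y = 0, z = 0), geom),
               "CELL_MEMBRANE")
  expect_error(compartment_of(tibble::tibble(x = 20, y = 0, z = 0), geom),
               "outside")
  set.seed(11)
  pts <- place_in_compartment(5e3, "CYTOPLASM", geom)
  pts <- dplyr::bind_rows(pts, place_in_compartment(5e3, "NUCLEUS", geom))
  lab <- compartment_of(pts, geom)
  r <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  sh <- geom$membrane_thickness / 2
  ref <- ifelse(abs(r - 10) <= sh, "CELL_MEMBRANE",
         ifelse(abs(r - 4) <= sh, "NUCLEAR_MEMBRANE",
         ifelse(r < 4, "NUCLEUS", "CYTOPLASM")))
  expect_identical(lab, ref)
})

test_that("membrane placement is on-shell and angularly uniform", {
  geom <- cell_geometry()
  expect_equal(nrow(place_on_membrane(0, "CELL_MEMBRANE", geom)), 0)
  set.seed(3)
  p <- place_on_membrane(1000, "NUCLEAR_MEMBRANE", geom)
  r <- sqrt(p$x^2 + p$y^2 + p$z^2)
  expect_true(all(abs(r - geom$nucleus_radius) < 1e-9))
  # octant uniformity by chi-square at alpha = 0.01
  oct <- paste(p$x > 0, p$y > 0, p$z > 0)
  counts <- table(factor(oct, levels = unique(paste(
    rep(c(TRUE, FALSE), each = 4),
    rep(rep(c(TRUE, FALSE), each = 2), 2), rep(c(TRUE, FALSE), 4)))))
  chi <- sum((counts - 125)^2 / 125)
  expect_lt(chi, qchisq(0.99, df = 7))
})
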