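test_that("a homogeneous elastic patch carries a uniform stress field", {
  cal <- synthetic_phantom_calibration()
  spec <- gen_voxel_cylinder(height = 3, diameter = 6, voxel = c(0.5, 0.25, 0.25),
                             bmd_field = 0.3, calibration = cal, seed = 1L)
  # full elements only: a true patch (partially weighted boundary elements
  # would make the lattice deliberately non-uniform)
  m <- build_model(spec, element_size = 1, hardening = "perfect",
                   min_fraction = 0.999)
  sol <- solve_compression(m, "confined", max_strain = 1e-3, n_increments = 1L)
  # confined homogeneous: exact uniform uniaxial-strain state everywhere
  card <- build_material_card(0.3, femoral_laws())
  nu <- 0.16
  # reaction = constrained stress x modelled cross-section (volume / height)
  area_model <- sum(m$fraction) * prod(m$h) / m$height
  expect_equal(tail(sol$curve$stress, 1L),
               card$E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)) * 1e-3 *
                 area_model / m$nominal_area,
               tolerance = 1e-8)
  # per-element energies equal up to the partial-volume weights
  dens <- sol$energy_element / m$fraction
  expect_lt(diff(range(dens)) / mean(dens), 1e-9)
})

test_that("a single element reproduces the material-point drivers", {
  card <- test_card(0.3, hardening = "trabecular")
  m <- single_element_model(card)
  for (mode in c("uniaxial", "confined")) {
    sol <- solve_compression(m, mode, max_strain = 0.05, n_increments = 25L)
    ref <- if (mode == "uniaxial") {
      run_uniaxial(card, max_strain = 0.05, n_steps = 25L)
    } else {
      run_confined(card, max_strain = 0.05, n_steps = 25L)
    }
    expect_equal(sol$curve$stress, ref$stress, tolerance = 5e-3)
    expect_lt(max(abs(sol$curve$stress - ref$stress) /
                    pmax(ref$stress, 1e-9)), 5e-3)
  }
  # comparator model too
  cs <- test_card(0.3, model = "svm", hardening = "svm")
  ms <- single_element_model(cs)
  sol <- solve_compression(ms, "uniaxial", max_strain = 0.05,
                           n_increments = 25L)
  ref <- run_uniaxial(cs, max_strain = 0.05, n_steps = 25L)
  expect_equal(sol$curve$stress, ref$stress, tolerance = 5e-3)
})

test_that("element counts scale with cross-section area and mesh size", {
  cal <- synthetic_phantom_calibration()
  spec <- gen_voxel_cylinder(bmd_field = 0.25, calibration = cal, seed = 1L)
  m1 <- build_model(spec, element_size = 1)
  m2 <- build_model(spec, element_size = 2)
  area <- pi * (11.65 / 2)^2
  # ~ area / h^2 columns x 12 / h layers; the partial boundary ring adds
  # some extra (fractionally weighted) elements
  expect_gt(nrow(m1$conn), area * 12)
  expect_lt(nrow(m1$conn), 1.3 * area * 12)
  expect_equal(nrow(m2$conn) / nrow(m1$conn), 1 / 8, tolerance = 0.35)
  # partial-volume weights reproduce the true cylinder volume closely
  expect_equal(sum(m1$fraction) * prod(m1$h), area * 12, tolerance = 5e-3)
  expect_equal(sum(m2$fraction) * prod(m2$h), area * 12, tolerance = 5e-3)
})

test_that("strain energy matches the closed form and the external work integral", {
  card <- test_card(0.3)
  m <- single_element_model(card, size = 2)
  sol <- solve_compression(m, "uniaxial", max_strain = 1e-3,
                           n_increments = 4L)
  sig <- card$E * 1e-3
  W_exact <- 0.5 * sig * 1e-3 * 8          # 1/2 sigma eps V, V = 8 mm^3
  expect_equal(sol$energy_total, W_exact, tolerance = 1e-6)
  expect_equal(strain_energy(m, sol), sol$energy_total)

  # doubling the volume doubles the energy
  m2 <- single_element_model(card, size = 2 * 2^(1 / 3))
  sol2 <- solve_compression(m2, "uniaxial", max_strain = 1e-3,
                            n_increments = 4L)
  expect_equal(sol2$energy_total / sol$energy_total, 2, tolerance = 1e-6)

  # elastoplastic run: energy equals the increment-wise external work
  card3 <- test_card(0.2, hardening = "trabecular")
  m3 <- single_element_model(card3)
  sol3 <- solve_compression(m3, "uniaxial", max_strain = 0.04,
                            n_increments = 40L)
  F <- -sol3$reactions$R_top                        # compressive force
  du <- diff(seq(0, 0.04, length.out = 41L))        # height 1 mm
  W_ext <- sum((F + c(0, F[-40L])) / 2 * du)
  expect_equal(sol3$energy_total, W_ext, tolerance = 1e-2)
})

test_that("reactions balance at every converged increment", {
  cal <- synthetic_phantom_calibration()
  spec <- gen_voxel_cylinder(height = 6, diameter = 6, voxel = c(0.5, 0.25, 0.25),
                             bmd_field = gen_smooth_bmd_field(seed = 3L),
                             calibration = cal, seed = 3L)
  m <- build_model(spec, element_size = 1.5, hardening = "trabecular")
  sol <- solve_compression(m, "uniaxial", max_strain = 0.02,
                           n_increments = 6L)
  bal <- abs(sol$reactions$R_top + sol$reactions$R_bottom) /
    abs(sol$reactions$R_top)
  expect_lt(max(bal), 1e-6)
})

test_that("plastic strain localizes in a weak band", {
  cal <- synthetic_phantom_calibration()
  # a soft low-density band at mid-height of an otherwise uniform cylinder
  band <- function(x, y, z) ifelse(abs(z) < 1, 0.12, 0.30)
  spec <- gen_voxel_cylinder(height = 9, diameter = 6, voxel = c(0.5, 0.25, 0.25),
                             bmd_field = band, calibration = cal, seed = 4L)
  m <- build_model(spec, element_size = 1.5, hardening = "perfect")
  sol <- solve_compression(m, "uniaxial", max_strain = 0.02,
                           n_increments = 8L)
  zc <- (m$nodes[m$conn[, 1L], 3L] + m$nodes[m$conn[, 5L], 3L]) / 2
  worst <- which.max(sol$eps_field)
  expect_lt(abs(zc[worst]), 1.0)                       # max EPS inside the band
  in_band <- abs(zc) < 1.0
  expect_gt(mean(sol$eps_field[in_band]), 10 * mean(sol$eps_field[!in_band]))
})

test_that("mesh refinement converges in total strain energy", {
  # the FE convergence study: one seeded heterogeneous cylinder compressed
  # to 1% nominal strain on three meshes; energies agree pairwise within 10%
  cal <- synthetic_phantom_calibration()
  spec <- gen_voxel_cylinder(bmd_field = gen_smooth_bmd_field(seed = 101L),
                             calibration = cal, seed = 101L)
  en <- vapply(c(1, 1.5, 2), function(h) {
    m <- build_model(spec, element_size = h, hardening = "trabecular")
    solve_compression(m, "uniaxial", max_strain = 0.01,
                      n_increments = 5L)$energy_total
  }, 0)
  pairs <- utils::combn(3L, 2L)
  rel <- apply(pairs, 2L, function(ij) {
    abs(en[ij[1L]] - en[ij[2L]]) / mean(en[ij])
  })
  expect_lt(max(rel), 0.10)
})

test_that("EPS fields export as readable legacy VTK", {
  card <- test_card(0.2, hardening = "trabecular")
  m <- single_element_model(card)
  sol <- solve_compression(m, "uniaxial", max_strain = 0.04,
                           n_increments = 10L)
  tmp <- file.path(tempdir(), "eps_test.vtk")
  write_vtk_field(m, sol$eps_field, tmp)
  lines <- readLines(tmp)
  expect_identical(lines[1L], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 8 double", lines)))
  expect_true(any(grepl("^SCALARS EPS double 1", lines)))
  expect_equal(as.numeric(lines[length(lines)]), sol$eps_field[1L],
               tolerance = 1e-6)
  unlink(tmp)
})
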