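test_that("phantom calibration recovers exact and noisy lines", {
  # exact linear data
  cal <- fit_hu_calibration(c(0, 50, 100, 200), c(10, 60, 110, 210))
  expect_equal(cal$slope, 1.0, tolerance = 1e-12)
  expect_equal(cal$intercept, -10, tolerance = 1e-10)

  # two-point line
  cal2 <- fit_hu_calibration(c(0, 200), c(0, 400))
  expect_equal(cal2$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal2$intercept, 0, tolerance = 1e-12)

  # noisy data against an independent normal-equation solve
  set.seed(11)
  dens <- c(0, 50, 100, 200)
  hu <- 2 * dens + 5 + rnorm(4, 0, 1)
  cal3 <- fit_hu_calibration(dens, hu)
  X <- cbind(1, hu)
  beta <- solve(t(X) %*% X, t(X) %*% dens)
  expect_equal(cal3$intercept, beta[1L], tolerance = 1e-9)
  expect_equal(cal3$slope, beta[2L], tolerance = 1e-9)

  expect_error(fit_hu_calibration(c(0, 50, 100), c(40, 40, 40)),
               "degenerate")
})

test_that("hu_to_bmd is affine up to the floor clamp and hits calibration points", {
  cal <- fit_hu_calibration(c(0, 50, 100, 200), c(5, 67.5, 130, 255))
  hu200 <- 255
  expect_equal(hu_to_bmd(hu200, cal), 0.200, tolerance = 1e-9)
  # below the 0 mg/ml insert: clamped to the floor
  expect_equal(hu_to_bmd(-500, cal), 0.001)
  # mid-range value on the fitted line
  expect_equal(hu_to_bmd(100, cal),
               (cal$slope * 100 + cal$intercept) / 1000, tolerance = 1e-12)
  # affinity before clamping
  h1 <- 80; h2 <- 240; lam <- 0.3
  expect_equal(hu_to_bmd(lam * h1 + (1 - lam) * h2, cal),
               lam * hu_to_bmd(h1, cal) + (1 - lam) * hu_to_bmd(h2, cal),
               tolerance = 1e-12)
})

test_that("piecewise K law matches its printed clamps and is continuous", {
  expect_equal(k_of_bmd(0.05), 2.993)
  expect_equal(k_of_bmd(1.20), 1.383)
  expect_equal(k_of_bmd(0.30), 1.361 * 0.30^-0.312, tolerance = 1e-12)
  laws <- femoral_laws()
  # power branch meets the clamps to 3 decimals at both breakpoints
  expect_lt(abs(eval_power_law(laws$k_law, 0.08) - 2.993), 5e-4)
  expect_lt(abs(eval_power_law(laws$k_law, 0.950) - 1.383), 5e-4)
  expect_lt(abs(k_of_bmd(0.08 - 1e-9) - k_of_bmd(0.08 + 1e-9)), 5e-4)
  expect_lt(abs(k_of_bmd(0.950 - 1e-9) - k_of_bmd(0.950 + 1e-9)), 5e-4)
  expect_error(k_of_bmd(-0.1), "positive")
  # an inconsistent clamp is rejected at construction
  expect_error(material_law_set(stiffness = power_law(100, 2),
                                yield = power_law(10, 1.5),
                                k_law = power_law(1.361, -0.312),
                                k_low = 2.5),
               "continuous")
})

test_that("stiffness and yield mappings evaluate both fit styles and branches", {
  lc <- femoral_laws("continuous"); ld <- femoral_laws("discontinuous")
  expect_equal(stiffness_of_bmd(1.0, lc), 12980)
  expect_equal(yield_of_bmd(1.0, lc), 109.3)
  expect_equal(stiffness_of_bmd(1.0, ld), 13750)
  expect_equal(yield_of_bmd(1.0, ld), 111.5)
  expect_equal(stiffness_of_bmd(1.0, ld, branch = "trabecular"), 5113)
  expect_equal(yield_of_bmd(1.0, ld, branch = "trabecular"), 79.36)
  expect_equal(stiffness_of_bmd(0.2, lc), 12980 * 0.2^2.567, tolerance = 1e-12)
  expect_equal(yield_of_bmd(0.2, lc), 109.3 * 0.2^1.872, tolerance = 1e-12)
  expect_error(stiffness_of_bmd(0.5, lc, branch = "trabecular"),
               "discontinuous")

  # strictly increasing on each branch; jump at the break only for the
  # discontinuous style
  grid <- seq(0.05, 1.4, by = 0.01)
  expect_true(all(diff(stiffness_of_bmd(grid, lc)) > 0))
  expect_true(all(diff(yield_of_bmd(grid, lc)) > 0))
  tg <- seq(0.05, 0.95, by = 0.01); cg <- seq(0.951, 1.4, by = 0.01)
  expect_true(all(diff(stiffness_of_bmd(tg, ld)) > 0))
  expect_true(all(diff(stiffness_of_bmd(cg, ld)) > 0))
  eps <- 1e-9
  jump_d <- stiffness_of_bmd(0.950 + eps, ld) - stiffness_of_bmd(0.950 - eps, ld)
  jump_c <- stiffness_of_bmd(0.950 + eps, lc) - stiffness_of_bmd(0.950 - eps, lc)
  expect_gt(abs(jump_d), 1000)          # discontinuous: a real jump (MPa)
  expect_lt(abs(jump_c), 1e-3)          # continuous: smooth
})

test_that("nu_p formula covers its limits and domain", {
  expect_equal(nu_p_of_k(1e-9), 0.5, tolerance = 1e-6)
  expect_equal(nu_p_of_k(sqrt(3)), 0, tolerance = 1e-12)
  expect_equal(nu_p_of_k(1.383), (3 - 1.383^2) / 6, tolerance = 1e-12)
  expect_error(nu_p_of_k(3.2), "\\(0, 3\\)")
  expect_error(nu_p_of_k(0), "\\(0, 3\\)")
})

test_that("material cards satisfy their defining identities", {
  ld <- femoral_laws("discontinuous")
  card <- build_material_card(1.2, ld)
  expect_equal(card$K, 1.383)
  expect_equal(card$p_y_hyd, card$sigma_y_uni / 1.383, tolerance = 1e-12)
  for (b in c(0.06, 0.3, 0.7, 1.1)) {
    cd <- build_material_card(b, ld)
    expect_equal(cd$sigma_y_uni / cd$p_y_hyd, cd$K, tolerance = 1e-9)
    expect_equal(cd$nu_p, (3 - cd$K^2) / 6, tolerance = 1e-9)
    expect_identical(cd$nu_e, 0.16)
  }
  # hand evaluation of every mapped field at bmd = 0.3, continuous fit
  lc <- femoral_laws("continuous")
  c3 <- build_material_card(0.3, lc)
  expect_equal(c3$E, 12980 * 0.3^2.567, tolerance = 1e-12)
  expect_equal(c3$sigma_y_uni, 109.3 * 0.3^1.872, tolerance = 1e-12)
  expect_equal(c3$K, 1.361 * 0.3^-0.312, tolerance = 1e-12)
  expect_error(material_card(E = -1, sigma_y = 5, K = 1), "E must be positive")
  expect_error(material_card(E = 100, sigma_y = 5, K = 3.5), "\\(0, 3\\)")
})

test_that("law sets, cards and calibrations survive JSON round trips", {
  tmp <- tempfile(fileext = ".json")
  for (fit in c("continuous", "discontinuous")) {
    laws <- femoral_laws(fit)
    write_law_set(laws, tmp)
    back <- read_law_set(tmp)
    expect_equal(stiffness_of_bmd(0.37, back), stiffness_of_bmd(0.37, laws))
    expect_equal(k_of_bmd(0.37, back), k_of_bmd(0.37, laws))
  }
  card <- build_material_card(0.25, femoral_laws(), hardening = "trabecular")
  write_material_card(card, tmp)
  back <- read_material_card(tmp)
  expect_equal(back$p_y_hyd, card$p_y_hyd)
  expect_equal(back$hardening$sigma_c, card$hardening$sigma_c)
  cal <- fit_hu_calibration(c(0, 50, 100, 200), c(5, 67.5, 130, 255))
  write_calibration(cal, tmp)
  expect_equal(read_calibration(tmp)$slope, cal$slope)
  unlink(tmp)
})

test_that("map_volume averages BMD over the mask and maps per-voxel cards", {
  cal <- synthetic_phantom_calibration()
  # uniform volume at the 100 mg/ml insert's HU
  spec <- gen_voxel_cylinder(height = 4, diameter = 4, voxel = c(1, 0.5, 0.5),
                             bmd_field = 0.100, calibration = cal)
  mv <- map_volume(spec, cal)
  expect_equal(mv$mean_bmd, 0.100, tolerance = 1e-9)
  inmask <- mv$cards$E[spec$mask]
  expect_true(all(abs(inmask - inmask[1L]) < 1e-9))

  # two-voxel arithmetic mean
  spec2 <- spec
  spec2$mask[] <- FALSE
  spec2$mask[c(1L, 2L)] <- TRUE
  spec2$hu[1L] <- bmd_to_hu(0.1, cal)
  spec2$hu[2L] <- bmd_to_hu(0.3, cal)
  expect_equal(map_volume(spec2, cal)$mean_bmd, 0.2, tolerance = 1e-9)

  # radial gradient: mean matches the analytic area average of the field
  grad <- function(x, y, z) 0.1 + 0.2 * sqrt(x^2 + y^2) / 6
  spec3 <- gen_voxel_cylinder(height = 6, diameter = 12,
                              voxel = c(0.5, 0.25, 0.25), bmd_field = grad,
                              calibration = cal)
  # area average of 0.1 + 0.2 r / 6 over a disc of radius 6: 0.1 + 0.2*2/3
  expect_equal(map_volume(spec3, cal)$mean_bmd, 0.1 + 0.2 * 2 / 3,
               tolerance = 0.01)
  spec3$mask[] <- FALSE
  expect_error(map_volume(spec3, cal), "empty")
})
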