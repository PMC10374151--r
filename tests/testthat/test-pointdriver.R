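test_that("uniaxial driver reproduces Hooke's law and the elastic Poisson ratio", {
  card <- test_card(0.3)
  cu <- run_uniaxial(card, max_strain = 0.01, n_steps = 50)
  # elastic slope
  slope <- (cu$stress[6L] - cu$stress[2L]) / (cu$strain[6L] - cu$strain[2L])
  expect_equal(slope, card$E, tolerance = 1e-3)
  # lateral/axial strain ratio = -nu_e (internal signs: lateral positive)
  h <- attr(cu, "history")
  expect_equal(h$eps_lat[10L] / cu$strain[10L], 0.16, tolerance = 1e-6)
})

test_that("uniaxial plastic flow reproduces the plastic Poisson ratio from the surface", {
  # ties the ellipse + associated flow to the printed (3 - K^2)/6 formula
  for (K in c(0.8, 1.383, 2.5)) {
    card <- material_card(E = 1000, sigma_y = 10, K = K, hardening = "perfect")
    cu <- run_uniaxial(card, max_strain = 0.10, n_steps = 100, lat_tol = 1e-12)
    h <- attr(cu, "history")
    n <- nrow(h)
    ratio <- (h$eps_p_trans[n] - h$eps_p_trans[n - 10L]) /
      (h$eps_p_axial[n] - h$eps_p_axial[n - 10L])
    expect_equal(ratio, -(3 - K^2) / 6, tolerance = 1e-6)
  }
})

test_that("confined driver gives the constrained modulus and decouples at nu = 0", {
  card <- test_card(0.3)
  cc <- run_confined(card, max_strain = 0.01, n_steps = 50)
  slope <- (cc$stress[4L] - cc$stress[2L]) / (cc$strain[4L] - cc$strain[2L])
  nu <- 0.16
  expect_equal(slope, card$E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)),
               tolerance = 1e-8)
  expect_equal(slope / card$E, 1.0649, tolerance = 1e-4)

  card0 <- material_card(E = 500, sigma_y = 8, K = 1.5, nu_e = 0,
                         hardening = "perfect")
  c1 <- run_uniaxial(card0, max_strain = 0.005, n_steps = 20)
  c2 <- run_confined(card0, max_strain = 0.005, n_steps = 20)
  expect_equal(c1$stress, c2$stress, tolerance = 1e-9)
})

test_that("offset yield handles bilinear, elastic-only and simulated curves", {
  # ideal bilinear curve: E = 1000, plateau 10 -> crossing at eps = 0.012
  eps <- seq(0, 0.03, length.out = 301L)
  sig <- pmin(1000 * eps, 10)
  bl <- stress_strain_curve(eps, sig)
  oy <- offset_yield(bl)
  expect_equal(oy$E, 1000, tolerance = 1e-6)
  expect_equal(oy$sigma_y, 10, tolerance = 1e-6)
  expect_equal(oy$eps_y, 0.012, tolerance = 1e-6)

  # purely elastic curve: no-yield condition
  el <- stress_strain_curve(eps, 1000 * eps)
  expect_error(offset_yield(el), class = "bonefoam_no_yield")

  # round trip through the integrator across BMD and both fit styles
  # (the continuous laws at low BMD yield only near 7% strain, so the
  # curves run deeper than the usual reduction window)
  for (fit in c("continuous", "discontinuous")) {
    for (b in c(0.05, 0.2, 0.7, 1.2)) {
      # trabecular template in its measured range; the steep cortical
      # softening template shifts the offset crossing by its own -2%, so
      # the driver/reduction loop is checked against perfect plasticity
      # there
      card <- build_material_card(b, femoral_laws(fit),
                                  hardening = if (b <= 0.95) "trabecular"
                                              else "perfect")
      cu <- run_uniaxial(card, max_strain = 0.12, n_steps = 480)
      oy <- offset_yield(cu)
      expect_equal(oy$E, card$E, tolerance = 2e-2)
      expect_equal(oy$sigma_y, card$sigma_y_uni, tolerance = 2e-2)
    }
  }
})

test_that("hydrostatic conversion follows the elastic lateral-stress relation", {
  expect_equal(confined_to_hydrostatic(9, 0), 3, tolerance = 1e-12)
  expect_equal(confined_to_hydrostatic(10, 0.4999), 10, tolerance = 1e-3)
  expect_equal(confined_to_hydrostatic(10, 0.16), 10 * 1.16 / (3 * 0.84),
               tolerance = 1e-12)
  expect_equal(confined_to_hydrostatic(10, 0.16), 4.603, tolerance = 1e-4)
  expect_error(confined_to_hydrostatic(10, 0.5), "0.5")
})

test_that("DIC Poisson estimation recovers exact, zero and noisy ratios", {
  ax <- seq(-0.001, -0.01, length.out = 20L)
  expect_equal(dic_poisson(ax, -0.16 * ax), 0.16, tolerance = 1e-12)
  expect_equal(dic_poisson(ax, rep(0, 20L)), 0, tolerance = 1e-12)
  set.seed(5)
  tr <- -0.3 * ax + rnorm(20L, 0, 1e-5)
  fit <- stats::lm(tr ~ ax)
  se <- summary(fit)$coefficients[2L, 2L]
  expect_lt(abs(dic_poisson(ax, tr) - 0.3), 3 * se)
  expect_error(dic_poisson(ax[1:2], tr[1:2]), ">= 3")
})

test_that("confined round trip recovers the hydrostatic yield where the conversion is valid", {
  # the elastic hydrostatic conversion is the testing protocol's own
  # approximation: exact only where the loading ray meets the cap nearly
  # head-on (high K). Assert 5% recovery in the mid-trabecular regime and
  # bound the protocol bias across the whole trabecular range.
  for (b in c(0.14, 0.16, 0.18)) {
    card <- build_material_card(b, femoral_laws("discontinuous"),
                                hardening = "trabecular")
    cc <- run_confined(card, max_strain = 0.06, n_steps = 240)
    py <- confined_to_hydrostatic(offset_yield(cc)$sigma_y, 0.16)
    expect_equal(py, card$p_y_hyd, tolerance = 5e-2)
  }
  for (b in c(0.06, 0.30, 0.40)) {
    card <- build_material_card(b, femoral_laws("discontinuous"),
                                hardening = "trabecular")
    cc <- run_confined(card, max_strain = 0.06, n_steps = 240)
    py <- confined_to_hydrostatic(offset_yield(cc)$sigma_y, 0.16)
    expect_gt(py / card$p_y_hyd, 0.75)
    expect_lt(py / card$p_y_hyd, 1.20)
  }
})

test_that("confined compression separates the foam model from the von Mises comparator", {
  # the pressure term caps the foam response; the comparator, blind to
  # pressure, keeps stiffening (the confined overprediction mechanism)
  b <- 0.2083
  icf <- build_material_card(b, femoral_laws("discontinuous"),
                             hardening = "trabecular")
  svm <- material_card(bmd = b, E = icf$E, sigma_y = icf$sigma_y_uni,
                       model = "svm", hardening = "svm")
  ci <- run_confined(icf, max_strain = 0.5, n_steps = 250)
  cs <- run_confined(svm, max_strain = 0.5, n_steps = 250)
  s_icf <- max(ci$stress); s_svm <- max(cs$stress)
  expect_gt(s_svm / icf$sigma_y_uni, 5)               # > 5x its yield stress
  expect_lt(s_icf / icf$sigma_y_uni, 10)              # within one order
  expect_gt(s_svm, s_icf)                             # ordering sVM >> ICF
  # once its deviator has saturated, the comparator keeps stiffening
  # monotonically — it has no mechanism to cap the confined response
  late <- cs$stress[cs$strain > 0.35]
  expect_true(all(diff(late) > 0))
})

test_that("curves survive a CSV round trip with their sidecar", {
  card <- test_card(0.25, hardening = "trabecular")
  cu <- run_uniaxial(card, max_strain = 0.02, n_steps = 30)
  tmp <- file.path(tempdir(), "curve_test.csv")
  write_curve_csv(cu, tmp)
  back <- read_curve_csv(tmp)
  expect_equal(back$stress, cu$stress)
  expect_identical(attr(back, "mode"), "uniaxial")
  unlink(c(tmp, paste0(tmp, ".json")))
})
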