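# Brute-force closest-point projection onto the crushable-foam ellipse in
# (p, q) space, minimizing the elastic-energy-norm distance
#   (p - p_tr)^2 / (2 Kb)  +  (q - q_tr)^2 / (6 G)
# over the parameterized surface (p, q) = (B/alpha cos t, B sin t), t in
# [0, pi]. Independent of the return-mapping implementation: coarse grid
# scan followed by golden-section refinement.
oracle_closest_point <- function(p_tr, q_tr, K, sigma_c, G, Kb) {
  alpha <- 3 * K / sqrt(9 - K^2)
  B <- sigma_c * sqrt(1 + alpha^2 / 9)
  phi <- function(t) {
    (B / alpha * cos(t) - p_tr)^2 / (2 * Kb) +
      (B * sin(t) - q_tr)^2 / (6 * G)
  }
  ts <- seq(0, pi, length.out = 2001L)
  i <- which.min(vapply(ts, phi, 0))
  op <- stats::optimize(phi, c(ts[max(1L, i - 1L)], ts[min(2001L, i + 1L)]),
                        tol = 1e-14)
  t <- op$minimum
  c(p = B / alpha * cos(t), q = B * sin(t))
}

elastic_gk <- function(card) {
  list(G = card$E / (2 * (1 + card$nu_e)),
       Kb = card$E / (3 * (1 - 2 * card$nu_e)))
}

# deterministic test card
test_card <- function(bmd = 0.3, fit = "discontinuous", hardening = "perfect",
                      model = "icf") {
  laws <- femoral_laws(fit)
  if (model == "svm") {
    material_card(bmd = bmd, E = stiffness_of_bmd(bmd, laws),
                  sigma_y = yield_of_bmd(bmd, laws), model = "svm",
                  hardening = if (identical(hardening, "perfect")) "perfect" else "svm")
  } else {
    material_card(bmd = bmd, E = stiffness_of_bmd(bmd, laws),
                  sigma_y = yield_of_bmd(bmd, laws), K = k_of_bmd(bmd, laws),
                  hardening = hardening)
  }
}
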