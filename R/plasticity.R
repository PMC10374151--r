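## Voigt convention used throughout: (11, 22, 33, 12, 13, 23).
## Stress components are tensorial; strain vectors carry engineering shears
## (gamma = 2 * eps_ij), so sigma . eps is the correct work product.
## Tensors keep the continuum tension-positive sign; the pressure invariant
## p = -tr(sigma)/3 is compression-positive.

.voigt6 <- function(x, what = "tensor") {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3L, 3L))) stop("expected a 3x3 matrix", call. = FALSE)
    if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x)))) {
      stop(sprintf("%s must be symmetric", what), call. = FALSE)
    }
    c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[1, 3], x[2, 3])
  } else {
    stopifnot(is.numeric(x), length(x) == 6L)
    as.numeric(x)
  }
}

#' Pressure and von Mises invariants of a stress tensor
#'
#' `p = -tr(sigma)/3` (positive in hydrostatic compression) and
#' `q = sqrt(3/2 s:s)` with `s` the stress deviator.
#'
#' @param sigma symmetric 3x3 stress matrix or length-6 Voigt vector
#'   (11, 22, 33, 12, 13, 23), MPa.
#' @return named numeric vector `c(p = , q = )`, MPa.
#' @export
pq_invariants <- function(sigma) {
  sv <- .voigt6(sigma, "stress")
  p <- -(sv[1] + sv[2] + sv[3]) / 3
  s <- sv[1:3] + p
  q2 <- 1.5 * sum(s^2) + 3 * sum(sv[4:6]^2)
  c(p = p, q = sqrt(max(q2, 0)))
}

#' Ellipse shape factor of the crushable-foam yield surface
#'
#' The yield surface `F = sqrt(q^2 + alpha^2 p^2) - B` passes through the
#' uniaxial point `(p, q) = (sigma_c/3, sigma_c)` and the hydrostatic point
#' `(B/alpha, 0)` when `alpha = 3K / sqrt(9 - K^2)`; associated flow on this
#' surface reproduces the plastic Poisson's ratio `(3 - K^2)/6`.
#'
#' @param K strength ratio in (0, 3); the ellipse degenerates at K = 3.
#' @return dimensionless shape factor alpha.
#' @export
alpha_of_k <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0) || any(K >= 3)) {
    stop("strength ratio K must lie in (0, 3)", call. = FALSE)
  }
  3 * K / sqrt(9 - K^2)
}

#' Crushable-foam yield surface at a given hardening state
#'
#' @param K strength ratio in (0, 3).
#' @param sigma_c current uniaxial yield stress, MPa (> 0).
#' @return list with `alpha`, `B` (surface size, MPa; `B = sigma_c *
#'   sqrt(1 + alpha^2/9)`), and `K`, of class `yield_surface_icf`.
#' @export
yield_surface_icf <- function(K, sigma_c) {
  alpha <- alpha_of_k(K)
  stopifnot(is.numeric(sigma_c), sigma_c > 0)
  structure(list(alpha = alpha, B = sigma_c * sqrt(1 + alpha^2 / 9), K = K),
            class = "yield_surface_icf")
}

#' Yield function value
#'
#' `F = sqrt(q^2 + alpha^2 p^2) - B`; negative inside the elastic domain,
#' zero on the surface.
#'
#' @param p,q stress invariants, MPa.
#' @param surface a [yield_surface_icf()].
#' @return F, MPa.
#' @export
yield_value <- function(p, q, surface) {
  stopifnot(inherits(surface, "yield_surface_icf"))
  sqrt(q^2 + surface$alpha^2 * p^2) - surface$B
}

#' Fresh plastic state for one material point
#'
#' Carries the total strain, plastic strain (both Voigt, engineering shears),
#' the scalar hardening variable (equivalent plastic strain, defined through
#' plastic dissipation: `sigma : deps_p = sigma_c * deps_bar`, which in
#' uniaxial compression equals the axial plastic strain), and the last
#' converged stress.
#'
#' @return object of class `plastic_state`.
#' @export
plastic_state <- function() {
  structure(list(eps = numeric(6), eps_p = numeric(6), eps_bar_p = 0,
                 sigma = numeric(6), yielded = FALSE),
            class = "plastic_state")
}

.elastic_constants <- function(card) {
  list(G = card$E / (2 * (1 + card$nu_e)),
       Kb = card$E / (3 * (1 - 2 * card$nu_e)))
}

.stress_from_elastic <- function(ee, G, Kb) {
  tr <- ee[1] + ee[2] + ee[3]
  sig <- numeric(6)
  sig[1:3] <- 2 * G * ee[1:3] + (Kb - 2 * G / 3) * tr
  sig[4:6] <- G * ee[4:6]
  sig
}

.elastic_from_stress <- function(sig, G, Kb) {
  p <- -(sig[1] + sig[2] + sig[3]) / 3
  ee <- numeric(6)
  ee[1:3] <- (sig[1:3] + p) / (2 * G) - p / (3 * Kb)
  ee[4:6] <- sig[4:6] / G
  ee
}

## Safeguarded scalar root finder (Illinois variant of regula falsi) on a
## bracket [lo, hi] with f(lo) > 0 > f(hi). Converges superlinearly without
## derivatives; used for the plastic-multiplier equations.
.illinois <- function(f, lo, hi, flo, fhi, tol_f, max_iter = 200L) {
  side <- 0L
  x <- hi; fx <- fhi
  for (i in seq_len(max_iter)) {
    x <- (flo * hi - fhi * lo) / (flo - fhi)
    if (!is.finite(x)) x <- (lo + hi) / 2
    fx <- f(x)
    if (abs(fx) <= tol_f) return(list(root = x, f = fx, iter = i))
    if (fx > 0) {
      lo <- x; flo <- fx
      if (side == -1L) fhi <- fhi / 2
      side <- -1L
    } else {
      hi <- x; fhi <- fx
      if (side == 1L) flo <- flo / 2
      side <- 1L
    }
    if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
      return(list(root = x, f = fx, iter = i))
    }
  }
  list(root = x, f = fx, iter = max_iter, converged = FALSE)
}

.integrator_error <- function(msg, p_tr, q_tr, resid) {
  stop(structure(class = c("bonefoam_integrator_error", "error", "condition"),
                 list(message = sprintf(
                   "%s (trial p = %.6g, q = %.6g, last residual = %.3g)",
                   msg, p_tr, q_tr, resid), call = NULL)))
}

#' Crushable-foam stress update (return mapping)
#'
#' Strain-driven elastoplastic update for the isotropic crushable foam model.
#' The elastic trial stress is computed with isotropic elasticity; if it lies
#' outside the current yield ellipse, an associated-flow return mapping pulls
#' it back to the surface (`|F| <= tol * B`), updating the hardening variable
#' consistently with plastic dissipation. With isotropic elasticity the
#' return is the closest-point projection onto the ellipse in the
#' elastic-energy norm. Hardening and softening branches of the card's
#' [hardening_curve()] are both honoured. On non-convergence the strain
#' increment is bisected (substepping, depth up to 10) before an integrator
#' error with trial-state diagnostics is raised.
#'
#' @param deps strain increment, Voigt with engineering shears
#'   (tension-positive).
#' @param state a [plastic_state()].
#' @param card an icf [material_card()].
#' @param tol relative tolerance on the yield residual.
#' @param max_depth maximum substepping depth.
#' @return list with `sigma` (Voigt stress, MPa), `state` (updated
#'   [plastic_state()]), and `plastic` (logical).
#' @export
icf_return_map <- function(deps, state, card, tol = 1e-10, max_depth = 10L) {
  stopifnot(inherits(state, "plastic_state"), inherits(card, "material_card"))
  if (card$model != "icf") stop("card model must be 'icf'", call. = FALSE)
  .icf_step(as.numeric(deps), state, card, tol, max_depth)
}

.icf_step <- function(deps, state, card, tol, depth) {
  ec <- .elastic_constants(card)
  G <- ec$G; Kb <- ec$Kb
  K <- card$K
  alpha2 <- 9 * K^2 / (9 - K^2)
  cB <- 3 / sqrt(9 - K^2)          # B = cB * sigma_c
  h <- card$hardening

  eps_new <- state$eps + deps
  ee_tr <- eps_new - state$eps_p
  sig_tr <- .stress_from_elastic(ee_tr, G, Kb)
  p_tr <- -(sig_tr[1] + sig_tr[2] + sig_tr[3]) / 3
  s_tr <- sig_tr
  s_tr[1:3] <- s_tr[1:3] + p_tr
  q_tr <- sqrt(max(1.5 * sum(s_tr[1:3]^2) + 3 * sum(s_tr[4:6]^2), 0))

  eb0 <- state$eps_bar_p
  sc0 <- sigma_c_at(h, eb0)
  B0 <- cB * sc0
  g_tr <- sqrt(q_tr^2 + alpha2 * p_tr^2)

  if (g_tr <= B0 * (1 + tol)) {
    state$eps <- eps_new
    state$sigma <- sig_tr
    return(list(sigma = sig_tr, state = state, plastic = FALSE))
  }

  ## Unknown: increment of the hardening variable de. On the solution the
  ## stress sits on the surface (g = B), so the flow magnitude is
  ## m = de * sigma_c / B^2, and the trial invariants relax as
  ## q = q_tr / (1 + 3 G m), p = p_tr / (1 + Kb alpha^2 m).
  resid <- function(de) {
    sc <- sigma_c_at(h, eb0 + de)
    B <- cB * sc
    m <- de * sc / B^2
    q <- q_tr / (1 + 3 * G * m)
    p <- p_tr / (1 + Kb * alpha2 * m)
    sqrt(q^2 + alpha2 * p^2) - B
  }

  tol_f <- tol * B0
  hi <- (g_tr - B0) / (3 * G + Kb * alpha2) * cB^2 + 1e-16
  fhi <- resid(hi)
  n_dbl <- 0L
  while (fhi > 0 && n_dbl < 80L) {
    hi <- hi * 2
    fhi <- resid(hi)
    n_dbl <- n_dbl + 1L
  }
  if (fhi > 0) {
    if (depth > 0L) return(.icf_substep(deps, state, card, tol, depth))
    .integrator_error("crushable-foam return mapping failed to bracket",
                      p_tr, q_tr, fhi)
  }
  sol <- .illinois(resid, 0, hi, g_tr - B0, fhi, tol_f)
  if (!is.null(sol$converged) && !sol$converged) {
    if (depth > 0L) return(.icf_substep(deps, state, card, tol, depth))
    .integrator_error("crushable-foam return mapping did not converge",
                      p_tr, q_tr, sol$f)
  }
  de <- sol$root
  sc <- sigma_c_at(h, eb0 + de)
  B <- cB * sc
  m <- de * sc / B^2
  s <- s_tr / (1 + 3 * G * m)
  p <- p_tr / (1 + Kb * alpha2 * m)
  sig <- s
  sig[1:3] <- sig[1:3] - p

  state$eps <- eps_new
  state$eps_p <- eps_new - .elastic_from_stress(sig, G, Kb)
  state$eps_bar_p <- eb0 + de
  state$sigma <- sig
  state$yielded <- TRUE
  list(sigma = sig, state = state, plastic = TRUE)
}

.icf_substep <- function(deps, state, card, tol, depth) {
  half <- deps / 2
  r1 <- .icf_step(half, state, card, tol, depth - 1L)
  .icf_step(half, r1$state, card, tol, depth - 1L)
}

#' Softening von Mises stress update (radial return)
#'
#' J2 plasticity with a piecewise-linear effective stress-strain law (yield,
#' softening modulus, residual plateau — the card's `"svm"` hardening
#' template by default). The update is a standard radial return in the
#' deviatoric plane; the pressure is untouched, so the model never yields
#' under hydrostatic load.
#'
#' @inheritParams icf_return_map
#' @param card an svm [material_card()].
#' @return list with `sigma`, `state`, `plastic` as [icf_return_map()].
#' @export
svm_update <- function(deps, state, card, tol = 1e-10, max_depth = 10L) {
  stopifnot(inherits(state, "plastic_state"), inherits(card, "material_card"))
  if (card$model != "svm") stop("card model must be 'svm'", call. = FALSE)
  ec <- .elastic_constants(card)
  G <- ec$G; Kb <- ec$Kb
  h <- card$hardening

  eps_new <- state$eps + as.numeric(deps)
  ee_tr <- eps_new - state$eps_p
  sig_tr <- .stress_from_elastic(ee_tr, G, Kb)
  p_tr <- -(sig_tr[1] + sig_tr[2] + sig_tr[3]) / 3
  s_tr <- sig_tr
  s_tr[1:3] <- s_tr[1:3] + p_tr
  q_tr <- sqrt(max(1.5 * sum(s_tr[1:3]^2) + 3 * sum(s_tr[4:6]^2), 0))

  eb0 <- state$eps_bar_p
  sf0 <- sigma_c_at(h, eb0)
  if (q_tr <= sf0 * (1 + tol)) {
    state$eps <- eps_new
    state$sigma <- sig_tr
    return(list(sigma = sig_tr, state = state, plastic = FALSE))
  }
  resid <- function(de) q_tr - 3 * G * de - sigma_c_at(h, eb0 + de)
  hi <- q_tr / (3 * G)             # q cannot relax below zero faster than this
  fhi <- resid(hi)
  while (fhi > 0) {
    hi <- hi * 2
    fhi <- resid(hi)
  }
  sol <- .illinois(resid, 0, hi, q_tr - sf0, fhi, tol * sf0)
  de <- sol$root
  q <- q_tr - 3 * G * de
  s <- s_tr * (q / q_tr)
  sig <- s
  sig[1:3] <- sig[1:3] - p_tr

  state$eps <- eps_new
  state$eps_p <- eps_new - .elastic_from_stress(sig, G, Kb)
  state$eps_bar_p <- eb0 + de
  state$sigma <- sig
  state$yielded <- TRUE
  list(sigma = sig, state = state, plastic = TRUE)
}

#' Dispatch a strain increment to the card's constitutive update
#'
#' @inheritParams icf_return_map
#' @param card a [material_card()] of either model.
#' @return as [icf_return_map()].
#' @export
integrate_increment <- function(deps, state, card, tol = 1e-10) {
  if (card$model == "icf") icf_return_map(deps, state, card, tol = tol)
  else svm_update(deps, state, card, tol = tol)
}
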