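## Batched material-point drivers: integrate many specimens' curves in one
## pass through the vectorized stress update. Numerically equivalent to
## run_uniaxial()/run_confined() per card (same return mapping, same
## tolerances); used by the population generator where thousands of curves
## are needed.

.batch_mat <- function(cards) {
  E <- vapply(cards, `[[`, 0, "E")
  nu <- vapply(cards, `[[`, 0, "nu_e")
  sy <- vapply(cards, `[[`, 0, "sigma_y_uni")
  model <- unique(vapply(cards, `[[`, "", "model"))
  if (length(model) != 1L) stop("batch requires a single model", call. = FALSE)
  eps_tab <- cards[[1L]]$hardening$eps_bar_p
  ratio <- cards[[1L]]$hardening$sigma_c / sy[1L]
  for (cd in cards) {
    if (length(cd$hardening$eps_bar_p) != length(eps_tab) ||
        any(abs(cd$hardening$eps_bar_p - eps_tab) > 1e-12) ||
        any(abs(cd$hardening$sigma_c / cd$sigma_y_uni - ratio) > 1e-9)) {
      stop("batch requires a shared hardening template shape", call. = FALSE)
    }
  }
  if (model == "icf") {
    K <- vapply(cards, `[[`, 0, "K")
    alpha2 <- 9 * K^2 / (9 - K^2)
    cB <- 3 / sqrt(9 - K^2)
  } else {
    K <- alpha2 <- cB <- rep(NA_real_, length(cards))
  }
  list(mat = list(G = E / (2 * (1 + nu)), Kb = E / (3 * (1 - 2 * nu)),
                  alpha2 = alpha2, cB = cB),
       E = E, model = model, eps_tab = eps_tab,
       sig_tab = outer(sy, ratio))
}

.batch_uniaxial <- function(cards, max_strain, n_steps, lat_tol = 1e-9,
                            max_lat_iter = 80L) {
  bm <- .batch_mat(cards)
  M <- length(cards)
  strain <- seq(0, max_strain, length.out = n_steps + 1L)
  stress <- matrix(0, n_steps + 1L, M)
  eps_p <- matrix(0, 6L, M)
  eb <- numeric(M)
  l_prev <- numeric(M)
  dl_prev <- numeric(M)
  tol_abs <- lat_tol * bm$E
  Eps <- matrix(0, 6L, M)
  evalu <- function(a_i, l) {
    Eps[1L, ] <- a_i
    Eps[2L, ] <- l
    Eps[3L, ] <- l
    .update_points(Eps, eps_p, eb, bm$mat, bm$eps_tab, bm$sig_tab, bm$model)
  }
  for (i in seq_len(n_steps)) {
    a_i <- -strain[i + 1L]
    l0 <- l_prev + dl_prev
    u0 <- evalu(a_i, l0); f0 <- u0$sigma[2L, ]
    act <- abs(f0) > tol_abs
    if (any(act)) {
      dl <- pmax(1e-7, abs(l0) * 1e-4)
      l1 <- ifelse(act, l0 + dl, l0)
      u1 <- evalu(a_i, l1); f1 <- u1$sigma[2L, ]
      for (it in seq_len(max_lat_iter)) {
        act <- abs(f1) > tol_abs
        if (!any(act)) break
        denom <- f1 - f0
        step <- ifelse(abs(denom) > 0, f1 * (l1 - l0) / denom, -dl)
        l2 <- ifelse(act, l1 - step, l1)
        l0 <- l1; f0 <- f1; l1 <- l2
        u1 <- evalu(a_i, l1); f1 <- u1$sigma[2L, ]
      }
      if (any(abs(f1) > tol_abs)) {
        stop(sprintf("batch lateral equilibrium failed at step %d", i),
             call. = FALSE)
      }
      u0 <- u1; l0 <- l1
    }
    eps_p <- u0$eps_p
    eb <- u0$eb
    stress[i + 1L, ] <- -u0$sigma[1L, ]
    dl_prev <- l0 - l_prev
    l_prev <- l0
  }
  list(strain = strain, stress = stress)
}

.batch_confined <- function(cards, max_strain, n_steps) {
  bm <- .batch_mat(cards)
  M <- length(cards)
  strain <- seq(0, max_strain, length.out = n_steps + 1L)
  stress <- matrix(0, n_steps + 1L, M)
  eps_p <- matrix(0, 6L, M)
  eb <- numeric(M)
  Eps <- matrix(0, 6L, M)
  for (i in seq_len(n_steps)) {
    Eps[1L, ] <- -strain[i + 1L]
    u <- .update_points(Eps, eps_p, eb, bm$mat, bm$eps_tab, bm$sig_tab,
                        bm$model)
    eps_p <- u$eps_p
    eb <- u$eb
    stress[i + 1L, ] <- -u$sigma[1L, ]
  }
  list(strain = strain, stress = stress)
}
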