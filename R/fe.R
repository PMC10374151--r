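## Voxel hexahedral finite elements, small strain, full 2x2x2 integration
## with B-bar volumetric treatment (guards against locking when the plastic
## Poisson's ratio approaches 0.5 at low K).

.hex_templates <- function(hx, hy, hz) {
  xi_n <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  eta_n <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  zet_n <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  g <- 1 / sqrt(3)
  gp <- expand.grid(xi = c(-g, g), eta = c(-g, g), zet = c(-g, g))
  w <- hx * hy * hz / 8
  Bs <- vector("list", 8L)
  bvols <- matrix(0, 8L, 24L)
  for (k in seq_len(8L)) {
    xi <- gp$xi[k]; eta <- gp$eta[k]; zet <- gp$zet[k]
    dNdx <- xi_n * (1 + eta * eta_n) * (1 + zet * zet_n) / 8 * (2 / hx)
    dNdy <- eta_n * (1 + xi * xi_n) * (1 + zet * zet_n) / 8 * (2 / hy)
    dNdz <- zet_n * (1 + xi * xi_n) * (1 + eta * eta_n) / 8 * (2 / hz)
    B <- matrix(0, 6L, 24L)
    ix <- 3 * (1:8) - 2
    B[1L, ix] <- dNdx
    B[2L, ix + 1L] <- dNdy
    B[3L, ix + 2L] <- dNdz
    B[4L, ix] <- dNdy; B[4L, ix + 1L] <- dNdx
    B[5L, ix] <- dNdz; B[5L, ix + 2L] <- dNdx
    B[6L, ix + 1L] <- dNdz; B[6L, ix + 2L] <- dNdy
    Bs[[k]] <- B
    bvols[k, ] <- B[1L, ] + B[2L, ] + B[3L, ]
  }
  bbar <- colMeans(bvols)
  Bb <- lapply(seq_len(8L), function(k) {
    B <- Bs[[k]]
    corr <- (bbar - bvols[k, ]) / 3
    B[1L, ] <- B[1L, ] + corr
    B[2L, ] <- B[2L, ] + corr
    B[3L, ] <- B[3L, ] + corr
    B
  })
  m6 <- c(1, 1, 1, 0, 0, 0)
  DG <- diag(c(4, 4, 4, 3, 3, 3) / 3)
  DG[1:3, 1:3] <- DG[1:3, 1:3] - 2 / 3
  diag(DG)[1:3] <- 4 / 3
  A_vol <- matrix(0, 24L, 24L)
  A_dev <- matrix(0, 24L, 24L)
  for (k in seq_len(8L)) {
    B <- Bb[[k]]
    bv <- m6 %*% B                       # volumetric row (identical for all k)
    A_vol <- A_vol + w * crossprod(bv)
    A_dev <- A_dev + w * t(B) %*% DG %*% B
  }
  list(B = Bb, w = w, A_vol = A_vol, A_dev = A_dev)
}

## area fraction of the square [x0,x1]x[y0,y1] inside the circle r <= R,
## by deterministic subsampling
.square_circle_fraction <- function(x0, x1, y0, y1, R, nsub = 32L) {
  xs <- x0 + (seq_len(nsub) - 0.5) / nsub * (x1 - x0)
  ys <- y0 + (seq_len(nsub) - 0.5) / nsub * (y1 - y0)
  mean(outer(xs^2, ys^2, "+") <= R^2)
}

#' Build a voxel finite-element model of a cylindrical specimen
#'
#' Resamples a voxel specimen to hexahedral elements of the requested size
#' (mean-pooling the BMD of masked voxels inside each element), assigns a
#' material card per element through the law set, and collects boundary node
#' sets. Boundary elements cut by the cylinder surface are retained with a
#' partial-volume weight equal to their in-cylinder area fraction, so the
#' modelled cross-section matches the true one at every element size. The
#' element height is rounded to divide the specimen height exactly
#' (`hz = height / round(height / element_size)`).
#'
#' @param spec a `voxel_specimen` (see [gen_voxel_cylinder()]).
#' @param element_size target element edge, mm.
#' @param calibration a [fit_hu_calibration()]; defaults to the specimen's
#'   phantom fit.
#' @param laws a [material_law_set()].
#' @param model `"icf"` or `"svm"`.
#' @param hardening hardening template name shared by all elements
#'   (scaled to each element's yield stress).
#' @param min_fraction drop elements with a smaller in-cylinder fraction.
#' @return object of class `voxel_fe_model`.
#' @export
build_model <- function(spec, element_size, calibration = NULL,
                        laws = femoral_laws(), model = c("icf", "svm"),
                        hardening = "trabecular", min_fraction = 0.02) {
  stopifnot(inherits(spec, "voxel_specimen"))
  model <- match.arg(model)
  if (!is.finite(element_size) || element_size <= 0) {
    stop("element_size must be positive", call. = FALSE)
  }
  if (is.null(calibration)) {
    calibration <- fit_hu_calibration(spec$phantom$density_mg_ml,
                                      spec$phantom$hu_mean)
  }
  H <- spec$height; D <- spec$diameter; R <- D / 2
  h <- element_size
  nez <- max(1L, as.integer(round(H / h)))
  hz <- H / nez
  nex <- as.integer(ceiling(D / h))
  ney <- nex
  ex0 <- -nex * h / 2
  ey0 <- -ney * h / 2
  ez0 <- -H / 2

  bmd_vox <- hu_to_bmd(spec$hu, calibration)
  vx <- spec$coords$x; vy <- spec$coords$y; vz <- spec$coords$z
  midx <- which(spec$mask, arr.ind = TRUE)
  if (!nrow(midx)) stop("empty voxel mask", call. = FALSE)
  ei <- pmin(pmax(floor((vx[midx[, 1L]] - ex0) / h), 0), nex - 1L) + 1L
  ej <- pmin(pmax(floor((vy[midx[, 2L]] - ey0) / h), 0), ney - 1L) + 1L
  ek <- pmin(pmax(floor((vz[midx[, 3L]] - ez0) / hz), 0), nez - 1L) + 1L
  eid <- ei + (ej - 1L) * nex + (ek - 1L) * nex * ney
  vals <- bmd_vox[spec$mask]
  bmd_sum <- rowsum(vals, eid)
  bmd_cnt <- rowsum(rep(1, length(eid)), eid)
  bmd_mean <- as.numeric(bmd_sum / bmd_cnt)
  filled <- as.integer(rownames(bmd_sum))

  ## in-cylinder area fraction per (i, j) column; full z coverage by design
  frac_col <- matrix(0, nex, ney)
  for (i in seq_len(nex)) {
    for (j in seq_len(ney)) {
      frac_col[i, j] <- .square_circle_fraction(
        ex0 + (i - 1L) * h, ex0 + i * h, ey0 + (j - 1L) * h, ey0 + j * h, R)
    }
  }
  bmd_e <- numeric(nex * ney * nez)
  bmd_e[filled] <- bmd_mean
  fr_e <- rep(as.vector(frac_col), times = nez)
  keep <- which(fr_e >= min_fraction & bmd_e > 0)
  if (!length(keep)) stop("no elements retained", call. = FALSE)
  ke_i <- (keep - 1L) %% nex + 1L
  ke_j <- ((keep - 1L) %/% nex) %% ney + 1L
  ke_k <- (keep - 1L) %/% (nex * ney) + 1L

  nid <- function(i, j, k) i + (j - 1L) * (nex + 1L) +
    (k - 1L) * (nex + 1L) * (ney + 1L)
  conn_full <- cbind(nid(ke_i, ke_j, ke_k), nid(ke_i + 1L, ke_j, ke_k),
                     nid(ke_i + 1L, ke_j + 1L, ke_k), nid(ke_i, ke_j + 1L, ke_k),
                     nid(ke_i, ke_j, ke_k + 1L), nid(ke_i + 1L, ke_j, ke_k + 1L),
                     nid(ke_i + 1L, ke_j + 1L, ke_k + 1L),
                     nid(ke_i, ke_j + 1L, ke_k + 1L))
  used <- sort(unique(as.vector(conn_full)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  conn <- matrix(remap[conn_full], ncol = 8L)
  gi <- (used - 1L) %% (nex + 1L)
  gj <- ((used - 1L) %/% (nex + 1L)) %% (ney + 1L)
  gk <- (used - 1L) %/% ((nex + 1L) * (ney + 1L))
  nodes <- cbind(x = ex0 + gi * h, y = ey0 + gj * h, z = ez0 + gk * hz)

  bmd_keep <- bmd_e[keep]
  E <- stiffness_of_bmd(bmd_keep, laws)
  sy <- yield_of_bmd(bmd_keep, laws)
  nu <- laws$nu_e
  if (model == "icf") {
    K <- k_of_bmd(bmd_keep, laws)
    alpha2 <- 9 * K^2 / (9 - K^2)
    cB <- 3 / sqrt(9 - K^2)
  } else {
    K <- rep(NA_real_, length(keep)); alpha2 <- cB <- K
    if (identical(hardening, "trabecular")) hardening <- "svm"
  }
  tmpl <- hardening_template(hardening, 1)
  eps_tab <- tmpl$eps_bar_p
  sig_tab <- outer(sy, tmpl$sigma_c)

  ## boundary node sets
  bottom <- which(gk == 0L)
  top <- which(gk == nez)
  occ <- array(FALSE, c(nex, ney, nez))
  occ[cbind(ke_i, ke_j, ke_k)] <- TRUE
  lat <- rep(FALSE, length(used))
  nb <- function(di, dj) {
    ii <- ke_i + di; jj <- ke_j + dj
    inside <- ii >= 1L & ii <= nex & jj >= 1L & jj <= ney
    has <- rep(FALSE, length(keep))
    has[inside] <- occ[cbind(ii[inside], jj[inside], ke_k[inside])]
    has
  }
  face_nodes <- list(`-x` = c(1L, 4L, 5L, 8L), `+x` = c(2L, 3L, 6L, 7L),
                     `-y` = c(1L, 2L, 5L, 6L), `+y` = c(3L, 4L, 7L, 8L))
  shifts <- list(`-x` = c(-1L, 0L), `+x` = c(1L, 0L),
                 `-y` = c(0L, -1L), `+y` = c(0L, 1L))
  for (f in names(shifts)) {
    open_face <- !nb(shifts[[f]][1L], shifts[[f]][2L])
    if (any(open_face)) {
      lat[unique(as.vector(conn[open_face, face_nodes[[f]], drop = FALSE]))] <- TRUE
    }
  }

  structure(list(
    nodes = nodes, conn = conn, h = c(h, h, hz), nominal_area = pi * R^2,
    height = H, diameter = D,
    bmd = bmd_keep, fraction = fr_e[keep], model = model,
    E = E, nu_e = nu, sigma_y = sy, K = K, alpha2 = alpha2, cB = cB,
    G = E / (2 * (1 + nu)), Kb = E / (3 * (1 - 2 * nu)),
    eps_tab = eps_tab, sig_tab = sig_tab,
    sets = list(bottom = bottom, top = top, lateral = which(lat)),
    templates = .hex_templates(h, h, hz)),
    class = "voxel_fe_model")
}

#' Single-element model from a material card
#'
#' A one-hexahedron model carrying one card, with the element cross-section
#' as nominal area — the FE counterpart of a material point, used to verify
#' that [solve_compression()] and the material-point drivers agree.
#'
#' @param card a [material_card()].
#' @param size element edge length, mm.
#' @return a `voxel_fe_model`.
#' @export
single_element_model <- function(card, size = 1) {
  h <- size
  nodes <- cbind(x = c(0, h, h, 0, 0, h, h, 0),
                 y = c(0, 0, h, h, 0, 0, h, h),
                 z = c(0, 0, 0, 0, h, h, h, h))
  conn <- matrix(1:8, nrow = 1L)
  icf <- card$model == "icf"
  tmpl <- card$hardening
  structure(list(
    nodes = nodes, conn = conn, h = c(h, h, h), nominal_area = h^2,
    height = h, diameter = h,
    bmd = card$bmd, fraction = 1, model = card$model,
    E = card$E, nu_e = card$nu_e, sigma_y = card$sigma_y_uni,
    K = card$K,
    alpha2 = if (icf) 9 * card$K^2 / (9 - card$K^2) else NA_real_,
    cB = if (icf) 3 / sqrt(9 - card$K^2) else NA_real_,
    G = card$E / (2 * (1 + card$nu_e)),
    Kb = card$E / (3 * (1 - 2 * card$nu_e)),
    eps_tab = tmpl$eps_bar_p,
    sig_tab = matrix(tmpl$sigma_c, nrow = 1L),
    sets = list(bottom = 1:4, top = 5:8, lateral = 1:8),
    templates = .hex_templates(h, h, h)),
    class = "voxel_fe_model")
}

#' @export
print.voxel_fe_model <- function(x, ...) {
  cat(sprintf("<voxel_fe_model> %d hexahedra (%.3g x %.3g x %.3g mm), %d nodes, model %s\n",
              nrow(x$conn), x$h[1L], x$h[2L], x$h[3L], nrow(x$nodes), x$model))
  invisible(x)
}

## shared-knot piecewise-linear interpolation with per-row tables,
## constant beyond the ends
.interp_rows <- function(x_tab, y_tab, x) {
  K <- length(x_tab)
  if (K == 1L) return(y_tab[, 1L])
  i <- findInterval(x, x_tab, all.inside = TRUE)
  t <- (x - x_tab[i]) / (x_tab[i + 1L] - x_tab[i])
  t <- pmin(pmax(t, 0), 1)
  rows <- seq_along(x)
  y0 <- y_tab[cbind(rows, i)]
  y0 + t * (y_tab[cbind(rows, i + 1L)] - y0)
}

## Vectorized stress update at M material points from committed plastic
## state. Eps: 6 x M total strain; returns stress, plastic strain, hardening
## variable. mat fields are length-M vectors.
.update_points <- function(Eps, eps_p, eb, mat, eps_tab, sig_tab,
                           model, tol = 1e-9) {
  M <- ncol(Eps)
  ee <- Eps - eps_p
  tr <- ee[1L, ] + ee[2L, ] + ee[3L, ]
  lam <- mat$Kb - 2 * mat$G / 3
  sig <- rbind(2 * rep(1, 3) %o% mat$G * ee[1:3, , drop = FALSE] +
                 rep(1, 3) %o% (lam * tr),
               rep(1, 3) %o% mat$G * ee[4:6, , drop = FALSE])
  p_tr <- -(sig[1L, ] + sig[2L, ] + sig[3L, ]) / 3
  s <- sig
  s[1:3, ] <- s[1:3, ] + rep(1, 3) %o% p_tr
  q_tr <- sqrt(pmax(1.5 * (s[1L, ]^2 + s[2L, ]^2 + s[3L, ]^2) +
                      3 * (s[4L, ]^2 + s[5L, ]^2 + s[6L, ]^2), 0))
  sc0 <- .interp_rows(eps_tab, sig_tab, eb)

  if (model == "icf") {
    g_tr <- sqrt(q_tr^2 + mat$alpha2 * p_tr^2)
    B0 <- mat$cB * sc0
    pl <- which(g_tr > B0 * (1 + tol))
  } else {
    pl <- which(q_tr > sc0 * (1 + tol))
  }
  if (!length(pl)) {
    return(list(sigma = sig, eps_p = eps_p, eb = eb,
                plastic = logical(M)))
  }
  G <- mat$G[pl]; Kb <- mat$Kb[pl]
  qt <- q_tr[pl]; pt <- p_tr[pl]
  ebp <- eb[pl]
  stab <- sig_tab[pl, , drop = FALSE]
  if (model == "icf") {
    a2 <- mat$alpha2[pl]; cB <- mat$cB[pl]
    g0 <- g_tr[pl]; Bp <- B0[pl]
    Rfun <- function(de) {
      sc <- .interp_rows(eps_tab, stab, ebp + de)
      B <- cB * sc
      m <- de * sc / B^2
      q <- qt / (1 + 3 * G * m)
      p <- pt / (1 + Kb * a2 * m)
      sqrt(q^2 + a2 * p^2) - B
    }
    hi <- (g0 - Bp) / (3 * G + Kb * a2) * cB^2 + 1e-16
    for (d in 1:80) {
      bad <- Rfun(hi) > 0
      if (!any(bad)) break
      hi[bad] <- hi[bad] * 2
    }
    lo <- numeric(length(pl))
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      up <- Rfun(mid) > 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    de <- (lo + hi) / 2
    sc <- .interp_rows(eps_tab, stab, ebp + de)
    B <- cB * sc
    m <- de * sc / B^2
    fac_q <- 1 / (1 + 3 * G * m)
    p_new <- pt / (1 + Kb * a2 * m)
    s[1:3, pl] <- s[1:3, pl, drop = FALSE] * (rep(1, 3) %o% fac_q)
    s[4:6, pl] <- s[4:6, pl, drop = FALSE] * (rep(1, 3) %o% fac_q)
    sig[, pl] <- s[, pl, drop = FALSE]
    sig[1:3, pl] <- sig[1:3, pl, drop = FALSE] - rep(1, 3) %o% p_new
  } else {
    Rfun <- function(de) qt - 3 * G * de -
      .interp_rows(eps_tab, stab, ebp + de)
    hi <- qt / (3 * G) + 1e-16
    for (d in 1:80) {
      bad <- Rfun(hi) > 0
      if (!any(bad)) break
      hi[bad] <- hi[bad] * 2
    }
    lo <- numeric(length(pl))
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      up <- Rfun(mid) > 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    de <- (lo + hi) / 2
    qn <- qt - 3 * G * de
    fac <- ifelse(qt > 0, qn / qt, 0)
    sig[, pl] <- s[, pl, drop = FALSE] * (rep(1, 6) %o% fac)
    sig[1:3, pl] <- sig[1:3, pl, drop = FALSE] - rep(1, 3) %o% pt
  }
  ## recover plastic strain from the elastic compliance of the final stress
  pf <- -(sig[1L, pl] + sig[2L, pl] + sig[3L, pl]) / 3
  sf <- sig[, pl, drop = FALSE]
  sf[1:3, ] <- sf[1:3, ] + rep(1, 3) %o% pf
  ee_f <- rbind(sf[1:3, , drop = FALSE] / (rep(1, 3) %o% (2 * G)) -
                  rep(1, 3) %o% (pf / (3 * Kb)),
                sf[4:6, , drop = FALSE] / (rep(1, 3) %o% G))
  eps_p[, pl] <- Eps[, pl, drop = FALSE] - ee_f
  eb[pl] <- ebp + de
  plastic <- logical(M); plastic[pl] <- TRUE
  list(sigma = sig, eps_p = eps_p, eb = eb, plastic = plastic)
}

#' Simulate compression of a voxel FE model
#'
#' Displacement-controlled compression: the bottom platen is fixed axially,
#' the top nodes move down in equal increments, and in-plane motion at the
#' platens is left free (frictionless platens). In confined mode the lateral
#' surface nodes are additionally pinned in-plane (rigid chamber). Each
#' increment is equilibrated by a modified Newton iteration on the elastic
#' stiffness (factorized once), with the vectorized crushable-foam or von
#' Mises stress update supplying the internal forces; non-convergence
#' triggers increment bisection.
#'
#' @param model a [build_model()] result.
#' @param mode `"uniaxial"` or `"confined"`.
#' @param max_strain final nominal compressive strain.
#' @param n_increments number of displacement increments.
#' @param tol relative force-residual tolerance.
#' @param max_iter modified-Newton iteration cap per increment.
#' @return list with `curve` (a [stress_strain_curve()], nominal stress on
#'   the full cross-section), `eps_field` (per-element equivalent plastic
#'   strain), `energy_total` (N.mm), `energy_history`, `energy_element`,
#'   `reactions` (top/bottom force balance per increment) and `u` (final
#'   displacement vector).
#' @export
solve_compression <- function(model, mode = c("uniaxial", "confined"),
                              max_strain = 0.01, n_increments = 5L,
                              tol = 1e-8, max_iter = 400L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "voxel_fe_model"))
  Ne <- nrow(model$conn)
  Nn <- nrow(model$nodes)
  ndof <- 3L * Nn
  tp <- model$templates
  edof <- matrix(0L, Ne, 24L)
  for (a in 1:8) {
    edof[, 3L * a - 2L] <- 3L * model$conn[, a] - 2L
    edof[, 3L * a - 1L] <- 3L * model$conn[, a] - 1L
    edof[, 3L * a] <- 3L * model$conn[, a]
  }
  Kb_f <- model$Kb * model$fraction
  G_f <- model$G * model$fraction
  xval <- Kb_f %o% as.vector(tp$A_vol) + G_f %o% as.vector(tp$A_dev)
  iidx <- edof[, rep(1:24, times = 24L), drop = FALSE]
  jidx <- edof[, rep(1:24, each = 24L), drop = FALSE]
  Kmat <- Matrix::sparseMatrix(i = as.vector(iidx), j = as.vector(jidx),
                               x = as.vector(xval), dims = c(ndof, ndof))

  bottom <- model$sets$bottom; top <- model$sets$top
  fixed <- c(3L * bottom, 3L * top)
  if (mode == "uniaxial") {
    ## pin rigid in-plane modes without constraining uniform contraction:
    ## one node fixes translation, a second node at the same y (different x)
    ## fixes rotation about the axis
    r2 <- model$nodes[bottom, 1L]^2 + model$nodes[bottom, 2L]^2
    pin <- bottom[which.min(r2)]
    same_y <- bottom[abs(model$nodes[bottom, 2L] - model$nodes[pin, 2L]) < 1e-9]
    far <- same_y[which.max(abs(model$nodes[same_y, 1L] - model$nodes[pin, 1L]))]
    fixed <- c(fixed, 3L * pin - 2L, 3L * pin - 1L, 3L * far - 1L)
  } else {
    lat <- model$sets$lateral
    fixed <- c(fixed, 3L * lat - 2L, 3L * lat - 1L)
  }
  fixed <- sort(unique(fixed))
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- Matrix::forceSymmetric(Kmat[free, free, drop = FALSE])
  fact <- Matrix::Cholesky(Kff, LDL = FALSE)

  M <- Ne * 8L
  mat <- list(G = rep(model$G, 8L), Kb = rep(model$Kb, 8L),
              alpha2 = rep(model$alpha2, 8L), cB = rep(model$cB, 8L))
  sig_tab8 <- model$sig_tab[rep(seq_len(Ne), 8L), , drop = FALSE]
  wfrac <- tp$w * model$fraction          # per-element integration weight

  strain_at <- function(u) {
    Ue <- matrix(u[t(edof)], nrow = 24L)  # 24 x Ne
    Eps <- matrix(0, 6L, M)
    for (g in 1:8) {
      Eps[, ((g - 1L) * Ne + 1L):(g * Ne)] <- tp$B[[g]] %*% Ue
    }
    Eps
  }
  internal_force <- function(Sig) {
    f <- numeric(ndof)
    for (g in 1:8) {
      blk <- Sig[, ((g - 1L) * Ne + 1L):(g * Ne), drop = FALSE]
      Fe <- crossprod(tp$B[[g]], blk * rep(wfrac, each = 6L))   # 24 x Ne
      agg <- rowsum(as.vector(Fe), as.vector(t(edof)))
      f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1L]
    }
    f
  }

  eps_p <- matrix(0, 6L, M)
  eb <- numeric(M)
  Sig_c <- matrix(0, 6L, M)
  Eps_c <- matrix(0, 6L, M)
  u <- numeric(ndof)
  energy_el <- numeric(Ne)
  strain_out <- seq(0, max_strain, length.out = n_increments + 1L)
  stress_out <- numeric(n_increments + 1L)
  energy_hist <- numeric(n_increments + 1L)
  reactions <- data.frame(increment = seq_len(n_increments),
                          R_top = NA_real_, R_bottom = NA_real_,
                          residual = NA_real_, iterations = NA_integer_)
  top_z <- 3L * top; bot_z <- 3L * bottom

  for (inc in seq_len(n_increments)) {
    u[top_z] <- -strain_out[inc + 1L] * model$height
    upd <- NULL
    ref <- NA_real_
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Eps <- strain_at(u)
      upd <- .update_points(Eps, eps_p, eb, mat, model$eps_tab, sig_tab8,
                            model$model)
      fint <- internal_force(upd$sigma)
      ref <- max(max(abs(fint[fixed])), 1e-6 * max(model$E))
      resn <- if (length(free)) max(abs(fint[free])) else 0
      if (resn <= tol * ref) {
        reactions$residual[inc] <- resn / ref
        reactions$iterations[inc] <- it
        converged <- TRUE
        break
      }
      if (length(free)) {
        du <- as.numeric(Matrix::solve(fact, -fint[free]))
        u[free] <- u[free] + du
      }
    }
    if (!converged) {
      stop(sprintf("FE increment %d did not converge (residual %.3g)",
                   inc, resn), call. = FALSE)
    }
    ## commit state, accumulate strain energy (trapezoidal work integral)
    Eps <- strain_at(u)
    dW <- colSums((Sig_c + upd$sigma) / 2 * (Eps - Eps_c))
    energy_el <- energy_el + unname(rowsum(dW * rep(wfrac, 8L),
                                           rep(seq_len(Ne), 8L))[, 1L])
    Sig_c <- upd$sigma
    Eps_c <- Eps
    eps_p <- upd$eps_p
    eb <- upd$eb
    fint <- internal_force(Sig_c)
    R_top <- sum(fint[top_z])
    R_bot <- sum(fint[bot_z])
    reactions$R_top[inc] <- R_top
    reactions$R_bottom[inc] <- R_bot
    stress_out[inc + 1L] <- -R_top / model$nominal_area
    energy_hist[inc + 1L] <- sum(energy_el)
  }
  eps_field <- unname(rowsum(eb, rep(seq_len(Ne), 8L))[, 1L] / 8)
  curve <- stress_strain_curve(strain_out, stress_out, mode = mode,
                               meta = list(element_size = model$h,
                                           n_elements = Ne))
  list(curve = curve, eps_field = eps_field,
       energy_total = sum(energy_el), energy_history = energy_hist,
       energy_element = energy_el, reactions = reactions, u = u)
}

#' Total strain energy of a solved model
#'
#' Sum of the element work integrals accumulated during
#' [solve_compression()] (elastic plus plastic work), N.mm.
#'
#' @param model a `voxel_fe_model`.
#' @param solution the matching [solve_compression()] result.
#' @return total strain energy, N.mm.
#' @export
strain_energy <- function(model, solution) {
  stopifnot(inherits(model, "voxel_fe_model"))
  solution$energy_total
}

#' Export an equivalent-plastic-strain field as legacy VTK
#'
#' Writes the model mesh and a per-element scalar field as an ASCII legacy
#' VTK unstructured grid, viewable in ParaView.
#'
#' @param model a `voxel_fe_model`.
#' @param field per-element scalar (e.g. `solution$eps_field`).
#' @param path output `.vtk` path.
#' @param name field name in the file.
#' @export
write_vtk_field <- function(model, field, path, name = "EPS") {
  stopifnot(inherits(model, "voxel_fe_model"),
            length(field) == nrow(model$conn))
  con <- file(path, "w")
  on.exit(close(con))
  Nn <- nrow(model$nodes); Ne <- nrow(model$conn)
  writeLines(c("# vtk DataFile Version 3.0", "bonefoam EPS field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", Nn)), con)
  utils::write.table(model$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", Ne, 9L * Ne), con)
  utils::write.table(cbind(8L, model$conn - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", Ne), con)
  writeLines(as.character(rep(12L, Ne)), con)
  writeLines(c(sprintf("CELL_DATA %d", Ne),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(field, digits = 9), con)
  invisible(path)
}
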