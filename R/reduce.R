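.no_yield_error <- function(msg) {
  stop(structure(class = c("bonefoam_no_yield", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## Rolling ordinary least squares of stress on strain over all contiguous
## windows of width w; returns slopes and R^2 computed from prefix sums.
.rolling_ols <- function(x, y, w) {
  n <- length(x)
  m <- n - w + 1L
  csum <- function(v) {
    cs <- cumsum(v)
    cs[w:n] - c(0, cs[seq_len(m - 1L)])
  }
  sx <- csum(x); sy <- csum(y)
  sxx <- csum(x * x); sxy <- csum(x * y); syy <- csum(y * y)
  vxx <- sxx - sx * sx / w
  vxy <- sxy - sx * sy / w
  vyy <- syy - sy * sy / w
  slope <- vxy / vxx
  r2 <- ifelse(vyy > 0, (vxy * vxy) / (vxx * vyy), 1)
  list(slope = slope, r2 = r2, start = seq_len(m), end = seq_len(m) + w - 1L)
}

#' Elastic modulus and 0.2% offset yield point of a curve
#'
#' The elastic modulus is taken as the maximal slope among sliding regression
#' windows (width `window_frac` of the samples) whose linearity satisfies
#' `R^2 >= r2_min`; if no window of that width qualifies, the width is halved
#' until one does. The yield point is the first intersection of the curve
#' with the offset line `sigma = E (eps - offset)`, linearly interpolated
#' between samples and with ties broken toward lower strain. A curve that
#' never meets the offset line (purely elastic) raises a `bonefoam_no_yield`
#' condition.
#'
#' @param curve a [stress_strain_curve()] (compression positive).
#' @param offset strain offset, default 0.002 (0.2%).
#' @param window_frac sliding-window width as a fraction of the sample count.
#' @param r2_min linearity threshold for a window to qualify.
#' @return list with `E` (MPa), `sigma_y` (MPa), `eps_y`, the window indices
#'   used, and the window's `r2`.
#' @export
offset_yield <- function(curve, offset = 0.002, window_frac = 0.10,
                         r2_min = 0.999) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  x <- curve$strain; y <- curve$stress
  n <- length(x)
  w <- max(3L, as.integer(round(window_frac * n)))
  # the elastic segment is at least as steep as the curve's overall chord;
  # this rejects flat plateau windows whose R^2 is a 0/0 artifact
  chord <- max(y) / max(x[n], .Machine$double.eps)
  pick <- NULL
  while (is.null(pick) && w >= 3L) {
    ro <- .rolling_ols(x, y, w)
    ok <- which(is.finite(ro$slope) & ro$slope >= chord & ro$r2 >= r2_min)
    if (length(ok)) {
      best <- ok[which.max(ro$slope[ok])]
      pick <- list(E = ro$slope[best], r2 = ro$r2[best],
                   window = c(ro$start[best], ro$end[best]))
    } else {
      w <- w %/% 2L
    }
  }
  if (is.null(pick)) {
    ro <- .rolling_ols(x, y, max(3L, as.integer(round(window_frac * n))))
    best <- which.max(ro$r2)
    pick <- list(E = ro$slope[best], r2 = ro$r2[best],
                 window = c(ro$start[best], ro$end[best]))
  }
  E <- pick$E
  if (!is.finite(E) || E <= 0) {
    .no_yield_error("no linear elastic segment identified")
  }
  d <- y - E * (x - offset)
  cross <- which(d[-1L] <= 0 & d[-n] > 0)
  if (!length(cross)) {
    .no_yield_error("curve never intersects the offset line (no yield)")
  }
  i <- cross[1L]                           # first crossing, lower strain wins
  t <- d[i] / (d[i] - d[i + 1L])
  eps_y <- x[i] + t * (x[i + 1L] - x[i])
  sigma_y <- y[i] + t * (y[i + 1L] - y[i])
  list(E = E, sigma_y = sigma_y, eps_y = eps_y,
       window = pick$window, r2 = pick$r2)
}

#' Convert a confined-compression yield stress to hydrostatic stress
#'
#' In the elastic uniaxial-strain state the lateral stress is
#' `sigma_r = nu/(1-nu) * sigma_a` (Hooke's law), so the mean pressure at the
#' measured axial yield stress is `p_y = sigma_a (1 + nu) / (3 (1 - nu))`.
#'
#' @param sigma_axial_yield axial yield stress from the confined test, MPa.
#' @param nu_e elastic Poisson's ratio in `[0, 0.5)`.
#' @return hydrostatic yield stress, MPa.
#' @export
confined_to_hydrostatic <- function(sigma_axial_yield, nu_e = 0.16) {
  if (any(!is.finite(nu_e)) || any(nu_e < 0) || any(nu_e >= 0.5)) {
    stop("nu_e must lie in [0, 0.5)", call. = FALSE)
  }
  sigma_axial_yield * (1 + nu_e) / (3 * (1 - nu_e))
}

#' Elastic Poisson's ratio from DIC strain traces
#'
#' Least-squares slope of transverse on axial strain over the elastic window;
#' the Poisson's ratio is minus that slope.
#'
#' @param axial_strain,transverse_strain paired strain arrays restricted to
#'   the elastic range (>= 3 points).
#' @return estimated Poisson's ratio (dimensionless).
#' @export
dic_poisson <- function(axial_strain, transverse_strain) {
  stopifnot(is.numeric(axial_strain), is.numeric(transverse_strain),
            length(axial_strain) == length(transverse_strain))
  if (length(axial_strain) < 3L) {
    stop("need >= 3 DIC points", call. = FALSE)
  }
  fit <- stats::lm(transverse_strain ~ axial_strain)
  -unname(stats::coef(fit)[2L])
}

#' Specimen test record
#'
#' One mechanical test: identity, mean BMD, mode, cylinder geometry, and
#' either a reduced [stress_strain_curve()] or raw force-displacement data
#' (`force_n`, Newtons, and `displacement_mm`).
#'
#' @param specimen_id identifier.
#' @param bmd mean specimen BMD, g/ml (> 0).
#' @param mode `"uniaxial"` or `"confined"`.
#' @param curve a [stress_strain_curve()], or `NULL` if force-displacement
#'   data are given.
#' @param force_n,displacement_mm raw test data (compression positive).
#' @param height,diameter cylinder geometry, mm.
#' @return object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, bmd, mode = c("uniaxial", "confined"),
                            curve = NULL, force_n = NULL,
                            displacement_mm = NULL,
                            height = 12, diameter = 11.65) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(bmd), length(bmd) == 1L)
  if (!is.finite(bmd) || bmd <= 0) stop("bmd must be positive", call. = FALSE)
  if (!is.finite(height) || height <= 0 || !is.finite(diameter) || diameter <= 0) {
    stop("geometry must be positive", call. = FALSE)
  }
  if (is.null(curve)) {
    if (is.null(force_n) || is.null(displacement_mm)) {
      stop("either a curve or force/displacement data are required",
           call. = FALSE)
    }
    area <- pi * (diameter / 2)^2
    curve <- stress_strain_curve(displacement_mm / height, force_n / area,
                                 mode = mode)
  }
  structure(list(specimen_id = specimen_id, bmd = bmd, mode = mode,
                 curve = curve, height = height, diameter = diameter),
            class = "specimen_record")
}

#' Reduce one specimen record to mechanical parameters
#'
#' Uniaxial records yield `E` and `sigma_y` via [offset_yield()]. Confined
#' records report the Young's modulus recovered from the confined elastic
#' slope through the constrained-modulus relation
#' `E = slope * (1 + nu)(1 - 2 nu) / (1 - nu)` (so `E` means the same
#' quantity for every record), and convert the axial yield stress to the
#' hydrostatic yield stress `p_y` via [confined_to_hydrostatic()]. Records
#' whose curve has no identifiable yield point are flagged excluded instead
#' of erroring (the fate of structurally failed specimens).
#'
#' @param record a [specimen_record()].
#' @param nu_e elastic Poisson's ratio used for the hydrostatic conversion.
#' @param offset yield offset strain.
#' @return a one-row data.frame with columns `specimen_id`, `bmd`, `mode`,
#'   `E`, `sigma_y`, `p_y`, `excluded`, `reason`.
#' @export
reduce_record <- function(record, nu_e = 0.16, offset = 0.002) {
  stopifnot(inherits(record, "specimen_record"))
  out <- data.frame(specimen_id = record$specimen_id, bmd = record$bmd,
                    mode = record$mode, E = NA_real_, sigma_y = NA_real_,
                    p_y = NA_real_, excluded = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  res <- tryCatch(offset_yield(record$curve, offset = offset),
                  bonefoam_no_yield = function(e) e)
  if (inherits(res, "bonefoam_no_yield")) {
    out$excluded <- TRUE
    out$reason <- conditionMessage(res)
    return(out)
  }
  if (record$mode == "uniaxial") {
    out$E <- res$E
    out$sigma_y <- res$sigma_y
  } else {
    out$E <- res$E * (1 + nu_e) * (1 - 2 * nu_e) / (1 - nu_e)
    out$sigma_y <- res$sigma_y
    out$p_y <- confined_to_hydrostatic(res$sigma_y, nu_e)
  }
  out
}
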