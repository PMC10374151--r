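#' Nominal stress-strain curve container
#'
#' Paired nominal axial strain/stress arrays in the compression-positive
#' reporting convention, with the test mode and optional provenance metadata
#' and per-step state history attached as attributes.
#'
#' @param strain nominal axial strain (compression positive), non-decreasing,
#'   starting at 0.
#' @param stress nominal axial stress, MPa (compression positive).
#' @param mode `"uniaxial"` or `"confined"`.
#' @param meta optional named list (card, BMD, ...).
#' @param history optional data.frame of per-step internal variables.
#' @return a data.frame of class `stress_strain_curve` with columns `strain`,
#'   `stress`.
#' @export
stress_strain_curve <- function(strain, stress,
                                mode = c("uniaxial", "confined"),
                                meta = list(), history = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(strain), is.numeric(stress),
            length(strain) == length(stress))
  if (length(strain) < 2L) stop("curve needs >= 2 points", call. = FALSE)
  if (strain[1L] != 0) stop("curve must start at strain 0", call. = FALSE)
  if (any(diff(strain) < 0)) {
    stop("strain must be non-decreasing", call. = FALSE)
  }
  out <- data.frame(strain = as.numeric(strain), stress = as.numeric(stress))
  attr(out, "mode") <- mode
  attr(out, "meta") <- meta
  attr(out, "history") <- history
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("<stress_strain_curve> mode %s, %d points, max strain %.4g, max stress %.5g MPa\n",
              attr(x, "mode"), nrow(x), max(x$strain), max(x$stress)))
  invisible(x)
}

.drive_steps <- function(card, max_strain, n_steps) {
  if (!is.finite(max_strain) || max_strain <= 0 || max_strain > 0.58) {
    stop("max_strain must lie in (0, 0.58]", call. = FALSE)
  }
  if (!is.finite(n_steps) || n_steps < 2L) {
    stop("need at least 2 steps", call. = FALSE)
  }
  seq(0, max_strain, length.out = n_steps + 1L)
}

#' Strain-driven uniaxial compression of one material point
#'
#' Prescribes the axial strain step by step and finds, by secant iteration on
#' the (equal) lateral strains, the laterally stress-free state that a
#' specimen between frictionless platens attains. The lateral normal stress
#' is driven below `lat_tol * E` at every step.
#'
#' @param card a [material_card()].
#' @param max_strain final nominal compressive strain, in (0, 0.58].
#' @param n_steps number of strain increments.
#' @param lat_tol relative tolerance on the lateral stress.
#' @param max_lat_iter iteration cap for the lateral equilibrium loop.
#' @return a [stress_strain_curve()] (compression-positive) whose `history`
#'   attribute holds per-step lateral strain, plastic strain components and
#'   the hardening variable.
#' @export
run_uniaxial <- function(card, max_strain = 0.58, n_steps = 580,
                         lat_tol = 1e-9, max_lat_iter = 60L) {
  strain <- .drive_steps(card, max_strain, n_steps)
  n <- length(strain)
  state <- plastic_state()
  stress <- numeric(n)
  lat <- numeric(n)
  hist <- data.frame(strain = strain, eps_lat = 0, eps_p_axial = 0,
                     eps_p_trans = 0, eps_bar_p = 0)
  tol_abs <- lat_tol * card$E
  a_prev <- 0; l_prev <- 0; dl_prev <- 0
  for (i in 2:n) {
    a_i <- -strain[i]                     # internal tension-positive axial
    trial <- function(l) {
      integrate_increment(c(a_i - a_prev, l - l_prev, l - l_prev, 0, 0, 0),
                          state, card)
    }
    l0 <- l_prev + dl_prev
    r0 <- trial(l0); f0 <- r0$sigma[2L]
    if (abs(f0) > tol_abs) {
      dl <- max(1e-7, abs(l0) * 1e-4)
      l1 <- l0 + dl
      r1 <- trial(l1); f1 <- r1$sigma[2L]
      it <- 0L
      while (abs(f1) > tol_abs && it < max_lat_iter) {
        denom <- f1 - f0
        l2 <- if (abs(denom) > 0) l1 - f1 * (l1 - l0) / denom else l1 + dl
        l0 <- l1; f0 <- f1
        l1 <- l2
        r1 <- trial(l1); f1 <- r1$sigma[2L]
        it <- it + 1L
      }
      if (abs(f1) > tol_abs) {
        stop(sprintf(
          "lateral equilibrium did not converge at step %d (|sigma_lat| = %.3g MPa)",
          i, abs(f1)), call. = FALSE)
      }
      r0 <- r1; l0 <- l1
    }
    state <- r0$state
    stress[i] <- -r0$sigma[1L]
    dl_prev <- l0 - l_prev
    l_prev <- l0
    a_prev <- a_i
    lat[i] <- l0
    hist$eps_lat[i] <- l0
    hist$eps_p_axial[i] <- -state$eps_p[1L]
    hist$eps_p_trans[i] <- -state$eps_p[2L]
    hist$eps_bar_p[i] <- state$eps_bar_p
  }
  stress_strain_curve(strain, stress, mode = "uniaxial",
                      meta = list(card = card, bmd = card$bmd),
                      history = hist)
}

#' Strain-driven confined compression of one material point
#'
#' Uniaxial-strain state: the axial strain is prescribed and all lateral
#' strains are held at zero (rigid chamber). The elastic slope equals the
#' constrained modulus `E (1 - nu) / ((1 + nu)(1 - 2 nu))`.
#'
#' @inheritParams run_uniaxial
#' @return a [stress_strain_curve()] with mode `"confined"`; the `history`
#'   attribute additionally records the lateral stress.
#' @export
run_confined <- function(card, max_strain = 0.58, n_steps = 580) {
  strain <- .drive_steps(card, max_strain, n_steps)
  n <- length(strain)
  state <- plastic_state()
  stress <- numeric(n)
  hist <- data.frame(strain = strain, sigma_lat = 0, eps_p_axial = 0,
                     eps_bar_p = 0)
  a_prev <- 0
  for (i in 2:n) {
    a_i <- -strain[i]
    r <- integrate_increment(c(a_i - a_prev, 0, 0, 0, 0, 0), state, card)
    state <- r$state
    stress[i] <- -r$sigma[1L]
    hist$sigma_lat[i] <- -r$sigma[2L]
    hist$eps_p_axial[i] <- -state$eps_p[1L]
    hist$eps_bar_p[i] <- state$eps_bar_p
    a_prev <- a_i
  }
  stress_strain_curve(strain, stress, mode = "confined",
                      meta = list(card = card, bmd = card$bmd),
                      history = hist)
}

#' Write / read stress-strain curves as CSV
#'
#' CSV columns `strain`, `stress_mpa`; mode and metadata go to a JSON sidecar
#' (`<path>.json`) when `sidecar = TRUE`.
#'
#' @param curve a [stress_strain_curve()].
#' @param path CSV file path.
#' @param sidecar write a JSON sidecar with mode/meta.
#' @export
write_curve_csv <- function(curve, path, sidecar = TRUE) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  utils::write.csv(data.frame(strain = curve$strain, stress_mpa = curve$stress),
                   path, row.names = FALSE)
  if (sidecar) {
    meta <- attr(curve, "meta")
    meta$card <- NULL                      # cards serialize separately
    jsonlite::write_json(list(mode = attr(curve, "mode"), meta = meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_curve_csv
#' @param mode curve mode, used when no sidecar is present.
#' @export
read_curve_csv <- function(path, mode = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("strain", "stress_mpa") %in% names(df))) {
    stop("curve CSV needs columns strain, stress_mpa", call. = FALSE)
  }
  meta <- list()
  side <- paste0(path, ".json")
  if (is.null(mode) && file.exists(side)) {
    obj <- jsonlite::read_json(side, simplifyVector = TRUE)
    mode <- obj$mode
    if (!is.null(obj$meta)) meta <- as.list(obj$meta)
  }
  if (is.null(mode)) mode <- "uniaxial"
  stress_strain_curve(df$strain, df$stress_mpa, mode = mode, meta = meta)
}
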