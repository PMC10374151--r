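#' Uniaxial hardening/softening curve
#'
#' Piecewise-linear table of uniaxial compressive yield stress `sigma_c`
#' against equivalent plastic strain `eps_bar_p`. The table may soften
#' (non-monotone `sigma_c`); `eps_bar_p` must be strictly increasing, start at
#' zero, and all stresses must be positive. Beyond the last knot the curve is
#' held constant.
#'
#' @param eps_bar_p equivalent plastic strain knots, first must be 0.
#' @param sigma_c uniaxial yield stress at each knot, MPa (> 0).
#' @return object of class `hardening_curve`.
#' @export
hardening_curve <- function(eps_bar_p, sigma_c) {
  stopifnot(is.numeric(eps_bar_p), is.numeric(sigma_c),
            length(eps_bar_p) == length(sigma_c), length(eps_bar_p) >= 1L)
  if (eps_bar_p[1L] != 0) {
    stop("hardening curve must start at eps_bar_p = 0", call. = FALSE)
  }
  if (length(eps_bar_p) > 1L && any(diff(eps_bar_p) <= 0)) {
    stop("eps_bar_p knots must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(sigma_c)) || any(sigma_c <= 0)) {
    stop("sigma_c must be positive and finite", call. = FALSE)
  }
  structure(list(eps_bar_p = as.numeric(eps_bar_p),
                 sigma_c = as.numeric(sigma_c)),
            class = "hardening_curve")
}

#' @export
print.hardening_curve <- function(x, ...) {
  cat(sprintf("<hardening_curve> %d knots, sigma_c(0) = %.4g MPa, range [%.4g, %.4g] MPa\n",
              length(x$eps_bar_p), x$sigma_c[1L], min(x$sigma_c), max(x$sigma_c)))
  invisible(x)
}

#' Interpolate a hardening curve
#'
#' Linear interpolation between knots, constant continuation outside the
#' table (so perfect plasticity is a one-knot table).
#'
#' @param curve a [hardening_curve()].
#' @param eps_bar_p query equivalent plastic strains (>= 0).
#' @return sigma_c values, MPa.
#' @export
sigma_c_at <- function(curve, eps_bar_p) {
  stopifnot(inherits(curve, "hardening_curve"))
  if (length(curve$eps_bar_p) == 1L) {
    return(rep(curve$sigma_c, length(eps_bar_p)))
  }
  stats::approx(curve$eps_bar_p, curve$sigma_c, xout = eps_bar_p,
                rule = 2L)$y
}

#' Hardening templates
#'
#' Ready-made hardening/softening shapes, scaled to a card's uniaxial yield
#' stress:
#'
#' * `"trabecular"`: mild post-yield softening, a long plateau, then
#'   densification hardening towards large strain — the shape of a cellular
#'   solid crushed to half its height;
#' * `"cortical"`: linear softening to a residual plateau, the behaviour of
#'   compact bone past yield;
#' * `"svm"`: trilinear effective-stress law for the softening von Mises
#'   comparator (yield, linear softening, residual plateau);
#' * `"perfect"`: perfect plasticity (constant `sigma_c`).
#'
#' @param template template name.
#' @param sigma_y uniaxial yield stress scale, MPa.
#' @return a [hardening_curve()] whose first stress equals `sigma_y`.
#' @export
hardening_template <- function(template = c("trabecular", "cortical",
                                            "svm", "perfect"),
                               sigma_y) {
  template <- match.arg(template)
  stopifnot(is.numeric(sigma_y), length(sigma_y) == 1L, sigma_y > 0)
  tab <- switch(template,
    trabecular = list(eps = c(0, 0.03, 0.25, 0.40, 0.58),
                      ratio = c(1, 0.92, 0.88, 1.15, 2.40)),
    cortical   = list(eps = c(0, 0.05, 0.30),
                      ratio = c(1, 0.50, 0.45)),
    svm        = list(eps = c(0, 0.05, 0.30),
                      ratio = c(1, 0.45, 0.45)),
    perfect    = list(eps = 0, ratio = 1))
  hardening_curve(tab$eps, tab$ratio * sigma_y)
}

#' Read / write hardening curves as CSV
#'
#' CSV columns: `eps_bar_p`, `sigma_c_mpa`.
#'
#' @param curve a [hardening_curve()].
#' @param path file path.
#' @export
write_hardening_csv <- function(curve, path) {
  stopifnot(inherits(curve, "hardening_curve"))
  utils::write.csv(data.frame(eps_bar_p = curve$eps_bar_p,
                              sigma_c_mpa = curve$sigma_c),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hardening_csv
#' @export
read_hardening_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("eps_bar_p", "sigma_c_mpa") %in% names(df))) {
    stop("hardening CSV needs columns eps_bar_p, sigma_c_mpa", call. = FALSE)
  }
  hardening_curve(df$eps_bar_p, df$sigma_c_mpa)
}
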