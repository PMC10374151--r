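#' Power law with fit statistics
#'
#' A simple container for a fitted (or published) power law `y = a * x^b`,
#' optionally carrying the correlation of the fit and the standard error of
#' the estimate (SEE) in the original units of `y`.
#'
#' @param a positive multiplicative coefficient.
#' @param b exponent.
#' @param r correlation coefficient of the fit (log-log Pearson by default;
#'   see [power_fit()]).
#' @param see standard error of the estimate, original units of `y`.
#' @return an object of class `power_law`.
#' @export
power_law <- function(a, b, r = NA_real_, see = NA_real_) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a <= 0) {
    stop("power-law coefficient `a` must be positive and finite", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 r = as.numeric(r), see = as.numeric(see)),
            class = "power_law")
}

#' Evaluate a power law
#'
#' @param law a [power_law()].
#' @param x numeric vector, must be positive.
#' @return `law$a * x^law$b`.
#' @export
eval_power_law <- function(law, x) {
  stopifnot(inherits(law, "power_law"))
  law$a * x^law$b
}

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("<power_law> y = %.6g * x^%.4g", x$a, x$b))
  if (is.finite(x$r)) cat(sprintf("  (r = %.3f)", x$r))
  if (is.finite(x$see)) cat(sprintf("  SEE = %.4g", x$see))
  cat("\n")
  invisible(x)
}

#' BMD-dependent material law set
#'
#' Bundles the power-law mappings from bone mineral density (BMD, g/ml) to
#' compressive stiffness and uniaxial yield stress, together with the
#' piecewise strength-ratio (K) law. Two fit styles are supported:
#'
#' * `"continuous"`: one power law per parameter over the whole BMD range
#'   (trabecular and cortical data pooled);
#' * `"discontinuous"`: independent trabecular (`BMD <= bmd_break`) and
#'   cortical (`BMD > bmd_break`) branches, with a jump at the break.
#'
#' The strength ratio K (uniaxial / hydrostatic yield stress) follows a single
#' power law between two clamps: `k_low` below `k_break_low` and `k_high`
#' above `bmd_break`. The clamps default to the power law itself evaluated at
#' the breakpoints and rounded to three decimals, and are validated to be
#' continuous with the power branch to within 5e-4.
#'
#' @param stiffness,yield either a single [power_law()] (continuous style) or
#'   a list with elements `trabecular` and `cortical` (discontinuous style).
#'   Units: MPa as a function of BMD in g/ml.
#' @param k_law [power_law()] for the strength ratio K(BMD) (dimensionless).
#' @param fit_style `"continuous"` or `"discontinuous"`.
#' @param bmd_break trabecular/cortical threshold, g/ml.
#' @param k_break_low lower clamp breakpoint of the K law, g/ml.
#' @param k_low,k_high clamp values of K below/above the breakpoints. Default:
#'   power branch at the breakpoint, rounded to 3 decimals.
#' @param nu_e elastic Poisson's ratio attached to every card built from the
#'   set (dimensionless).
#' @return an object of class `material_law_set`.
#' @seealso [femoral_laws()] for the published femoral parameter set.
#' @export
material_law_set <- function(stiffness, yield, k_law,
                             fit_style = c("continuous", "discontinuous"),
                             bmd_break = 0.950, k_break_low = 0.08,
                             k_low = NULL, k_high = NULL, nu_e = 0.16) {
  fit_style <- match.arg(fit_style)
  chk_branch <- function(x, what) {
    if (fit_style == "continuous") {
      if (!inherits(x, "power_law")) {
        stop(sprintf("continuous style: `%s` must be a single power_law", what),
             call. = FALSE)
      }
    } else {
      if (!is.list(x) || !inherits(x$trabecular, "power_law") ||
          !inherits(x$cortical, "power_law")) {
        stop(sprintf(
          "discontinuous style: `%s` needs `trabecular` and `cortical` power_law branches",
          what), call. = FALSE)
      }
    }
  }
  chk_branch(stiffness, "stiffness")
  chk_branch(yield, "yield")
  stopifnot(inherits(k_law, "power_law"))
  stopifnot(is.numeric(bmd_break), bmd_break > 0,
            is.numeric(k_break_low), k_break_low > 0, k_break_low < bmd_break)
  if (is.null(k_low)) k_low <- round(eval_power_law(k_law, k_break_low), 3)
  if (is.null(k_high)) k_high <- round(eval_power_law(k_law, bmd_break), 3)
  if (!(k_low > 0 && k_low < 3) || !(k_high > 0 && k_high < 3)) {
    stop("K clamps must lie in (0, 3)", call. = FALSE)
  }
  # continuity of clamps with the power branch (3-decimal rounding tolerance)
  if (abs(k_low - eval_power_law(k_law, k_break_low)) >= 5e-4 ||
      abs(k_high - eval_power_law(k_law, bmd_break)) >= 5e-4) {
    stop("K clamps are not continuous with the power branch at the breakpoints",
         call. = FALSE)
  }
  structure(list(stiffness = stiffness, yield = yield, k_law = k_law,
                 fit_style = fit_style, bmd_break = bmd_break,
                 k_break_low = k_break_low,
                 k_low = as.numeric(k_low), k_high = as.numeric(k_high),
                 nu_e = as.numeric(nu_e)),
            class = "material_law_set")
}

#' @export
print.material_law_set <- function(x, ...) {
  cat(sprintf("<material_law_set> fit: %s, BMD break %.3f g/ml\n",
              x$fit_style, x$bmd_break))
  show1 <- function(nm, l) {
    if (inherits(l, "power_law")) {
      cat(sprintf("  %-9s: %.6g * BMD^%.4g\n", nm, l$a, l$b))
    } else {
      cat(sprintf("  %-9s: trab %.6g * BMD^%.4g | cort %.6g * BMD^%.4g\n",
                  nm, l$trabecular$a, l$trabecular$b, l$cortical$a, l$cortical$b))
    }
  }
  show1("E (MPa)", x$stiffness)
  show1("sy (MPa)", x$yield)
  cat(sprintf("  K        : %.4g * BMD^%.4g, clamps %.3f (<%.2f) / %.3f (>%.3f)\n",
              x$k_law$a, x$k_law$b, x$k_low, x$k_break_low, x$k_high, x$bmd_break))
  cat(sprintf("  nu_e     : %.2f\n", x$nu_e))
  invisible(x)
}

#' Published femoral bone material laws
#'
#' The BMD-dependent material parameter mappings for human femoral bone:
#' continuous fits pool trabecular and cortical data into a single power law
#' per parameter, discontinuous fits keep separate trabecular
#' (`BMD <= 0.950 g/ml`) and cortical branches. The strength-ratio law is
#' `K = 1.361 * BMD^-0.312`, clamped at 2.993 below 0.08 g/ml and at 1.383
#' above 0.950 g/ml.
#'
#' @param fit `"continuous"` or `"discontinuous"`.
#' @return a [material_law_set()].
#' @examples
#' stiffness_of_bmd(1.0, femoral_laws("continuous"))   # 12980 MPa
#' yield_of_bmd(1.0, femoral_laws("discontinuous"))    # 111.5 MPa (cortical)
#' k_of_bmd(c(0.05, 0.3, 1.2))
#' @export
femoral_laws <- function(fit = c("continuous", "discontinuous")) {
  fit <- match.arg(fit)
  k_law <- power_law(1.361, -0.312)
  if (fit == "continuous") {
    material_law_set(
      stiffness = power_law(12980, 2.567, r = 0.745, see = 59.24),
      yield     = power_law(109.3, 1.872, r = 0.881, see = 0.450),
      k_law = k_law, fit_style = "continuous")
  } else {
    material_law_set(
      stiffness = list(
        trabecular = power_law(5113, 1.653, r = 0.768, see = 46.76),
        cortical   = power_law(13750, 2.429, r = 0.725, see = 67.43)),
      yield = list(
        trabecular = power_law(79.36, 1.553, r = 0.836, see = 0.742),
        cortical   = power_law(111.5, 1.800, r = 0.887, see = 0.361)),
      k_law = k_law, fit_style = "discontinuous")
  }
}

#' Strength ratio K as a function of BMD
#'
#' Piecewise law for the ratio of uniaxial to hydrostatic yield stress:
#' constant `k_low` below the lower breakpoint, a power law in between, and
#' constant `k_high` above the trabecular/cortical threshold. With the default
#' femoral laws: K = 2.993 for BMD < 0.08, 1.361*BMD^-0.312 for
#' 0.08 <= BMD <= 0.950, and 1.383 above.
#'
#' @param bmd numeric vector of BMD values, g/ml; must be positive.
#' @param laws a [material_law_set()].
#' @return dimensionless K, same length as `bmd`.
#' @export
k_of_bmd <- function(bmd, laws = femoral_laws()) {
  stopifnot(inherits(laws, "material_law_set"))
  if (any(!is.finite(bmd)) || any(bmd <= 0)) {
    stop("`bmd` must be positive and finite", call. = FALSE)
  }
  k <- eval_power_law(laws$k_law, bmd)
  k[bmd < laws$k_break_low] <- laws$k_low
  k[bmd > laws$bmd_break] <- laws$k_high
  k
}

.eval_branched <- function(entry, bmd, laws, branch, what) {
  if (laws$fit_style == "continuous") {
    if (branch != "auto") {
      stop(sprintf("branch selection requires a discontinuous law set (%s)", what),
           call. = FALSE)
    }
    return(eval_power_law(entry, bmd))
  }
  if (branch == "trabecular") return(eval_power_law(entry$trabecular, bmd))
  if (branch == "cortical") return(eval_power_law(entry$cortical, bmd))
  ifelse(bmd <= laws$bmd_break,
         eval_power_law(entry$trabecular, bmd),
         eval_power_law(entry$cortical, bmd))
}

#' Compressive stiffness from BMD
#'
#' Evaluates the stiffness mapping of a law set. For a discontinuous set the
#' trabecular branch applies for `BMD <= bmd_break` and the cortical branch
#' above; `branch` forces evaluation of one branch as a bare formula
#' (extrapolating beyond its fitted range).
#'
#' @param bmd BMD, g/ml (positive).
#' @param laws a [material_law_set()].
#' @param branch `"auto"` (default), `"trabecular"` or `"cortical"`.
#' @return Young's modulus, MPa.
#' @export
stiffness_of_bmd <- function(bmd, laws = femoral_laws(),
                             branch = c("auto", "trabecular", "cortical")) {
  branch <- match.arg(branch)
  if (any(!is.finite(bmd)) || any(bmd <= 0)) {
    stop("`bmd` must be positive and finite", call. = FALSE)
  }
  .eval_branched(laws$stiffness, bmd, laws, branch, "stiffness")
}

#' Uniaxial yield stress from BMD
#'
#' @inheritParams stiffness_of_bmd
#' @return uniaxial compressive yield stress, MPa.
#' @export
yield_of_bmd <- function(bmd, laws = femoral_laws(),
                         branch = c("auto", "trabecular", "cortical")) {
  branch <- match.arg(branch)
  if (any(!is.finite(bmd)) || any(bmd <= 0)) {
    stop("`bmd` must be positive and finite", call. = FALSE)
  }
  .eval_branched(laws$yield, bmd, laws, branch, "yield")
}

#' Plastic Poisson's ratio from the strength ratio
#'
#' For the crushable-foam yield surface with associated flow, the plastic
#' Poisson's ratio in uniaxial compression is `(3 - K^2) / 6`. It is 0.5 in
#' the incompressible (von Mises, K -> 0) limit, crosses zero at K = sqrt(3),
#' and is negative (volumetric collapse) for larger K.
#'
#' @param K strength ratio, must lie in (0, 3).
#' @return plastic Poisson's ratio, dimensionless.
#' @export
nu_p_of_k <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0) || any(K >= 3)) {
    stop("strength ratio K must lie in (0, 3)", call. = FALSE)
  }
  (3 - K^2) / 6
}

.law_to_list <- function(l) list(a = l$a, b = l$b, r = l$r, see = l$see)
.law_from_list <- function(l) power_law(l$a, l$b,
                                        r = if (is.null(l$r)) NA_real_ else l$r,
                                        see = if (is.null(l$see)) NA_real_ else l$see)

#' Write / read a material law set as JSON
#'
#' The JSON carries explicit units (MPa vs g/ml) and the fit style; the reader
#' re-validates all invariants through [material_law_set()].
#'
#' @param laws a [material_law_set()].
#' @param path file path.
#' @return `write_law_set` returns `path` invisibly; `read_law_set` returns a
#'   [material_law_set()].
#' @export
write_law_set <- function(laws, path) {
  stopifnot(inherits(laws, "material_law_set"))
  ser <- function(x) {
    if (inherits(x, "power_law")) .law_to_list(x)
    else list(trabecular = .law_to_list(x$trabecular),
              cortical = .law_to_list(x$cortical))
  }
  obj <- list(
    format = "bonefoam_law_set", version = 1L,
    units = list(bmd = "g/ml", stiffness = "MPa", yield = "MPa"),
    fit_style = laws$fit_style, bmd_break = laws$bmd_break,
    k_break_low = laws$k_break_low, k_low = laws$k_low, k_high = laws$k_high,
    nu_e = laws$nu_e,
    stiffness = ser(laws$stiffness), yield = ser(laws$yield),
    k_law = .law_to_list(laws$k_law))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_law_set
#' @export
read_law_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "bonefoam_law_set") {
    stop("not a bonefoam law-set JSON file", call. = FALSE)
  }
  des <- function(x, style) {
    if (style == "continuous") .law_from_list(x)
    else list(trabecular = .law_from_list(x$trabecular),
              cortical = .law_from_list(x$cortical))
  }
  material_law_set(
    stiffness = des(obj$stiffness, obj$fit_style),
    yield = des(obj$yield, obj$fit_style),
    k_law = .law_from_list(obj$k_law),
    fit_style = obj$fit_style, bmd_break = obj$bmd_break,
    k_break_low = obj$k_break_low, k_low = obj$k_low, k_high = obj$k_high,
    nu_e = obj$nu_e)
}
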