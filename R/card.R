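#' Construct a material card directly
#'
#' A material card is the complete parameter set of one material point:
#' elasticity (`E`, `nu_e`), uniaxial yield stress, and — for the crushable
#' foam model — the strength ratio `K`, hydrostatic yield stress
#' `p_y = sigma_y / K`, plastic Poisson's ratio `nu_p = (3 - K^2)/6`, and a
#' hardening curve. The softening von Mises comparator (`model = "svm"`)
#' needs no pressure parameters; its `K`, `p_y` and `nu_p` are `NA`.
#'
#' @param bmd bone mineral density the card represents, g/ml (may be `NA` for
#'   cards built from direct measurements).
#' @param E Young's modulus, MPa.
#' @param sigma_y uniaxial compressive yield stress, MPa.
#' @param K strength ratio in (0, 3); required for `model = "icf"`.
#' @param nu_e elastic Poisson's ratio.
#' @param model `"icf"` or `"svm"`.
#' @param hardening a [hardening_curve()], a template name accepted by
#'   [hardening_template()], or `NULL` for perfect plasticity. The curve's
#'   initial stress must equal `sigma_y` (templates are scaled automatically).
#' @return object of class `material_card`.
#' @seealso [build_material_card()] to derive a card from BMD and a law set.
#' @export
material_card <- function(bmd = NA_real_, E, sigma_y, K = NULL,
                          nu_e = 0.16, model = c("icf", "svm"),
                          hardening = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(E), length(E) == 1L, is.numeric(sigma_y),
            length(sigma_y) == 1L)
  if (!is.finite(E) || E <= 0) stop("E must be positive", call. = FALSE)
  if (!is.finite(sigma_y) || sigma_y <= 0) {
    stop("sigma_y must be positive", call. = FALSE)
  }
  if (!is.finite(nu_e) || nu_e < 0 || nu_e >= 0.5) {
    stop("nu_e must lie in [0, 0.5)", call. = FALSE)
  }
  if (model == "icf") {
    if (is.null(K)) stop("icf card requires the strength ratio K", call. = FALSE)
    if (!is.finite(K) || K <= 0 || K >= 3) {
      stop("strength ratio K must lie in (0, 3)", call. = FALSE)
    }
    p_y <- sigma_y / K
    nu_p <- nu_p_of_k(K)
  } else {
    K <- NA_real_; p_y <- NA_real_; nu_p <- NA_real_
  }
  if (is.null(hardening)) hardening <- "perfect"
  if (is.character(hardening)) {
    hardening <- hardening_template(hardening, sigma_y)
  }
  stopifnot(inherits(hardening, "hardening_curve"))
  if (abs(hardening$sigma_c[1L] - sigma_y) > 1e-9 * sigma_y) {
    stop("hardening curve must start at the card's sigma_y", call. = FALSE)
  }
  card <- structure(list(bmd = as.numeric(bmd), E = as.numeric(E),
                         nu_e = as.numeric(nu_e),
                         sigma_y_uni = as.numeric(sigma_y),
                         p_y_hyd = as.numeric(p_y), K = as.numeric(K),
                         nu_p = as.numeric(nu_p), model = model,
                         hardening = hardening),
                    class = "material_card")
  validate_material_card(card)
  card
}

#' Validate a material card's internal consistency
#'
#' Checks `K = sigma_y_uni / p_y_hyd` and `nu_p = (3 - K^2)/6` to 1e-9
#' relative, `0 < K < 3`, `E > 0` (crushable foam cards only for the pressure
#' identities).
#'
#' @param card a [material_card()].
#' @return `card`, invisibly; errors on violation.
#' @export
validate_material_card <- function(card) {
  stopifnot(inherits(card, "material_card"))
  if (!is.finite(card$E) || card$E <= 0) stop("invalid card: E <= 0", call. = FALSE)
  if (card$model == "icf") {
    if (!(card$K > 0 && card$K < 3)) {
      stop("invalid card: K outside (0, 3)", call. = FALSE)
    }
    if (abs(card$sigma_y_uni / card$p_y_hyd - card$K) > 1e-9 * card$K) {
      stop("invalid card: sigma_y_uni / p_y_hyd != K", call. = FALSE)
    }
    nu_ref <- (3 - card$K^2) / 6
    if (abs(card$nu_p - nu_ref) > 1e-9 * max(1, abs(nu_ref))) {
      stop("invalid card: nu_p != (3 - K^2)/6", call. = FALSE)
    }
  }
  invisible(card)
}

#' @export
print.material_card <- function(x, ...) {
  cat(sprintf("<material_card> model %s", x$model))
  if (is.finite(x$bmd)) cat(sprintf(", BMD %.3f g/ml", x$bmd))
  cat("\n")
  cat(sprintf("  E = %.5g MPa, nu_e = %.2f, sigma_y = %.5g MPa\n",
              x$E, x$nu_e, x$sigma_y_uni))
  if (x$model == "icf") {
    cat(sprintf("  K = %.4f, p_y = %.5g MPa, nu_p = %.4f\n",
                x$K, x$p_y_hyd, x$nu_p))
  }
  cat(sprintf("  hardening: %d knot(s)\n", length(x$hardening$eps_bar_p)))
  invisible(x)
}

#' Build a material card from BMD
#'
#' Maps one BMD value to a complete card through a law set: `E` and `sigma_y`
#' from the power laws, `K` from [k_of_bmd()], `p_y = sigma_y / K`, `nu_p`
#' from [nu_p_of_k()], and the elastic Poisson's ratio carried by the law set
#' (0.16 for the femoral laws).
#'
#' @param bmd BMD, g/ml (positive scalar).
#' @param laws a [material_law_set()].
#' @param model `"icf"` or `"svm"`.
#' @param hardening `"auto"` (trabecular template at or below the BMD break,
#'   cortical above), a template name, a [hardening_curve()], or `NULL` for
#'   perfect plasticity. The svm model defaults to its trilinear template.
#' @return a [material_card()].
#' @examples
#' build_material_card(0.3, femoral_laws("continuous"))
#' @export
build_material_card <- function(bmd, laws = femoral_laws(),
                                model = c("icf", "svm"),
                                hardening = "auto") {
  model <- match.arg(model)
  stopifnot(is.numeric(bmd), length(bmd) == 1L)
  if (!is.finite(bmd) || bmd <= 0) stop("`bmd` must be positive", call. = FALSE)
  E <- stiffness_of_bmd(bmd, laws)
  sy <- yield_of_bmd(bmd, laws)
  if (identical(hardening, "auto")) {
    hardening <- if (model == "svm") "svm"
                 else if (bmd <= laws$bmd_break) "trabecular" else "cortical"
  }
  K <- if (model == "icf") k_of_bmd(bmd, laws) else NULL
  material_card(bmd = bmd, E = E, sigma_y = sy, K = K, nu_e = laws$nu_e,
                model = model, hardening = hardening)
}

#' Write / read material cards as JSON
#'
#' @param card a [material_card()].
#' @param path file path.
#' @export
write_material_card <- function(card, path) {
  validate_material_card(card)
  obj <- list(format = "bonefoam_material_card", version = 1L,
              units = list(E = "MPa", sigma_y_uni = "MPa", p_y_hyd = "MPa",
                           bmd = "g/ml"),
              model = card$model, bmd = card$bmd, E = card$E,
              nu_e = card$nu_e, sigma_y_uni = card$sigma_y_uni,
              p_y_hyd = card$p_y_hyd, K = card$K, nu_p = card$nu_p,
              hardening = list(eps_bar_p = card$hardening$eps_bar_p,
                               sigma_c = card$hardening$sigma_c))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_material_card
#' @export
read_material_card <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "bonefoam_material_card") {
    stop("not a bonefoam material-card JSON file", call. = FALSE)
  }
  material_card(bmd = if (is.null(obj$bmd)) NA_real_ else obj$bmd,
                E = obj$E, sigma_y = obj$sigma_y_uni,
                K = if (obj$model == "icf") obj$K else NULL,
                nu_e = obj$nu_e, model = obj$model,
                hardening = hardening_curve(obj$hardening$eps_bar_p,
                                            obj$hardening$sigma_c))
}
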