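#' Fit a phantom HU-to-density calibration
#'
#' Ordinary least-squares line through the calibration phantom inserts:
#' `density [mg/ml] = slope * HU + intercept`. At least two distinct HU values
#' are required; identical HU across all inserts is a degenerate fit.
#'
#' @param known_densities reference insert densities, mg/ml (e.g. 0, 50, 100,
#'   200 mg/ml calcium hydroxyapatite).
#' @param measured_hu mean Hounsfield units measured in each insert.
#' @return an object of class `phantom_calibration` with fields `slope`
#'   (mg/ml per HU), `intercept` (mg/ml), `known_densities`, `measured_hu`,
#'   `residuals` and `r_squared`.
#' @export
fit_hu_calibration <- function(known_densities, measured_hu) {
  stopifnot(is.numeric(known_densities), is.numeric(measured_hu))
  if (length(known_densities) != length(measured_hu) ||
      length(known_densities) < 2L) {
    stop("need >= 2 paired (density, HU) points", call. = FALSE)
  }
  if (length(unique(measured_hu)) < 2L) {
    stop("degenerate calibration: all inserts have the same HU", call. = FALSE)
  }
  fit <- stats::lm(known_densities ~ measured_hu)
  cf <- unname(stats::coef(fit))
  slope <- cf[2L]
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive (density increases with HU)",
         call. = FALSE)
  }
  r2 <- if (stats::var(known_densities) > 0) {
    suppressWarnings(summary(fit)$r.squared)   # exact fits are legitimate here
  } else NA_real_
  structure(list(slope = slope, intercept = cf[1L],
                 known_densities = as.numeric(known_densities),
                 measured_hu = as.numeric(measured_hu),
                 residuals = unname(stats::residuals(fit)),
                 r_squared = r2),
            class = "phantom_calibration")
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat(sprintf(
    "<phantom_calibration> density [mg/ml] = %.6g * HU + %.6g  (n = %d, R^2 = %s)\n",
    x$slope, x$intercept, length(x$measured_hu),
    ifelse(is.finite(x$r_squared), sprintf("%.4f", x$r_squared), "NA")))
  invisible(x)
}

#' Convert Hounsfield units to BMD
#'
#' Applies the fitted calibration line and converts mg/ml to g/ml. Values
#' below `floor_g_ml` (marrow, air) are clamped to the floor; clamping is part
#' of the contract, no error is raised.
#'
#' @param hu numeric vector or array of Hounsfield units.
#' @param calibration a [fit_hu_calibration()] result.
#' @param floor_g_ml lower clamp for the returned BMD, g/ml.
#' @return BMD in g/ml with the shape of `hu`.
#' @export
hu_to_bmd <- function(hu, calibration, floor_g_ml = 0.001) {
  stopifnot(inherits(calibration, "phantom_calibration"))
  bmd <- (calibration$slope * hu + calibration$intercept) / 1000
  bmd[bmd < floor_g_ml] <- floor_g_ml
  bmd
}

#' Invert a calibration: BMD to HU
#'
#' Used by the synthetic CT generator to paint voxels with the HU that would
#' have produced a given BMD under `calibration`.
#'
#' @inheritParams hu_to_bmd
#' @param bmd_g_ml BMD values, g/ml.
#' @return Hounsfield units with the shape of `bmd_g_ml`.
#' @export
bmd_to_hu <- function(bmd_g_ml, calibration) {
  stopifnot(inherits(calibration, "phantom_calibration"))
  (bmd_g_ml * 1000 - calibration$intercept) / calibration$slope
}

#' Read / write phantom calibration tables
#'
#' Phantom tables are CSV files with columns `density_mg_ml` and `hu_mean`.
#' Calibrations serialize to JSON.
#'
#' @param path file path.
#' @return `read_phantom_csv` returns a data.frame;
#'   `calibrate_phantom_csv` fits and returns a `phantom_calibration`.
#' @export
read_phantom_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("density_mg_ml", "hu_mean")
  if (!all(need %in% names(df))) {
    stop("phantom CSV needs columns density_mg_ml, hu_mean", call. = FALSE)
  }
  df
}

#' @rdname read_phantom_csv
#' @export
calibrate_phantom_csv <- function(path) {
  df <- read_phantom_csv(path)
  fit_hu_calibration(df$density_mg_ml, df$hu_mean)
}

#' @rdname read_phantom_csv
#' @param calibration a `phantom_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "phantom_calibration"))
  obj <- list(format = "bonefoam_calibration", version = 1L,
              units = list(slope = "mg/ml per HU", intercept = "mg/ml"),
              slope = calibration$slope, intercept = calibration$intercept,
              known_densities = calibration$known_densities,
              measured_hu = calibration$measured_hu,
              r_squared = calibration$r_squared)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname read_phantom_csv
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "bonefoam_calibration") {
    stop("not a bonefoam calibration JSON file", call. = FALSE)
  }
  fit_hu_calibration(obj$known_densities, obj$measured_hu)
}
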