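#' Power-law regression on log-log axes
#'
#' Fits `y = a * x^b` by ordinary least squares of `log(y)` on `log(x)`.
#' The correlation is reported both as the log-log Pearson coefficient and as
#' Spearman's rho (published tables differ in which they quote), and the
#' standard error of the estimate (SEE) is computed in the original units of
#' `y` with `n - 2` degrees of freedom. An optional nonlinear refinement
#' re-minimizes the original-units residual sum of squares starting from the
#' log-log solution.
#'
#' @param x,y positive numeric vectors, length >= 3.
#' @param refine run a nonlinear least-squares refinement (`stats::nls`).
#' @param conf_level confidence level for the stored coefficient intervals.
#' @return a [power_law()] carrying additionally `n`, `r_spearman`, `ci_a`,
#'   `ci_b` (confidence intervals from the log-log fit) and `degenerate`
#'   (TRUE when `y` does not vary, in which case `r` is `NA`).
#' @export
power_fit <- function(x, y, refine = FALSE, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    stop("power_fit requires positive finite x and y", call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  cf <- unname(stats::coef(fit))
  a <- exp(cf[1L]); b <- cf[2L]
  degenerate <- stats::sd(ly) < 1e-12
  r <- if (degenerate) NA_real_ else stats::cor(lx, ly)
  r_sp <- if (degenerate) NA_real_ else {
    stats::cor(x, y, method = "spearman")
  }
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  if (refine && !degenerate) {
    nl <- tryCatch(
      stats::nls(y ~ a * x^b, start = list(a = a, b = b),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cfn <- stats::coef(nl)
      a <- unname(cfn["a"]); b <- unname(cfn["b"])
    }
  }
  see <- sqrt(sum((y - a * x^b)^2) / (length(x) - 2L))
  out <- power_law(a, b, r = r, see = see)
  out$n <- length(x)
  out$r_spearman <- r_sp
  out$ci_a <- exp(unname(ci[1L, ]))
  out$ci_b <- unname(ci[2L, ])
  out$degenerate <- degenerate
  out
}

#' Synthetic cortical pseudo-records
#'
#' Literature-style cortical data points to pool with trabecular specimens
#' when fitting continuous or discontinuous law sets (no raw cortical test
#' data ships with the package). The points are drawn around the cortical
#' power laws of a reference law set with small multiplicative noise and are
#' synthetic stand-ins, not measurements.
#'
#' @param n number of pseudo-records.
#' @param bmd_range cortical BMD range, g/ml.
#' @param laws reference [material_law_set()] (discontinuous).
#' @param noise_cv multiplicative coefficient of variation.
#' @param seed RNG seed.
#' @return data.frame with columns `specimen_id`, `bmd`, `mode`, `E`,
#'   `sigma_y`, `p_y`, `excluded`, `reason`, matching [reduce_record()] rows.
#' @export
cortical_pseudo_records <- function(n = 12, bmd_range = c(0.96, 1.25),
                                    laws = femoral_laws("discontinuous"),
                                    noise_cv = 0.05, seed = 1L) {
  stopifnot(n >= 3, bmd_range[1L] > 0, bmd_range[2L] > bmd_range[1L])
  rng <- .seeded_rng(seed)
  bmd <- rng$runif(n, bmd_range[1L], bmd_range[2L])
  sdl <- sqrt(log(1 + noise_cv^2))
  E <- stiffness_of_bmd(bmd, laws, branch = "cortical") *
    exp(rng$rnorm(n, -sdl^2 / 2, sdl))
  sy <- yield_of_bmd(bmd, laws, branch = "cortical") *
    exp(rng$rnorm(n, -sdl^2 / 2, sdl))
  data.frame(specimen_id = sprintf("cortical_pseudo_%02d", seq_len(n)),
             bmd = bmd, mode = "uniaxial", E = E, sigma_y = sy,
             p_y = NA_real_, excluded = FALSE, reason = "synthetic cortical",
             stringsAsFactors = FALSE)
}

#' Fit a material law set from reduced specimen data
#'
#' Takes a table of reduced records (one row per specimen, as produced by
#' [reduce_record()] / [reduce_manifest()]) and fits BMD power laws for
#' stiffness (all records: [reduce_record()] reports a Young's modulus for
#' both testing modes), uniaxial yield stress (uniaxial records) and
#' hydrostatic yield stress (confined records). The continuous style pools
#' all data into one law per parameter; the discontinuous style fits
#' independent branches on each side of `bmd_break` (an empty branch is a
#' configuration error).
#'
#' The strength-ratio law is obtained either from the ratio of the fitted
#' uniaxial and hydrostatic yield laws (`k_fit = "ratio"`:
#' `a = a_u / a_p`, `b = b_u - b_p`) or by a direct power fit on per-pair
#' ratios when a `pair_id` column links uniaxial and confined specimens
#' (`k_fit = "paired"`). `"auto"` uses pairs when they exist. The K clamps
#' are re-derived at `k_break_low` and `bmd_break` from the fitted law;
#' where the fitted law would exceed the physical admissibility bound
#' `K < 3` at `k_break_low`, the lower breakpoint moves up to the BMD at
#' which the law crosses 2.993 — the same construction that ties the
#' published clamp to its breakpoint.
#'
#' @param reduced data.frame of reduced records (columns `bmd`, `mode`, `E`,
#'   `sigma_y`, `p_y`, `excluded`; optional `pair_id`).
#' @param fit_style `"continuous"` or `"discontinuous"`.
#' @param bmd_break trabecular/cortical threshold, g/ml.
#' @param k_break_low lower K clamp breakpoint, g/ml.
#' @param cortical optional extra rows (e.g. [cortical_pseudo_records()]) to
#'   pool with the measured records.
#' @param k_fit `"auto"`, `"ratio"` or `"paired"`.
#' @param nu_e elastic Poisson's ratio to attach.
#' @return a [material_law_set()].
#' @export
fit_law_set <- function(reduced, fit_style = c("continuous", "discontinuous"),
                        bmd_break = 0.950, k_break_low = 0.08,
                        cortical = NULL, k_fit = c("auto", "ratio", "paired"),
                        nu_e = 0.16) {
  fit_style <- match.arg(fit_style)
  k_fit <- match.arg(k_fit)
  if (!is.null(cortical)) {
    keep <- intersect(names(reduced), names(cortical))
    reduced <- rbind(reduced[keep], cortical[keep])
  }
  reduced <- reduced[!reduced$excluded, , drop = FALSE]
  uni <- reduced[reduced$mode == "uniaxial", , drop = FALSE]
  conf <- reduced[reduced$mode == "confined", , drop = FALSE]
  if (nrow(uni) < 3L) stop("need >= 3 uniaxial records", call. = FALSE)

  fit_param <- function(bmd, val, what) {
    ok <- is.finite(val) & val > 0
    if (fit_style == "continuous") {
      return(power_fit(bmd[ok], val[ok]))
    }
    lo <- ok & bmd <= bmd_break
    hi <- ok & bmd > bmd_break
    if (sum(lo) < 3L || sum(hi) < 3L) {
      stop(sprintf(
        "discontinuous fit of %s needs >= 3 records on each side of %.3f g/ml",
        what, bmd_break), call. = FALSE)
    }
    list(trabecular = power_fit(bmd[lo], val[lo]),
         cortical = power_fit(bmd[hi], val[hi]))
  }
  law_E <- fit_param(reduced$bmd, reduced$E, "stiffness")
  law_sy <- fit_param(uni$bmd, uni$sigma_y, "yield stress")

  if (nrow(conf) < 3L) stop("need >= 3 confined records for the K law",
                            call. = FALSE)
  okp <- is.finite(conf$p_y) & conf$p_y > 0
  law_py <- power_fit(conf$bmd[okp], conf$p_y[okp])

  have_pairs <- "pair_id" %in% names(reduced) &&
    any(!is.na(reduced$pair_id))
  use_paired <- (k_fit == "paired") || (k_fit == "auto" && have_pairs)
  if (use_paired && !have_pairs) {
    stop("k_fit = 'paired' requires a pair_id column linking the modes",
         call. = FALSE)
  }
  if (use_paired) {
    m <- merge(uni[c("pair_id", "bmd", "sigma_y")],
               conf[c("pair_id", "p_y")], by = "pair_id")
    m <- m[is.finite(m$sigma_y) & is.finite(m$p_y) & m$p_y > 0, ]
    if (nrow(m) < 3L) stop("fewer than 3 usable specimen pairs", call. = FALSE)
    k_law <- power_fit(m$bmd, m$sigma_y / m$p_y)
  } else {
    ## ratio of the trabecular-side yield laws (K is BMD-dependent only in
    ## the trabecular regime; cortical K is the upper clamp)
    law_u <- if (fit_style == "continuous") law_sy else law_sy$trabecular
    k_law <- power_law(law_u$a / law_py$a, law_u$b - law_py$b)
  }

  ## lower clamp from the admissibility bound 0 < K < 3: if the fitted law
  ## is above 2.993 at the requested breakpoint, the breakpoint is wherever
  ## the law crosses that value
  k_bound <- 2.993
  if (k_law$b < 0 && eval_power_law(k_law, k_break_low) > k_bound) {
    k_break_low <- min((k_bound / k_law$a)^(1 / k_law$b), bmd_break / 2)
  }

  material_law_set(stiffness = law_E, yield = law_sy, k_law = k_law,
                   fit_style = fit_style, bmd_break = bmd_break,
                   k_break_low = k_break_low, nu_e = nu_e)
}

#' Reduce a whole manifest of specimen records
#'
#' @param records list of [specimen_record()] objects.
#' @param nu_e,offset passed to [reduce_record()].
#' @return data.frame with one row per record.
#' @export
reduce_manifest <- function(records, nu_e = 0.16, offset = 0.002) {
  rows <- lapply(records, reduce_record, nu_e = nu_e, offset = offset)
  do.call(rbind, rows)
}
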