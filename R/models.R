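#' Dose-response model equations
#'
#' The three nested inhibition models used throughout the package, as pure
#' functions of drug concentration. All concentrations are in nanomolar (nM),
#' the package's canonical internal unit; see [as_nM()] for conversion.
#'
#' * **Monophasic** (single-target binding):
#'   \eqn{I = D / (D + IC_{50})}.
#' * **Modified Hill**:
#'   \eqn{I = I_{max} D^n / (IC_{50}^{*n} + D^n)}. The zero-dose inhibition
#'   term is fixed at 0 because no inhibition can occur without drug.
#' * **Biphasic** (two-site):
#'   \eqn{I = F_1 D/(D + K_{d1}) + (1 - F_1) D/(D + K_{d2})},
#'   where \eqn{F_1} is the fraction of viability attributable to the
#'   target-specific (high-affinity) phase and \eqn{K_{d1} \le K_{d2}}.
#'
#' All three return the inhibition fraction \eqn{I(d)}; the corresponding
#' relative viability is \eqn{1 - I(d)}.
#'
#' @param d Numeric vector of concentrations in nM, `>= 0`.
#' @param ic50 Monophasic half-inhibition concentration (nM), `> 0`.
#' @param i_max Maximal inhibition at saturating dose, in `(0, 1.2]`.
#' @param ic50_star Hill half-of-maximal-inhibition concentration (nM).
#' @param n Hill coefficient, `> 0`.
#' @param f1 Target-specific fraction of viability, in `[0, 1]`.
#' @param kd1,kd2 Apparent affinities (nM) of the target-specific and
#'   off-target phases; convention `kd1 <= kd2`.
#' @return Numeric vector of inhibition fractions, same length as `d`.
#' @examples
#' eval_monophasic(150, ic50 = 100)          # 0.6
#' eval_hill(100, i_max = 0.8, ic50_star = 100, n = 0.5)  # 0.4
#' eval_biphasic(19.8, f1 = 0.57, kd1 = 19.8, kd2 = 1e6)
#' @name dose_response_models
NULL

#' @rdname dose_response_models
#' @export
eval_monophasic <- function(d, ic50) {
  stopifnot(all(d >= 0), ic50 > 0)
  d / (d + ic50)
}

#' @rdname dose_response_models
#' @export
eval_hill <- function(d, i_max, ic50_star, n) {
  stopifnot(all(d >= 0), i_max > 0, ic50_star > 0, n > 0)
  dn <- d^n
  i_max * dn / (ic50_star^n + dn)
}

#' @rdname dose_response_models
#' @export
eval_biphasic <- function(d, f1, kd1, kd2) {
  stopifnot(all(d >= 0), f1 >= 0, f1 <= 1, kd1 > 0, kd2 > 0)
  f1 * d / (d + kd1) + (1 - f1) * d / (d + kd2)
}

#' Closed-form inhibitory concentration ICx
#'
#' Inverts each dose-response model analytically to find the concentration
#' producing a given inhibition level `x`.
#'
#' For the monophasic model the inverse is \eqn{x \cdot IC_{50} / (1 - x)};
#' for the Hill model \eqn{IC_{50}^{*} (x / (I_{max} - x))^{1/n}}. For the
#' biphasic model, clearing denominators gives the quadratic
#' \deqn{(1 - x) D^2 + [F_1 K_{d2} + (1 - F_1) K_{d1} - x (K_{d1} + K_{d2})] D
#'   - x K_{d1} K_{d2} = 0,}
#' whose unique positive root is returned (computed in the numerically
#' stable form that avoids cancellation).
#'
#' @param x Target inhibition fraction. Must be strictly between 0 and the
#'   model's supremum (`1` for monophasic/biphasic, `i_max` for Hill).
#' @inheritParams dose_response_models
#' @return Concentration in nM at which the model reaches inhibition `x`.
#' @examples
#' icx_monophasic(0.5, ic50 = 100)   # 100 by definition
#' icx_biphasic(0.5, f1 = 1, kd1 = 165, kd2 = 1e6)  # 165
#' @name analytic_icx
NULL

#' @rdname analytic_icx
#' @export
icx_monophasic <- function(x, ic50) {
  stopifnot(ic50 > 0)
  if (any(x <= 0 | x >= 1)) {
    stop("inhibition level x = ", paste(x[x <= 0 | x >= 1], collapse = ", "),
         " is unattainable for the monophasic model (requires 0 < x < 1)",
         call. = FALSE)
  }
  x * ic50 / (1 - x)
}

#' @rdname analytic_icx
#' @export
icx_hill <- function(x, i_max, ic50_star, n) {
  stopifnot(i_max > 0, ic50_star > 0, n > 0)
  if (any(x <= 0 | x >= i_max)) {
    stop("inhibition level x = ", paste(x[x <= 0 | x >= i_max], collapse = ", "),
         " is unattainable for this Hill model (requires 0 < x < i_max = ",
         i_max, ")", call. = FALSE)
  }
  ic50_star * (x / (i_max - x))^(1 / n)
}

#' @rdname analytic_icx
#' @export
icx_biphasic <- function(x, f1, kd1, kd2) {
  stopifnot(f1 >= 0, f1 <= 1, kd1 > 0, kd2 > 0)
  if (any(x <= 0 | x >= 1)) {
    stop("inhibition level x = ", paste(x[x <= 0 | x >= 1], collapse = ", "),
         " is unattainable for the biphasic model (requires 0 < x < 1)",
         call. = FALSE)
  }
  a <- 1 - x
  b <- f1 * kd2 + (1 - f1) * kd1 - x * (kd1 + kd2)
  cc <- -x * kd1 * kd2
  # stable quadratic: c < 0 and a > 0 guarantee one positive root
  disc <- sqrt(b^2 - 4 * a * cc)
  q <- -(b + sign(b) * disc) / 2
  root1 <- q / a
  root2 <- cc / q
  ifelse(root1 > 0, root1, root2)
}

#' Root mean square error between observed and model-predicted viability
#'
#' The fitting objective: RMSE over all replicate points between observed
#' relative viability and the model's predicted viability \eqn{1 - I(d)}.
#' Because observed and predicted differ by the same quantity on either
#' scale, this equals the inhibition-scale RMSE.
#'
#' @param data A data frame with columns `conc_nM` and `viability`
#'   (one row per replicate point).
#' @param inhibition_fn Function mapping a concentration vector (nM) to
#'   predicted inhibition fractions.
#' @param use_means If `TRUE`, collapse replicates to per-dose means before
#'   computing the RMSE. Default uses all replicate points.
#' @return Nonnegative scalar RMSE (viability units).
#' @export
#' @examples
#' d <- tibble::tibble(conc_nM = c(10, 100, 1000),
#'                     viability = c(0.9, 0.5, 0.1))
#' rmse_curve(d, function(d) eval_monophasic(d, ic50 = 100))
rmse_curve <- function(data, inhibition_fn, use_means = FALSE) {
  if (nrow(data) == 0L) {
    stop("cannot compute RMSE on an empty curve", call. = FALSE)
  }
  if (use_means) {
    data <- dplyr::summarise(dplyr::group_by(data, .data$conc_nM),
                             viability = mean(.data$viability),
                             .groups = "drop")
  }
  pred <- 1 - inhibition_fn(data$conc_nM)
  sqrt(mean((data$viability - pred)^2))
}

#' Convert concentrations to canonical nanomolar
#'
#' @param value Numeric concentrations.
#' @param unit One of `"nM"` or `"uM"` (micromolar; `"µM"` accepted).
#' @return Concentrations in nM.
#' @export
#' @examples
#' as_nM(1.28, "uM")  # 1280
as_nM <- function(value, unit = "nM") {
  unit <- gsub("µ", "u", unit)
  factor <- switch(tolower(unit), nm = 1, um = 1e3, mm = 1e6,
                   stop("unknown concentration unit: ", unit, call. = FALSE))
  value * factor
}

#' Standard concentration grids
#'
#' The two dilution series the package emulates: a 16-point grid spanning
#' 0.6 nM to 20 uM (2x serial dilution from the top dose), and the
#' 9-point high-throughput-screen grid from 5 nM to 1.28 uM (2x series).
#'
#' @return Numeric vector of concentrations in nM, ascending.
#' @export
#' @examples
#' grid_sixteen_point()
#' grid_gdsc_nine_point()
grid_sixteen_point <- function() {
  sort(20000 / 2^(0:15))
}

#' @rdname grid_sixteen_point
#' @export
grid_gdsc_nine_point <- function() {
  5 * 2^(0:8)
}
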