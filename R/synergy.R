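#' Estimate the concentration producing x fraction inhibition (ICx)
#'
#' Two estimation routes are available. `method = "interpolated"` is the
#' reproducible analogue of reading the value off a graph: replicate-mean
#' inhibition is linearly interpolated against log10(concentration) between
#' the two measured points bracketing `x`. `method = "from_fit"` fits the
#' biphasic model and inverts it analytically ([icx_biphasic()]).
#'
#' When the maximum observed (or fitted) inhibition never reaches `x`, the
#' level is flagged unattainable rather than raising an error, mirroring
#' the "NC" (not calculated) convention for combination reports.
#'
#' @param data Curve data frame (`conc_nM`, `viability`).
#' @param x Inhibition level, fraction in (0, 1).
#' @param method `"interpolated"` (default) or `"from_fit"`.
#' @param config A [drc_config()], used by the `"from_fit"` route.
#' @return A one-row tibble: `x`, `conc_nM`, `method`, `attainable`.
#' @export
#' @examples
#' curve <- simulate_curve(truth = list(model = "monophasic", ic50 = 100),
#'                         noise_sd = 0, seed = 1)
#' estimate_icx(curve, 0.5)               # ~100 nM
#' estimate_icx(curve, 0.6)               # ~150 nM
estimate_icx <- function(data, x, method = c("interpolated", "from_fit"),
                         config = drc_config()) {
  method <- match.arg(method)
  stopifnot(x > 0, x < 1)
  means <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(data, .data$conc_nM), .data$conc_nM),
    inhibition = 1 - mean(.data$viability), .groups = "drop"
  )
  out <- tibble::tibble(x = x, conc_nM = NA_real_, method = method,
                        attainable = FALSE)
  if (method == "interpolated") {
    if (nrow(means) < 2 || max(means$inhibition) < x) return(out)
    # first crossing of level x along increasing dose
    above <- which(means$inhibition >= x)
    i <- above[1]
    if (i == 1L) {
      out$conc_nM <- means$conc_nM[1]
    } else {
      l1 <- log10(means$conc_nM[i - 1]); l2 <- log10(means$conc_nM[i])
      y1 <- means$inhibition[i - 1]; y2 <- means$inhibition[i]
      out$conc_nM <- 10^(l1 + (x - y1) / (y2 - y1) * (l2 - l1))
    }
    out$attainable <- TRUE
  } else {
    fit <- fit_biphasic(data, config)
    top <- eval_biphasic(max(data$conc_nM), fit$params$f1,
                         fit$params$kd1, fit$params$kd2)
    # require the fitted curve to actually reach x within the tested range
    if (max(means$inhibition, top) < x) return(out)
    out$conc_nM <- icx_biphasic(x, fit$params$f1, fit$params$kd1,
                                fit$params$kd2)
    out$attainable <- TRUE
  }
  out
}

#' Dose reduction index for a 1:1 drug combination
#'
#' The aggregate fold-reduction in dose achieved by combining two drugs at
#' a given inhibition level:
#' \deqn{DRI = \frac{IC_{x,1} \times IC_{x,2}}
#'   {IC_{x,1+2} \times (IC_{x,1} + IC_{x,2})}}
#' where \eqn{IC_{x,1}}, \eqn{IC_{x,2}} and \eqn{IC_{x,1+2}} are the
#' concentrations of drug 1 alone, drug 2 alone, and the 1:1 combination
#' (total drug) reaching x inhibition. The statistic is symmetric in the
#' two drugs and invariant to rescaling the concentration unit. DRI = 1
#' means the combination merely shares dose; values well above 1 indicate
#' synergy.
#'
#' @param icx_a,icx_b,icx_ab Positive concentrations (same unit) of drug A,
#'   drug B, and the 1:1 combination at the chosen inhibition level.
#' @return The dose reduction index (positive scalar, dimensionless).
#' @export
#' @examples
#' compute_dri(500, 790, 28)   # 10.94, i.e. ~11-fold
compute_dri <- function(icx_a, icx_b, icx_ab) {
  if (any(c(icx_a, icx_b, icx_ab) <= 0) ||
      any(!is.finite(c(icx_a, icx_b, icx_ab)))) {
    stop("all ICx inputs must be positive and finite", call. = FALSE)
  }
  icx_a * icx_b / (icx_ab * (icx_a + icx_b))
}

#' Dose reduction index table across inhibition levels
#'
#' For each requested inhibition level, estimates ICx for drug A, drug B
#' and the 1:1 combination, and computes the DRI where all three are
#' attainable. Unattainable levels are reported with `attainable = FALSE`
#' and `dri = NA` (the "not calculated" convention when a drug fails to
#' reach the level within the tested range).
#'
#' @param curve_a,curve_b,curve_ab Curve data frames for drug A, drug B,
#'   and the 1:1 combination; `curve_ab$conc_nM` is the total combined
#'   dose. The per-drug dose in the combination is half the total and is
#'   reported alongside.
#' @param levels Inhibition levels to evaluate (default 40-70%).
#' @param method ICx method, see [estimate_icx()].
#' @param config A [drc_config()].
#' @return A tibble of class `dri_report`: one row per level with columns
#'   `x`, `icx_a`, `icx_b`, `icx_ab`, `icx_ab_per_drug`, `attainable`,
#'   `dri`.
#' @export
dri_table <- function(curve_a, curve_b, curve_ab,
                      levels = c(0.4, 0.5, 0.6, 0.7),
                      method = c("interpolated", "from_fit"),
                      config = drc_config()) {
  method <- match.arg(method)
  rows <- purrr::map_dfr(levels, function(x) {
    ea <- estimate_icx(curve_a, x, method, config)
    eb <- estimate_icx(curve_b, x, method, config)
    eab <- estimate_icx(curve_ab, x, method, config)
    ok <- ea$attainable && eb$attainable && eab$attainable
    tibble::tibble(
      x = x,
      icx_a = ea$conc_nM, icx_b = eb$conc_nM, icx_ab = eab$conc_nM,
      icx_ab_per_drug = eab$conc_nM / 2,
      attainable = ok,
      dri = if (ok) compute_dri(ea$conc_nM, eb$conc_nM, eab$conc_nM)
            else NA_real_
    )
  })
  class(rows) <- c("dri_report", class(rows))
  rows
}
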