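#' Fitting configuration
#'
#' Collects every tunable of the model-fitting layer in one validated list,
#' so a whole analysis is reproducible from its configuration alone.
#'
#' @param ratio_threshold Monophasic/biphasic RMSE ratio above which
#'   [compare_models()] prefers the biphasic model. Default 2.
#' @param f1_grid_n Number of F1 values in the coarse biphasic start lattice.
#' @param kd_grid_n Number of log-spaced Kd values per axis in the lattice.
#' @param n_refine How many of the best lattice starts are refined by
#'   bounded local optimization.
#' @param use_means If `TRUE`, fit to per-dose replicate means rather than
#'   all replicate points.
#' @param kd_lower_factor,kd_upper_factor Bounds for IC50/Kd1 relative to
#'   the tested concentration range: two decades below the lowest and above
#'   the highest dose by default.
#' @param kd2_upper_factor Upper bound for Kd2 relative to the top dose; six
#'   decades by default so "largely resistant" off-target plateaus are
#'   representable.
#' @param rmse_floor Absolute RMSE floor used when forming the
#'   monophasic/biphasic RMSE ratio, so near-perfect fits yield a ratio of 1
#'   instead of noise amplification.
#' @param lv_threshold,lv_range,ni_threshold,f1_mp_threshold Classification
#'   thresholds, see [classify_response()].
#' @param qc_rmse_threshold,qc_jump_threshold QC rejection rules, see
#'   [qc_filter()].
#' @param phase_sep_factor Minimum Kd2/Kd1 ratio for the two fitted phases
#'   to count as genuinely resolved in classification; closer phases are
#'   treated as one effective phase (see [classify_response()]).
#' @param blip_f1_max Maximum F1 for a phase saturated below the tested
#'   range (Kd1 under half the lowest dose) to be treated as an intercept
#'   artifact rather than a target-specific phase.
#' @return A list of class `drc_config`.
#' @export
drc_config <- function(ratio_threshold = 2,
                       f1_grid_n = 21,
                       kd_grid_n = 20,
                       n_refine = 10,
                       use_means = FALSE,
                       kd_lower_factor = 1 / 100,
                       kd_upper_factor = 100,
                       kd2_upper_factor = 1e6,
                       rmse_floor = 1e-6,
                       lv_threshold = 0.35,
                       lv_range = 0.2,
                       ni_threshold = 0.20,
                       f1_mp_threshold = 0.85,
                       qc_rmse_threshold = 0.15,
                       qc_jump_threshold = 0.25,
                       phase_sep_factor = 10,
                       blip_f1_max = 0.15) {
  cfg <- list(
    ratio_threshold = ratio_threshold, f1_grid_n = f1_grid_n,
    kd_grid_n = kd_grid_n, n_refine = n_refine, use_means = use_means,
    kd_lower_factor = kd_lower_factor, kd_upper_factor = kd_upper_factor,
    kd2_upper_factor = kd2_upper_factor, rmse_floor = rmse_floor,
    lv_threshold = lv_threshold, lv_range = lv_range,
    ni_threshold = ni_threshold, f1_mp_threshold = f1_mp_threshold,
    qc_rmse_threshold = qc_rmse_threshold,
    qc_jump_threshold = qc_jump_threshold,
    phase_sep_factor = phase_sep_factor,
    blip_f1_max = blip_f1_max
  )
  stopifnot(ratio_threshold > 0, f1_grid_n >= 3, kd_grid_n >= 5,
            n_refine >= 1, kd_lower_factor > 0, kd_upper_factor >= 1,
            kd2_upper_factor >= kd_upper_factor)
  structure(cfg, class = "drc_config")
}

# validate a curve data frame and optionally collapse replicates
prepare_curve <- function(data, use_means = FALSE, min_conc = 4L) {
  stopifnot(is.data.frame(data))
  if (!all(c("conc_nM", "viability") %in% names(data))) {
    stop("curve data must have columns 'conc_nM' and 'viability'",
         call. = FALSE)
  }
  data <- dplyr::filter(data, !is.na(.data$viability))
  if (nrow(data) == 0L) stop("curve has no usable points", call. = FALSE)
  if (any(data$conc_nM <= 0)) {
    stop("concentrations must be strictly positive (zero-dose controls are ",
         "handled during normalization, not fitting)", call. = FALSE)
  }
  if (any(!is.finite(data$viability))) {
    stop("viability values must be finite", call. = FALSE)
  }
  n_conc <- dplyr::n_distinct(data$conc_nM)
  if (n_conc < min_conc) {
    stop("at least ", min_conc, " distinct concentrations are required ",
         "(got ", n_conc, ")", call. = FALSE)
  }
  if (use_means) {
    data <- dplyr::summarise(dplyr::group_by(data, .data$conc_nM),
                             viability = mean(.data$viability),
                             .groups = "drop")
  }
  dplyr::arrange(data, .data$conc_nM)
}

new_drc_fit <- function(model, params, rmse, n_points, n_conc, at_bound,
                        starts_tried, converged, data, config) {
  structure(
    list(model = model, params = params, rmse = rmse, n_points = n_points,
         n_conc = n_conc, at_bound = at_bound, starts_tried = starts_tried,
         converged = converged, data = data, config = config),
    class = c(paste0(model, "_fit"), "drc_fit")
  )
}

# names of transformed parameters sitting on a box bound
bound_hits <- function(th, lower, upper, names, rel = 1e-6) {
  span <- pmax(upper - lower, 1)
  hit <- (th - lower) < rel * span | (upper - th) < rel * span
  names[hit]
}

# refine the best `n_refine` starts with bounded local optimization and
# return the winner; ties broken deterministically by the tie_key function
refine_starts <- function(starts, obj, lower, upper, n_refine, tie_key) {
  ord <- order(vapply(starts, function(s) s$rmse, numeric(1)))
  starts <- starts[ord[seq_len(min(n_refine, length(starts)))]]
  fits <- lapply(starts, function(s) {
    res <- stats::nlminb(s$th, obj, lower = lower, upper = upper,
                         control = list(iter.max = 500, eval.max = 1000))
    list(th = res$par, rmse = sqrt(res$objective),
         converged = res$convergence == 0)
  })
  keys <- t(vapply(fits, function(f) c(f$rmse, tie_key(f$th)), numeric(3)))
  best <- fits[[order(keys[, 1], keys[, 2], keys[, 3])[1]]]
  best
}

#' Fit the monophasic (single-target) model
#'
#' Finds the IC50 minimizing the RMSE between observed viability and
#' \eqn{1 - D/(D + IC_{50})}, by a coarse log-spaced scan of the bounded
#' IC50 range followed by bounded local refinement. Deterministic for a
#' given curve and configuration.
#'
#' @param data Data frame with columns `conc_nM` and `viability`; at least
#'   4 distinct concentrations.
#' @param config A [drc_config()] list.
#' @return An object of class `monophasic_fit`/`drc_fit` with elements
#'   `params` (`ic50`), `rmse`, `at_bound`, `converged`.
#' @seealso [fit_hill()], [fit_biphasic()], [compare_models()]
#' @export
#' @examples
#' curve <- simulate_curve(truth = list(model = "monophasic", ic50 = 100),
#'                         noise_sd = 0, seed = 1)
#' fit_monophasic(curve)
fit_monophasic <- function(data, config = drc_config()) {
  data <- prepare_curve(data, config$use_means)
  d <- data$conc_nM; v <- data$viability
  lo <- log10(min(d) * config$kd_lower_factor)
  hi <- log10(max(d) * config$kd_upper_factor)
  obj <- function(th) mean((v - 1 + eval_monophasic(d, 10^th[1]))^2)

  grid <- seq(lo, hi, length.out = 4 * config$kd_grid_n)
  scan <- vapply(grid, function(l) obj(l), numeric(1))
  starts <- lapply(order(scan)[1:3],
                   function(i) list(th = grid[i], rmse = sqrt(scan[i])))
  best <- refine_starts(starts, obj, lo, hi, config$n_refine,
                        tie_key = function(th) c(th[1], 0))
  new_drc_fit(
    model = "monophasic",
    params = list(ic50 = 10^best$th[1]),
    rmse = best$rmse, n_points = nrow(data),
    n_conc = dplyr::n_distinct(data$conc_nM),
    at_bound = bound_hits(best$th, lo, hi, "ic50"),
    starts_tried = length(starts), converged = best$converged,
    data = data, config = config
  )
}

#' Fit the modified Hill model
#'
#' Minimizes RMSE over \eqn{(I_{max}, IC_{50}^{*}, n)} within the bounds
#' \eqn{I_{max} \in (0, 1.2]}, \eqn{n \in [0.05, 10]} and IC50* spanning
#' two decades beyond the tested range, from a deterministic coarse lattice
#' plus the best monophasic fit as an extra start (which guarantees the
#' Hill fit never does worse than the monophasic fit).
#'
#' @inheritParams fit_monophasic
#' @return An object of class `hill_fit`/`drc_fit` with `params`
#'   (`i_max`, `ic50_star`, `n`).
#' @export
fit_hill <- function(data, config = drc_config()) {
  data <- prepare_curve(data, config$use_means)
  d <- data$conc_nM; v <- data$viability
  lo <- log10(min(d) * config$kd_lower_factor)
  hi <- log10(max(d) * config$kd_upper_factor)
  lower <- c(1e-6, lo, log10(0.05))
  upper <- c(1.2, hi, log10(10))
  obj <- function(th) {
    mean((v - 1 + eval_hill(d, th[1], 10^th[2], 10^th[3]))^2)
  }

  lat <- expand.grid(i_max = c(0.2, 0.5, 0.8, 1, 1.2),
                     lic = seq(lo, hi, length.out = 10),
                     ln = log10(c(0.2, 0.5, 1, 2, 5)))
  scan <- apply(lat, 1, obj)
  starts <- lapply(order(scan)[1:6], function(i) {
    list(th = as.numeric(lat[i, ]), rmse = sqrt(scan[i]))
  })
  # monophasic-equivalent start: i_max = 1, n = 1 at the best mono IC50
  mono <- fit_monophasic(data, config)
  th_m <- c(1, log10(mono$params$ic50), 0)
  starts <- c(starts, list(list(th = th_m, rmse = sqrt(obj(th_m)))))

  best <- refine_starts(starts, obj, lower, upper, config$n_refine + 2,
                        tie_key = function(th) c(th[2], th[1]))
  th <- best$th
  # zero-inhibition data admit several boundary representations (i_max -> 0,
  # or ic50_star beyond the range with steep n); canonicalize to the
  # i_max-at-lower-bound form
  if (eval_hill(max(d), th[1], 10^th[2], 10^th[3]) < 1e-4) {
    th[1] <- lower[1]
    best$rmse <- sqrt(obj(th))
  }
  new_drc_fit(
    model = "hill",
    params = list(i_max = th[1], ic50_star = 10^th[2], n = 10^th[3]),
    rmse = best$rmse, n_points = nrow(data),
    n_conc = dplyr::n_distinct(data$conc_nM),
    at_bound = bound_hits(th, lower, upper,
                          c("i_max", "ic50_star", "n")),
    starts_tried = length(starts), converged = best$converged,
    data = data, config = config
  )
}

#' Fit the biphasic (two-site) model
#'
#' Minimizes RMSE over \eqn{(F_1, K_{d1}, K_{d2})} with \eqn{F_1 \in [0,1]}
#' and both affinities log-parameterized, Kd1 bounded two decades beyond
#' the tested range and Kd2 allowed up to six decades above the top dose so
#' that "largely resistant" off-target plateaus are representable. Starts
#' come from a deterministic coarse lattice (vectorized scan over
#' \eqn{F_1 \times K_{d1} \times K_{d2}}), plus the single-phase start
#' \eqn{F_1 = 1, K_{d1} = } best monophasic IC50, which guarantees
#' RMSE(biphasic) <= RMSE(monophasic). Phase 1 is defined as the
#' high-affinity phase: results always satisfy `kd1 <= kd2` (labels are
#' swapped and `f1` complemented if the optimizer crosses). Equal-RMSE
#' ties are broken by smallest Kd1, then smallest F1.
#'
#' @inheritParams fit_monophasic
#' @return An object of class `biphasic_fit`/`drc_fit` with `params`
#'   (`f1`, `kd1`, `kd2`; `f2 = 1 - f1` is reported by [tidy()]).
#' @export
#' @examples
#' curve <- simulate_curve(truth = list(model = "biphasic", f1 = 0.57,
#'                                      kd1 = 19.8, kd2 = 1e6),
#'                         noise_sd = 0, seed = 1)
#' fit_biphasic(curve)
fit_biphasic <- function(data, config = drc_config()) {
  data <- prepare_curve(data, config$use_means)
  d <- data$conc_nM; v <- data$viability
  lo <- log10(min(d) * config$kd_lower_factor)
  hi1 <- log10(max(d) * config$kd_upper_factor)
  hi2 <- log10(max(d) * config$kd2_upper_factor)
  lower <- c(0, lo, lo)
  upper <- c(1, hi2, hi2)
  obj <- function(th) {
    mean((v - 1 + eval_biphasic(d, th[1], 10^th[2], 10^th[3]))^2)
  }

  # vectorized lattice scan: per ordered Kd pair the RMSE^2 is quadratic in
  # F1, so all (f1, kd1, kd2) combinations are scanned with three dot
  # products per pair
  lk <- seq(lo, hi2, length.out = config$kd_grid_n)
  M <- outer(10^lk, d, function(k, dd) dd / (dd + k))  # inhibition, K x m
  pairs <- which(upper.tri(diag(length(lk)), diag = TRUE), arr.ind = TRUE)
  A <- M[pairs[, "row"], , drop = FALSE]   # kd1 (smaller) phase
  B <- M[pairs[, "col"], , drop = FALSE]   # kd2 phase
  base <- sweep(B, 2, v - 1, "+")
  diff <- A - B
  c0 <- rowMeans(base^2); c1 <- 2 * rowMeans(base * diff)
  c2 <- rowMeans(diff^2)
  f1s <- seq(0, 1, length.out = config$f1_grid_n)
  sse <- outer(c2, f1s^2) + outer(c1, f1s) + c0   # pairs x f1
  top <- arrayInd(order(sse)[seq_len(config$n_refine * 2)], dim(sse))
  starts <- lapply(seq_len(nrow(top)), function(i) {
    p <- top[i, 1]; f <- f1s[top[i, 2]]
    th <- c(f, lk[pairs[p, "row"]], lk[pairs[p, "col"]])
    list(th = th, rmse = sqrt(sse[top[i, 1], top[i, 2]]))
  })
  mono <- fit_monophasic(data, config)
  th_m <- c(1, log10(mono$params$ic50), hi2)
  starts <- c(starts, list(list(th = th_m, rmse = sqrt(obj(th_m)))))

  # canonical representation: high-affinity phase first (kd1 <= kd2), and
  # single-phase solutions (all weight on one Kd) written as f1 = 1 with
  # kd1 = the active affinity, matching the monophasic limiting case
  canon <- function(th) {
    f1 <- th[1]; l1 <- th[2]; l2 <- th[3]
    if (l1 > l2) { f1 <- 1 - f1; tmp <- l1; l1 <- l2; l2 <- tmp }
    if (f1 <= 1e-6) { f1 <- 1; l1 <- l2; l2 <- hi2 }
    if (f1 >= 1 - 1e-6) f1 <- 1
    c(f1, l1, l2)
  }
  key <- function(th) {
    cth <- canon(th)
    c(cth[2], cth[1])
  }
  best <- refine_starts(starts, obj, lower, upper,
                        config$n_refine + 2, tie_key = key)
  th <- canon(best$th)
  new_drc_fit(
    model = "biphasic",
    params = list(f1 = th[1], kd1 = 10^th[2], kd2 = 10^th[3]),
    rmse = best$rmse, n_points = nrow(data),
    n_conc = dplyr::n_distinct(data$conc_nM),
    at_bound = bound_hits(th, lower, upper, c("f1", "kd1", "kd2")),
    starts_tried = length(starts), converged = best$converged,
    data = data, config = config
  )
}

#' Fit and compare all three dose-response models
#'
#' Fits the monophasic, Hill and biphasic models to one curve and reports
#' which is preferred. The biphasic model is preferred when the
#' monophasic/biphasic RMSE ratio exceeds `config$ratio_threshold`
#' (default 2); otherwise the monophasic model is kept. Both RMSEs are
#' floored at `config$rmse_floor` before forming the ratio so that two
#' near-perfect fits give a ratio of 1. The Hill fit is always reported
#' but never preferred: it serves as a descriptive check on the shape of
#' the response.
#'
#' @inheritParams fit_monophasic
#' @return An object of class `drc_comparison`: a list with `fits` (named
#'   list of the three `drc_fit` objects), `preferred`, and `rmse_ratio`.
#' @export
#' @examples
#' curve <- simulate_curve(truth = list(model = "biphasic", f1 = 0.5,
#'                                      kd1 = 10, kd2 = 1e5),
#'                         noise_sd = 0, seed = 1)
#' compare_models(curve)
compare_models <- function(data, config = drc_config()) {
  fits <- list(
    monophasic = fit_monophasic(data, config),
    hill = fit_hill(data, config),
    biphasic = fit_biphasic(data, config)
  )
  fl <- config$rmse_floor
  ratio <- max(fits$monophasic$rmse, fl) / max(fits$biphasic$rmse, fl)
  preferred <- if (ratio > config$ratio_threshold) "biphasic" else "monophasic"
  structure(list(fits = fits, preferred = preferred, rmse_ratio = ratio),
            class = "drc_comparison")
}
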