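#' Normalize raw viability readings against controls
#'
#' Converts raw plate readings to relative viability per cell line x drug
#' series: `viability = raw / control`, where the control is the mean of
#' the untreated control readings. When any drug-treated reading exceeds
#' the control (a low-dose growth uptick), the highest reading in the
#' series is used as the control instead, so relative viability is 1 at
#' that point and below 1 elsewhere. Normalization is scale-free: doubling
#' every raw reading leaves the output unchanged.
#'
#' @param table Long data frame with columns `cell_line`, `drug`,
#'   `conc_nM`, `raw`, and logical `is_control` (control rows may carry
#'   `NA` concentration).
#' @return Tibble of the treated rows with an added `viability` column and
#'   the `control_used` value per series.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   cell_line = "A", drug = "dasatinib",
#'   conc_nM = c(NA, 10, 100, 1000),
#'   raw = c(1.0, 1.10, 0.8, 0.4),
#'   is_control = c(TRUE, FALSE, FALSE, FALSE)
#' )
#' normalize_viability(tbl)   # renormalized by 1.10
normalize_viability <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("cell_line", "drug", "conc_nM", "raw", "is_control")
  if (!all(need %in% names(table))) {
    stop("raw viability table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  groups <- dplyr::group_split(dplyr::group_by(table, .data$cell_line,
                                               .data$drug))
  purrr::map_dfr(groups, function(g) {
    ctrl_rows <- g$raw[g$is_control]
    if (length(ctrl_rows) == 0L) {
      stop("no control reading for cell line '", g$cell_line[1],
           "', drug '", g$drug[1], "'", call. = FALSE)
    }
    control <- mean(ctrl_rows)
    treated <- dplyr::filter(g, !.data$is_control)
    # highest-reading rule: upticks above the control redefine the control
    control_used <- max(control, treated$raw)
    dplyr::mutate(treated,
                  viability = .data$raw / control_used,
                  control_used = control_used,
                  is_control = NULL)
  })
}

#' Quality-control filter for normalized dose-response curves
#'
#' Flags curves whose scatter makes model fitting meaningless. Two rules:
#' a curve is rejected when the largest single-step *increase* in per-dose
#' mean viability along increasing dose exceeds `qc_jump_threshold`
#' (default 0.25, reason `non-monotone-jump`), or when the best RMSE over
#' the three fitted models exceeds `qc_rmse_threshold` (default 0.15,
#' reason `high-rmse`). Both thresholds live in [drc_config()].
#'
#' @param table Long normalized data frame (`cell_line`, `drug`, `conc_nM`,
#'   `viability`).
#' @param config A [drc_config()].
#' @return A list with `kept` (tibble of surviving rows) and `rejected`
#'   (tibble of `cell_line`, `drug`, `reason`).
#' @export
qc_filter <- function(table, config = drc_config()) {
  groups <- dplyr::group_split(dplyr::group_by(table, .data$cell_line,
                                               .data$drug))
  verdicts <- purrr::map(groups, function(g) {
    means <- dplyr::summarise(dplyr::group_by(dplyr::arrange(g, .data$conc_nM),
                                              .data$conc_nM),
                              viability = mean(.data$viability),
                              .groups = "drop")
    jump <- if (nrow(means) > 1) max(diff(means$viability)) else 0
    if (jump > config$qc_jump_threshold) return("non-monotone-jump")
    cmp <- compare_models(g, config)
    best <- min(vapply(cmp$fits, function(f) f$rmse, numeric(1)))
    if (best > config$qc_rmse_threshold) return("high-rmse")
    NA_character_
  })
  reasons <- unlist(verdicts)
  keys <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(cell_line = g$cell_line[1], drug = g$drug[1])
  })
  list(
    kept = dplyr::bind_rows(groups[is.na(reasons)]),
    rejected = dplyr::mutate(keys[!is.na(reasons), ],
                             reason = reasons[!is.na(reasons)])
  )
}

#' Classify a dose-response curve into LV / NI / MP / BP
#'
#' The four screening response categories:
#' * **LV** (low viability): viability is low at every dose — mean per-dose
#'   viability below `lv_threshold` (default 0.35) with range below
#'   `lv_range` (default 0.2) — so no dose-dependent signal exists.
#' * **NI** (no inhibition): maximum inhibition across the tested range
#'   below `ni_threshold` (default 0.20).
#' * **MP** (monophasic): dose-dependent inhibition with fitted biphasic
#'   `F1 >= f1_mp_threshold` (default 0.85): blocking the drug's specific
#'   target is essentially sufficient to kill the cells.
#' * **BP** (biphasic): dose-dependent inhibition with `F1 < 0.85` — a
#'   target-specific nanomolar phase plus a resistant remainder,
#'   the signature of multi-driver proliferation.
#'
#' The fitted Kd2 is flagged unreliable when the top tested dose is below
#' ten times Kd1, since the off-target phase is then barely sampled.
#'
#' @param data Normalized, QC-passed curve (`conc_nM`, `viability`).
#' @param config A [drc_config()].
#' @return One-row tibble: `category` plus the evidence used
#'   (`mean_viability`, `viability_range`, `max_inhibition`, `f1`, `kd1`,
#'   `kd2`, `kd2_reliable`, `rmse_monophasic`, `rmse_biphasic`,
#'   `ic50_monophasic`).
#' @export
classify_response <- function(data, config = drc_config()) {
  means <- dplyr::summarise(dplyr::group_by(dplyr::arrange(data,
                                                           .data$conc_nM),
                                            .data$conc_nM),
                            viability = mean(.data$viability),
                            .groups = "drop")
  mv <- mean(means$viability)
  rng <- max(means$viability) - min(means$viability)
  max_inh <- 1 - min(means$viability)
  base <- tibble::tibble(
    category = NA_character_, mean_viability = mv, viability_range = rng,
    max_inhibition = max_inh, f1 = NA_real_, kd1 = NA_real_,
    kd2 = NA_real_, kd2_reliable = NA, rmse_monophasic = NA_real_,
    rmse_biphasic = NA_real_, ic50_monophasic = NA_real_
  )
  if (mv < config$lv_threshold && rng < config$lv_range) {
    base$category <- "LV"
    return(base)
  }
  if (max_inh < config$ni_threshold) {
    base$category <- "NI"
    return(base)
  }
  mono <- fit_monophasic(data, config)
  bi <- fit_biphasic(data, config)
  eff <- effective_phases(bi$params, min(data$conc_nM), config)
  base$f1 <- eff$f1
  base$kd1 <- eff$kd1
  base$kd2 <- eff$kd2
  # the off-target affinity is only trustworthy when the tested range
  # actually engages that phase (top dose at least ~half-saturating it)
  base$kd2_reliable <- !is.na(eff$kd2) && max(data$conc_nM) >= eff$kd2
  base$rmse_monophasic <- mono$rmse
  base$rmse_biphasic <- bi$rmse
  base$ic50_monophasic <- mono$params$ic50
  base$category <- if (eff$f1 >= config$f1_mp_threshold) "MP" else "BP"
  base
}

# Identifiability guards on a fitted biphasic parameter set, applied before
# the F1-based MP/BP call. Two artifacts of unconstrained RMSE-optimal
# fitting carry no evidence of real two-phase structure:
#   * an "intercept blip" -- a small phase saturated below the lowest
#     tested dose is indistinguishable from a constant offset, so the
#     dose-dependent phase 2 is the operative target phase;
#   * unresolved phases -- when Kd2/Kd1 is under phase_sep_factor the data
#     cannot separate the phases and the curve is effectively single-phase.
effective_phases <- function(p, min_dose, config) {
  f1 <- p$f1; kd1 <- p$kd1; kd2 <- p$kd2
  if (kd1 < min_dose / 2 && f1 < config$blip_f1_max) {
    f1 <- 1 - f1; kd1 <- kd2; kd2 <- NA_real_
  } else if (kd2 < config$phase_sep_factor * kd1) {
    # one effective phase at the fraction-weighted (log-scale) affinity
    kd1 <- exp(f1 * log(kd1) + (1 - f1) * log(kd2))
    f1 <- 1; kd2 <- NA_real_
  }
  list(f1 = f1, kd1 = kd1, kd2 = kd2)
}

#' Batch screen analysis: normalize, QC, fit and classify every curve
#'
#' Runs the full screening pipeline over a long table of viability data.
#' If the table carries raw readings (`raw` + `is_control` columns) it is
#' normalized first; duplicate cell line x drug rows are treated as
#' replicates. Per-curve failures are captured in an `error` column rather
#' than aborting the batch.
#'
#' @param table Long data frame: either normalized (`cell_line`, `drug`,
#'   `conc_nM`, `viability`) or raw (`cell_line`, `drug`, `conc_nM`, `raw`,
#'   `is_control`).
#' @param config A [drc_config()].
#' @param qc Apply [qc_filter()] before classification (default `TRUE`).
#' @return A tibble of class `screen_report`, one row per cell line x drug
#'   with the [classify_response()] evidence columns; QC rejections appear
#'   with `category = NA` and a `qc_reason`. The category tally is
#'   available via [category_tally()].
#' @export
batch_analyze <- function(table, config = drc_config(), qc = TRUE) {
  empty <- tibble::tibble(
    cell_line = character(), drug = character(), category = character(),
    qc_reason = character(), error = character()
  )
  if (nrow(table) == 0L) {
    return(structure(empty, class = c("screen_report", class(empty))))
  }
  if ("raw" %in% names(table) && "is_control" %in% names(table)) {
    table <- normalize_viability(table)
  }
  rejected <- NULL
  if (qc) {
    flt <- qc_filter(table, config)
    table <- flt$kept
    rejected <- flt$rejected
  }
  groups <- dplyr::group_split(dplyr::group_by(table, .data$cell_line,
                                               .data$drug))
  rows <- purrr::map_dfr(groups, function(g) {
    res <- tryCatch(
      dplyr::mutate(classify_response(g, config), error = NA_character_),
      error = function(e) tibble::tibble(category = NA_character_,
                                         error = conditionMessage(e))
    )
    dplyr::bind_cols(tibble::tibble(cell_line = g$cell_line[1],
                                    drug = g$drug[1]), res)
  })
  if (!is.null(rejected) && nrow(rejected) > 0) {
    rejected <- dplyr::mutate(rejected, qc_reason = .data$reason,
                              reason = NULL, category = NA_character_)
    rows <- dplyr::bind_rows(rows, rejected)
  }
  if (nrow(rows) == 0L) rows <- empty
  if (!"qc_reason" %in% names(rows)) rows$qc_reason <- NA_character_
  structure(rows, class = c("screen_report", class(rows)))
}

#' Tally of response categories in a screen report
#'
#' @param report A `screen_report` from [batch_analyze()].
#' @return Tibble of `category` and `n`, including all four categories
#'   (zero counts kept) and a `QC-rejected` row when applicable.
#' @export
category_tally <- function(report) {
  lv <- factor(report$category, levels = c("LV", "NI", "MP", "BP"))
  out <- tibble::as_tibble(as.data.frame(table(category = lv),
                                         responseName = "n"))
  out$category <- as.character(out$category)
  n_rej <- sum(is.na(report$category))
  if (n_rej > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(category = "QC-rejected",
                                                n = n_rej))
  }
  out$n <- as.integer(out$n)
  out
}
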