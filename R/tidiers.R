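#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a fitted dose-response model
#'
#' @param x A `drc_fit` from [fit_monophasic()], [fit_hill()] or
#'   [fit_biphasic()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `at_bound`. For the
#'   biphasic model the derived `f2 = 1 - f1` is included.
#' @export
tidy.drc_fit <- function(x, ...) {
  params <- x$params
  if (x$model == "biphasic") params$f2 <- 1 - params$f1
  tibble::tibble(
    term = names(params),
    estimate = unlist(params, use.names = FALSE),
    at_bound = names(params) %in% x$at_bound
  )
}

#' One-row fit summary
#'
#' @param x A `drc_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `rmse`, `n_points`, `n_conc`,
#'   `starts_tried`, `converged`, `any_at_bound`.
#' @export
glance.drc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, rmse = x$rmse, n_points = x$n_points,
    n_conc = x$n_conc, starts_tried = x$starts_tried,
    converged = x$converged, any_at_bound = length(x$at_bound) > 0
  )
}

#' Tidy a three-model comparison
#'
#' @param x A `drc_comparison` from [compare_models()].
#' @param ... Unused.
#' @return One row per model x parameter, with the preferred model marked.
#' @export
tidy.drc_comparison <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::mutate(tidy(f), model = f$model, .before = 1)
  })
}

#' @rdname tidy.drc_comparison
#' @export
glance.drc_comparison <- function(x, ...) {
  tibble::tibble(
    preferred = x$preferred, rmse_ratio = x$rmse_ratio,
    rmse_monophasic = x$fits$monophasic$rmse,
    rmse_hill = x$fits$hill$rmse,
    rmse_biphasic = x$fits$biphasic$rmse
  )
}

#' @export
print.drc_fit <- function(x, ...) {
  cat("<", x$model, " dose-response fit>\n", sep = "")
  p <- x$params
  shown <- vapply(names(p), function(nm) {
    val <- p[[nm]]
    if (grepl("^(ic50|kd)", nm)) format_conc(val)
    else format(signif(val, 4))
  }, character(1))
  cat(paste0("  ", names(p), " = ", shown,
             ifelse(names(p) %in% x$at_bound, " [at bound]", "")),
      sep = "\n")
  cat(sprintf("  RMSE %.4g on %d points (%d concentrations)\n",
              x$rmse, x$n_points, x$n_conc))
  invisible(x)
}

#' @export
print.drc_comparison <- function(x, ...) {
  cat("<model comparison> preferred:", x$preferred,
      sprintf("(monophasic/biphasic RMSE ratio %.3g)\n", x$rmse_ratio))
  for (f in x$fits) print(f)
  invisible(x)
}

#' Plot a fitted dose-response curve
#'
#' Observed viability (points, per replicate) with the fitted model curve
#' on a log10 concentration axis.
#'
#' @param object A `drc_fit`.
#' @param n_grid Resolution of the fitted line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drc_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  rng <- range(d$conc_nM)
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n_grid)
  p <- object$params
  inhib <- switch(object$model,
                  monophasic = eval_monophasic(grid, p$ic50),
                  hill = eval_hill(grid, p$i_max, p$ic50_star, p$n),
                  biphasic = eval_biphasic(grid, p$f1, p$kd1, p$kd2))
  fit_df <- tibble::tibble(conc_nM = grid, viability = 1 - inhib)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_nM, y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fit_df, colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "relative viability",
                  title = paste(object$model, "fit"),
                  subtitle = sprintf("RMSE = %.4g", object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Overlays the monophasic (dashed) and biphasic (solid) fitted curves on
#' the observed data, the visual diagnostic for biphasic behavior.
#'
#' @param object A `drc_comparison`.
#' @param n_grid Resolution of the fitted lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drc_comparison <- function(object, n_grid = 200, ...) {
  d <- object$fits$monophasic$data
  rng <- range(d$conc_nM)
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n_grid)
  pm <- object$fits$monophasic$params
  pb <- object$fits$biphasic$params
  lines <- dplyr::bind_rows(
    tibble::tibble(conc_nM = grid, model = "monophasic",
                   viability = 1 - eval_monophasic(grid, pm$ic50)),
    tibble::tibble(conc_nM = grid, model = "biphasic",
                   viability = 1 - eval_biphasic(grid, pb$f1, pb$kd1,
                                                 pb$kd2))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_nM, y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(linetype = .data$model),
                       colour = "#2166ac") +
    ggplot2::scale_linetype_manual(values = c(monophasic = "dashed",
                                              biphasic = "solid")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "relative viability",
                  subtitle = paste("preferred:", object$preferred)) +
    ggplot2::theme_minimal()
}

#' Plot a dose reduction index report
#'
#' Single-agent and combination ICx values per inhibition level, with DRI
#' annotations.
#'
#' @param object A `dri_report` from [dri_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dri_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("x", "icx_a", "icx_b", "icx_ab")],
    cols = -"x", names_to = "series", values_to = "conc_nM"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$x * 100),
                                     y = .data$conc_nM,
                                     fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inhibition level (%)", y = "ICx (nM)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
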