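parse_conc_column <- function(df, path) {
  if ("conc_nM" %in% names(df)) {
    conc <- df$conc_nM
  } else if ("conc_uM" %in% names(df)) {
    conc <- as_nM(df$conc_uM, "uM")
  } else if (all(c("conc", "unit") %in% names(df))) {
    conc <- mapply(as_nM, df$conc, df$unit)
  } else {
    stop("'", path, "': need a concentration column: conc_nM, conc_uM, ",
         "or conc + unit", call. = FALSE)
  }
  bad <- which(!is.na(conc) & conc < 0)
  if (length(bad) > 0) {
    stop("'", path, "': negative concentration at data row ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conc
}

#' Read a long-format dose-response CSV
#'
#' Column contract: `cell_line`, `drug`, a concentration column (`conc_nM`,
#' `conc_uM`, or `conc` plus a `unit` column with nM/uM values), and either
#' `viability` (already normalized) or `raw` + `is_control` (raw plate
#' readings, to be passed through [normalize_viability()]). An optional
#' `role` column (a/b/ab) marks combination datasets and an optional
#' `replicate` column distinguishes replicate wells. Concentrations are
#' canonicalized to nM and rows sorted; malformed rows fail loudly with
#' their row number — no row is ever silently dropped.
#'
#' @param path CSV file path.
#' @return Tibble in canonical long form (`conc_nM` in nM, ascending per
#'   series).
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_line", "drug")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("'", path, "': missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("viability" %in% names(df)) &&
      !all(c("raw", "is_control") %in% names(df))) {
    stop("'", path, "': need either a 'viability' column or ",
         "'raw' + 'is_control' columns", call. = FALSE)
  }
  df$conc_nM <- parse_conc_column(df, path)
  val_col <- if ("viability" %in% names(df)) "viability" else "raw"
  bad <- which(!is.finite(df[[val_col]]))
  if (length(bad) > 0) {
    stop("'", path, "': non-numeric ", val_col, " at data row ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nonctrl <- if ("is_control" %in% names(df)) !df$is_control else TRUE
  bad0 <- which(nonctrl & (is.na(df$conc_nM) | df$conc_nM <= 0))
  if (length(bad0) > 0) {
    stop("'", path, "': missing or nonpositive concentration on a ",
         "non-control row: ", paste(utils::head(bad0, 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c("cell_line", "drug", "role", "conc_nM", "viability",
                      "raw", "is_control", "replicate"), names(df))
  dplyr::arrange(df[keep], .data$cell_line, .data$drug, .data$conc_nM)
}

#' Read a wide screening table (one concentration per column)
#'
#' Dialect: one row per cell line (x drug), columns `cell_line`, optional
#' `drug`, one or more control columns whose names start with `control`,
#' and one column per dose named as a number with unit suffix (`5nM`,
#' `0.02uM`, ...). The table is melted to the long raw format consumed by
#' [normalize_viability()]; the highest-reading control rule is applied
#' there, not here.
#'
#' @param path CSV file path.
#' @param drug Drug label used when the table has no `drug` column.
#' @return Long tibble with `cell_line`, `drug`, `conc_nM`, `raw`,
#'   `is_control`.
#' @export
read_wide_table <- function(path, drug = "drug") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"cell_line" %in% names(df)) {
    stop("'", path, "': wide table needs a 'cell_line' column",
         call. = FALSE)
  }
  if (!"drug" %in% names(df)) df$drug <- drug
  ctrl_cols <- grep("^control", names(df), value = TRUE)
  if (length(ctrl_cols) == 0) {
    stop("'", path, "': no control column (name must start with 'control')",
         call. = FALSE)
  }
  other <- setdiff(names(df), c("cell_line", "drug", ctrl_cols))
  m <- regmatches(other, regexec("^([0-9.eE+-]+) ?(nM|uM|µM)$", other))
  parsed <- vapply(m, length, integer(1)) == 3
  if (any(!parsed)) {
    stop("'", path, "': ambiguous dose column(s): ",
         paste(other[!parsed], collapse = ", "),
         " (expected e.g. '5nM' or '1.28uM')", call. = FALSE)
  }
  doses <- vapply(m, function(g) as_nM(as.numeric(g[2]), g[3]), numeric(1))
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(c(ctrl_cols, other)),
                              names_to = "column", values_to = "raw")
  long$is_control <- long$column %in% ctrl_cols
  long$conc_nM <- doses[match(long$column, other)]
  dplyr::arrange(
    long[c("cell_line", "drug", "conc_nM", "raw", "is_control")],
    .data$cell_line, .data$drug, .data$conc_nM
  )
}

#' Render a concentration for human-readable reports
#'
#' Uses 4 significant figures in nM, switching to micromolar above 1000 nM;
#' Kd values beyond the representable micromolar range (> 1e6 nM) print as
#' `"> 1000 uM"` — the numeric value remains available in machine outputs.
#'
#' @param conc_nM Concentration in nM.
#' @return Character scalar.
#' @export
#' @examples
#' format_conc(19.8)     # "19.8 nM"
#' format_conc(2.3e7)    # "> 1000 uM"
format_conc <- function(conc_nM) {
  vapply(conc_nM, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x > 1e6) return("> 1000 uM")
    if (x >= 1000) paste(signif(x / 1000, 4), "uM")
    else paste(signif(x, 4), "nM")
  }, character(1))
}

#' Write an analysis report as JSON (machine) and/or TSV (human)
#'
#' JSON embeds the full resolved configuration and seed so any report can
#' be regenerated from its own metadata; numeric values are written at
#' full precision. TSV renders concentrations through [format_conc()].
#'
#' @param report A data frame (e.g. `screen_report` or `dri_report`).
#' @param json_path,tsv_path Output paths; `NULL` skips that format.
#' @param config The [drc_config()] used.
#' @param seed Seed used, if any.
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL,
                         config = drc_config(), seed = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      config = unclass(config), seed = seed,
      version = as.character(utils::packageVersion("biphasr")),
      report = as.data.frame(report)
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path)) {
    out <- as.data.frame(report)
    for (col in intersect(c("kd1", "kd2", "ic50_monophasic", "icx_a",
                            "icx_b", "icx_ab", "conc_nM"), names(out))) {
      out[[col]] <- format_conc(out[[col]])
    }
    readr::write_tsv(out, tsv_path, progress = FALSE)
  }
  invisible(report)
}

#' Load an analysis configuration from YAML
#'
#' Keys mirror the arguments of [drc_config()]; unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A validated [drc_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(drc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(drc_config, vals)
}
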