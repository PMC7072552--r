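make_raw <- function(cell_line, conc, raw, control = 1.0) {
  dplyr::bind_rows(
    tibble::tibble(cell_line = cell_line, drug = "dasatinib",
                   conc_nM = NA_real_, raw = control, is_control = TRUE),
    tibble::tibble(cell_line = cell_line, drug = "dasatinib",
                   conc_nM = conc, raw = raw, is_control = FALSE)
  )
}

test_that("normalization divides by the control, or the highest reading", {
  # raw equals control everywhere -> viability 1
  t1 <- make_raw("A", c(10, 100, 1000), c(1, 1, 1))
  expect_equal(normalize_viability(t1)$viability, c(1, 1, 1))

  # low-dose uptick above the control: renormalize by the highest reading
  t2 <- make_raw("A", c(10, 100, 1000), c(1.10, 0.8, 0.4))
  v <- normalize_viability(t2)$viability
  expect_equal(v, c(1.10, 0.8, 0.4) / 1.10, tolerance = 1e-9)
  expect_equal(max(v), 1)

  # all readings below control: plain division
  t3 <- make_raw("A", c(10, 100, 1000), c(0.9, 0.5, 0.2))
  expect_equal(normalize_viability(t3)$viability, c(0.9, 0.5, 0.2))
})

test_that("normalization is scale-free and fails loudly without controls", {
  t2 <- make_raw("A", c(10, 100, 1000), c(1.10, 0.8, 0.4))
  doubled <- dplyr::mutate(t2, raw = raw * 2)
  expect_equal(normalize_viability(doubled)$viability,
               normalize_viability(t2)$viability)
  no_ctrl <- dplyr::filter(t2, !is_control)
  expect_error(normalize_viability(no_ctrl), "control.*'A'")
})

test_that("QC keeps clean curves and rejects scatter with a reason", {
  clean <- simulate_curve(list(model = "biphasic", f1 = 0.5, kd1 = 30,
                               kd2 = 1e5), grid = "gdsc_nine_point",
                          noise_sd = 0, replicates = 2, seed = 1)
  res <- qc_filter(clean)
  expect_equal(nrow(res$rejected), 0)
  expect_equal(nrow(res$kept), nrow(clean))

  # swap one dose's viability upward to create a 0.5 jump
  jump <- dplyr::mutate(
    clean, viability = replace(viability, conc_nM == 320, 1.0))
  resj <- qc_filter(jump)
  expect_equal(resj$rejected$reason, "non-monotone-jump")

  # white noise around 0.7, sd 0.25: overwhelmingly rejected
  rejected <- vapply(1:20, function(s) {
    set.seed(s)
    noise <- tibble::tibble(
      cell_line = "N", drug = "d",
      conc_nM = rep(grid_gdsc_nine_point(), each = 2),
      viability = 0.7 + rnorm(18, 0, 0.25))
    nrow(qc_filter(noise)$rejected) == 1
  }, logical(1))
  expect_gte(sum(rejected), 18)
})

test_that("noiseless exemplars classify into their defining categories", {
  mp <- simulate_curve(list(model = "monophasic", ic50 = 50),
                       grid = "gdsc_nine_point", noise_sd = 0,
                       replicates = 1, seed = 1)
  rm <- classify_response(mp)
  expect_identical(rm$category, "MP")
  expect_equal(rm$f1, 1, tolerance = 0.01)

  ni <- tibble::tibble(conc_nM = grid_gdsc_nine_point(), viability = 1)
  expect_identical(classify_response(ni)$category, "NI")

  lv <- tibble::tibble(conc_nM = grid_gdsc_nine_point(), viability = 0.2)
  expect_identical(classify_response(lv)$category, "LV")

  bp <- simulate_curve(list(model = "biphasic", f1 = 0.5, kd1 = 30,
                            kd2 = 1e5), grid = "gdsc_nine_point",
                       noise_sd = 0, replicates = 1, seed = 1)
  rb <- classify_response(bp)
  expect_identical(rb$category, "BP")
  expect_equal(rb$f1, 0.5, tolerance = 0.02)
  # off-target phase far above the tested range: Kd2 marked unreliable
  expect_false(rb$kd2_reliable)
})

test_that("Kd2 is reliable only when the grid reaches well past Kd1", {
  bp <- simulate_curve(list(model = "biphasic", f1 = 0.6, kd1 = 100,
                            kd2 = 5e3), grid = "sixteen_point",
                       noise_sd = 0, replicates = 1, seed = 1)
  r <- classify_response(bp)
  expect_true(r$kd2_reliable)
  expect_equal(r$kd2, 5e3, tolerance = 0.05 * 5e3)
})

test_that("classification recovers generating categories away from thresholds", {
  set.seed(99)
  n <- 60
  correct <- vapply(seq_len(n), function(i) {
    pick <- (i %% 4) + 1
    truth <- switch(pick,
      list(model = "monophasic",
           ic50 = 10^runif(1, log10(20), log10(80))),       # MP
      list(model = "biphasic", f1 = runif(1, 0.35, 0.65),
           kd1 = 10^runif(1, 1, 1.6), kd2 = 1e5),           # BP
      list(model = "biphasic", f1 = 0, kd1 = 1, kd2 = 1e8), # NI (flat 1)
      list(model = "hill", i_max = runif(1, 0.75, 0.82),
           ic50_star = 1e-4, n = 1))                        # LV (flat low)
    expected <- c("MP", "BP", "NI", "LV")[pick]
    cv <- simulate_curve(truth, grid = "gdsc_nine_point", noise_sd = 0,
                         replicates = 1, seed = i)
    classify_response(cv)$category == expected
  }, logical(1))
  expect_gte(mean(correct), 0.95)
})

test_that("batch analysis reports per-curve evidence and a full tally", {
  pan <- fixture_panel(seed = 3, k = 2)
  rep <- batch_analyze(dplyr::select(pan, -true_category))
  expect_s3_class(rep, "screen_report")
  expect_equal(nrow(rep), 10)       # 5 categories x 2 curves
  tal <- category_tally(rep)
  expect_setequal(tal$category, c("LV", "NI", "MP", "BP", "QC-rejected"))
  expect_equal(sum(tal$n), 10)

  # empty input: empty report, zero tally
  er <- batch_analyze(tibble::tibble())
  expect_equal(nrow(er), 0)
  expect_equal(sum(category_tally(er)$n), 0)
})

test_that("duplicate cell line x drug rows are merged as replicates", {
  cv <- simulate_curve(list(model = "monophasic", ic50 = 50),
                       grid = "gdsc_nine_point", noise_sd = 0.02,
                       replicates = 1, seed = 1)
  dup <- dplyr::bind_rows(cv, dplyr::mutate(cv, viability = viability + 0.01))
  rep <- batch_analyze(dup, qc = FALSE)
  expect_equal(nrow(rep), 1)
  expect_identical(rep$category, "MP")
})

test_that("raw tables are normalized on the way into batch analysis", {
  g <- grid_gdsc_nine_point()
  raw <- make_raw("X", g, 0.95 * (1 - eval_monophasic(g, 50)) + 0.02,
                  control = 0.95)
  rep <- batch_analyze(raw, qc = FALSE)
  expect_identical(rep$category, "MP")
})
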