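test_that("each model refits its own noiseless data", {
  mono <- simulate_curve(list(model = "monophasic", ic50 = 100),
                         noise_sd = 0, replicates = 1, seed = 1)
  fm <- fit_monophasic(mono)
  expect_equal(fm$params$ic50, 100, tolerance = 1e-6)
  expect_lt(fm$rmse, 1e-7)

  hill <- simulate_curve(list(model = "hill", i_max = 0.8,
                              ic50_star = 500, n = 0.34),
                         noise_sd = 0, replicates = 1, seed = 1)
  fh <- fit_hill(hill)
  expect_equal(fh$params$i_max, 0.8, tolerance = 0.01)
  expect_equal(fh$params$ic50_star, 500, tolerance = 0.01)
  expect_equal(fh$params$n, 0.34, tolerance = 0.01)

  bi <- simulate_curve(list(model = "biphasic", f1 = 0.57, kd1 = 19.8,
                            kd2 = 1e6), noise_sd = 0, replicates = 1,
                       seed = 1)
  fb <- fit_biphasic(bi)
  expect_equal(fb$params$f1, 0.57, tolerance = 0.01)
  expect_equal(fb$params$kd1, 19.8, tolerance = 0.01 * 19.8)
  expect_equal(fb$params$kd2, 1e6, tolerance = 0.01 * 1e6)
})

test_that("cross-model fits recover the equivalent parameterization", {
  # Hill data with i_max = 1, n = 1 is monophasic
  hm <- simulate_curve(list(model = "hill", i_max = 1, ic50_star = 250,
                            n = 1), noise_sd = 0, replicates = 1, seed = 1)
  expect_equal(fit_monophasic(hm)$params$ic50, 250, tolerance = 1e-5)
  # monophasic data through the Hill fitter
  mono <- simulate_curve(list(model = "monophasic", ic50 = 100),
                         noise_sd = 0, replicates = 1, seed = 1)
  fh <- fit_hill(mono)
  expect_equal(fh$params$i_max, 1, tolerance = 0.01)
  expect_equal(fh$params$n, 1, tolerance = 0.01)
  expect_equal(fh$params$ic50_star, 100, tolerance = 1)
})

test_that("biphasic fit of monophasic data returns the single-phase identity", {
  # F1 = 100% and Kd1 = IC50 when one phase suffices
  mono <- simulate_curve(list(model = "monophasic", ic50 = 165),
                         noise_sd = 0, replicates = 1, seed = 1)
  fb <- fit_biphasic(mono)
  expect_equal(fb$params$f1, 1, tolerance = 0.005)
  expect_equal(fb$params$kd1, 165, tolerance = 0.01 * 165)
  expect_true(fb$params$kd1 <= fb$params$kd2)
})

test_that("monophasic fit cannot explain strongly biphasic data", {
  bi <- simulate_curve(list(model = "biphasic", f1 = 0.5, kd1 = 10,
                            kd2 = 1e5), noise_sd = 0, replicates = 1,
                       seed = 1)
  fm <- fit_monophasic(bi)
  oracle <- oracle_best_mono_rmse(bi$conc_nM, bi$viability)
  expect_gt(oracle, 0.05)       # even the dense-grid floor is poor
  expect_gt(fm$rmse, 0.05)
  expect_equal(fm$rmse, oracle, tolerance = 1e-3)
})

test_that("degenerate inputs are flagged, not fatal", {
  flat <- tibble::tibble(conc_nM = 10^(0:7), viability = 1)
  fh <- fit_hill(flat)
  expect_equal(fh$params$i_max, 1e-6, tolerance = 1e-3)
  expect_true("i_max" %in% fh$at_bound)
  fm <- fit_monophasic(flat)
  expect_true(length(fm$at_bound) > 0)
  expect_error(fit_biphasic(tibble::tibble(conc_nM = c(1, 10, 100),
                                           viability = c(1, 0.5, 0.2))),
               "at least 4")
  expect_error(fit_monophasic(tibble::tibble(conc_nM = rep(c(1, 10), 4),
                                             viability = 0.5)),
               "at least 4")
})

test_that("nested models never fit worse than the monophasic special case", {
  for (s in 1:25) {
    cv <- random_curve(s)
    rm <- fit_monophasic(cv)$rmse
    expect_lte(fit_biphasic(cv)$rmse, rm + 1e-9)
    expect_lte(fit_hill(cv)$rmse, rm + 1e-9)
  }
})

test_that("fits are deterministic and scale-equivariant", {
  cv <- random_curve(7)
  f1 <- fit_biphasic(cv)
  f2 <- fit_biphasic(cv)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$rmse, f2$rmse)

  for (c_scale in c(0.1, 1000)) {
    scaled <- dplyr::mutate(cv, conc_nM = conc_nM * c_scale)
    fs <- fit_biphasic(scaled)
    expect_equal(fs$params$f1, f1$params$f1, tolerance = 1e-4)
    expect_equal(fs$params$kd1, f1$params$kd1 * c_scale,
                 tolerance = 1e-4 * f1$params$kd1 * c_scale)
    expect_equal(fs$rmse, f1$rmse, tolerance = 1e-6)
    fm <- fit_monophasic(cv); fms <- fit_monophasic(scaled)
    expect_equal(fms$params$ic50, fm$params$ic50 * c_scale,
                 tolerance = 1e-4 * fm$params$ic50 * c_scale)
  }
})

test_that("noisy replicated data recovers the generating F1", {
  errs <- vapply(1:15, function(s) {
    cv <- simulate_curve(list(model = "biphasic", f1 = 0.6, kd1 = 50,
                              kd2 = 2e5), noise_sd = 0.05, replicates = 3,
                         seed = s)
    abs(fit_biphasic(cv)$params$f1 - 0.6)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("model comparison prefers the right model and reports the ratio", {
  mono <- simulate_curve(list(model = "monophasic", ic50 = 100),
                         noise_sd = 0, replicates = 1, seed = 1)
  cm <- compare_models(mono)
  expect_identical(cm$preferred, "monophasic")
  expect_equal(cm$rmse_ratio, 1, tolerance = 0.2)

  bi <- simulate_curve(list(model = "biphasic", f1 = 0.5, kd1 = 10,
                            kd2 = 1e5), noise_sd = 0, replicates = 1,
                       seed = 1)
  cb <- compare_models(bi)
  expect_identical(cb$preferred, "biphasic")
  expect_gt(cb$rmse_ratio, 2)
})

test_that("use_means config collapses replicates in the objective", {
  cv <- simulate_curve(list(model = "monophasic", ic50 = 80),
                       noise_sd = 0.1, replicates = 3, seed = 3)
  fa <- fit_monophasic(cv)
  fm <- fit_monophasic(cv, drc_config(use_means = TRUE))
  means <- dplyr::summarise(dplyr::group_by(cv, conc_nM),
                            viability = mean(viability), .groups = "drop")
  expect_equal(fm$rmse,
               rmse_curve(means, function(d) eval_monophasic(d, fm$params$ic50)),
               tolerance = 1e-9)
  expect_false(identical(fa$rmse, fm$rmse))
})
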