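# run expr with a locally-set RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

resolve_grid <- function(grid) {
  if (is.character(grid)) {
    grid <- switch(grid,
                   sixteen_point = grid_sixteen_point(),
                   gdsc_nine_point = grid_gdsc_nine_point(),
                   stop("unknown grid '", grid, "'", call. = FALSE))
  }
  stopifnot(is.numeric(grid), all(grid > 0), !is.unsorted(grid,
                                                          strictly = TRUE))
  grid
}

truth_fn <- function(truth) {
  stopifnot(is.list(truth), !is.null(truth$model))
  switch(truth$model,
    monophasic = function(d) eval_monophasic(d, truth$ic50),
    hill = function(d) eval_hill(d, truth$i_max, truth$ic50_star, truth$n),
    biphasic = function(d) eval_biphasic(d, truth$f1, truth$kd1, truth$kd2),
    stop("unknown truth model '", truth$model, "'", call. = FALSE)
  )
}

#' Simulate a dose-response curve from a known model
#'
#' Generates `viability = 1 - I(d) + noise` per replicate at each grid
#' concentration, with additive Gaussian noise (sd `noise_sd`) truncated
#' below at -0.05. Bit-reproducible for a given seed; the caller's RNG
#' state is untouched.
#'
#' @param truth A list naming the generating model and its parameters:
#'   `list(model = "monophasic", ic50 = )`,
#'   `list(model = "hill", i_max = , ic50_star = , n = )`, or
#'   `list(model = "biphasic", f1 = , kd1 = , kd2 = )` (concentrations nM).
#' @param grid `"sixteen_point"` (0.6 nM-20 uM), `"gdsc_nine_point"`
#'   (5 nM-1.28 uM, 2x series), or a custom ascending nM vector.
#' @param noise_sd Gaussian noise standard deviation in viability units.
#' @param replicates Replicate wells per concentration.
#' @param seed Integer RNG seed.
#' @param cell_line,drug Labels carried into the output.
#' @return Tibble with `cell_line`, `drug`, `conc_nM`, `viability`,
#'   `replicate`.
#' @export
#' @examples
#' simulate_curve(truth = list(model = "biphasic", f1 = 0.57, kd1 = 19.8,
#'                             kd2 = 1e6), noise_sd = 0.05, seed = 7)
simulate_curve <- function(truth, grid = "sixteen_point", noise_sd = 0.05,
                           replicates = 3, seed = 1,
                           cell_line = "sim", drug = truth$model) {
  stopifnot(noise_sd >= 0, replicates >= 1)
  grid <- resolve_grid(grid)
  inhib <- truth_fn(truth)
  d <- rep(grid, each = replicates)
  v_clean <- 1 - inhib(d)
  v <- with_seed(seed, v_clean + stats::rnorm(length(d), 0, noise_sd))
  tibble::tibble(
    cell_line = cell_line, drug = drug, conc_nM = d,
    viability = pmax(v, -0.05),
    replicate = rep(seq_len(replicates), times = length(grid))
  )
}

#' Simulate a 1:1 drug combination over independent cell subpopulations
#'
#' A generative model for combination screening built from four cell
#' subpopulations: a fraction `f_a` killed only through drug A's target, a
#' fraction `f_b` killed only through drug B's target, a fraction
#' `f_shared` sensitive to both, and a fraction `f_resistant` touched only
#' by off-target toxicity. Single-agent curves are then biphasic
#' (target-specific phase of size `f_a + f_shared` for drug A, remainder
#' responding only at the off-target affinity `kd2_a`). For the 1:1
#' combination at total dose D each drug is present at D/2, and survival
#' is multiplicative across independent kill mechanisms within each
#' subpopulation. This is a testbed construction, not a claim about any
#' particular biology: it produces single-agent plateaus and combination
#' synergy of the kind multi-driver cell lines show.
#'
#' @param f_a,f_b,f_shared,f_resistant Subpopulation fractions, `>= 0`,
#'   summing to 1.
#' @param kd_a,kd_b Target affinities (nM) of drugs A and B.
#' @param kd2_a,kd2_b Off-target affinities (nM), micromolar-scale.
#' @param grid,noise_sd,replicates,seed As [simulate_curve()].
#' @return Tibble with a `role` column (`"a"`, `"b"`, `"ab"`); `conc_nM`
#'   for role `"ab"` is the total combined dose.
#' @export
#' @examples
#' combo <- simulate_combination(f_a = 0.45, f_b = 0.45, f_shared = 0,
#'                               f_resistant = 0.1, kd_a = 50, kd_b = 80,
#'                               noise_sd = 0, seed = 1)
#' dri_table(combo[combo$role == "a", ], combo[combo$role == "b", ],
#'           combo[combo$role == "ab", ], levels = 0.5)
simulate_combination <- function(f_a, f_b, f_shared, f_resistant,
                                 kd_a, kd_b, kd2_a = 1e6, kd2_b = 1e6,
                                 grid = "sixteen_point", noise_sd = 0.05,
                                 replicates = 3, seed = 1) {
  fr <- c(f_a, f_b, f_shared, f_resistant)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("subpopulation fractions must be nonnegative and sum to 1",
         call. = FALSE)
  }
  grid <- resolve_grid(grid)
  s <- function(d, kd) kd / (d + kd)   # survival of one kill mechanism
  v_a <- function(d) {
    (f_a + f_shared) * s(d, kd_a) + (f_b + f_resistant) * s(d, kd2_a)
  }
  v_b <- function(d) {
    (f_b + f_shared) * s(d, kd_b) + (f_a + f_resistant) * s(d, kd2_b)
  }
  v_ab <- function(total) {
    d <- total / 2
    f_a * s(d, kd_a) * s(d, kd2_b) +
      f_b * s(d, kd_b) * s(d, kd2_a) +
      f_shared * s(d, kd_a) * s(d, kd_b) +
      f_resistant * s(d, kd2_a) * s(d, kd2_b)
  }
  one <- function(role, vfun, drug) {
    d <- rep(grid, each = replicates)
    tibble::tibble(cell_line = "sim", drug = drug, role = role,
                   conc_nM = d, viability = vfun(d),
                   replicate = rep(seq_len(replicates), times = length(grid)))
  }
  out <- dplyr::bind_rows(one("a", v_a, "drugA"), one("b", v_b, "drugB"),
                          one("ab", v_ab, "drugA+drugB"))
  noisy <- with_seed(seed, out$viability +
                             stats::rnorm(nrow(out), 0, noise_sd))
  out$viability <- pmax(noisy, -0.05)
  out
}

#' Labeled fixture panel for classifier testing
#'
#' Builds a deterministic panel of curves with known ground-truth
#' categories on the 9-point screening grid: flat low-viability (LV), flat
#' uninhibited (NI), monophasic with nanomolar IC50 (MP), biphasic with
#' mid-range F1 (BP), and white-noise scatter (`scattered`, which QC
#' should reject). Generating parameters are drawn away from the
#' classification thresholds so labels are unambiguous.
#'
#' @param seed Integer seed.
#' @param k Curves per category.
#' @param noise_sd Noise for the model-generated categories.
#' @return Tibble of curves with a `true_category` column.
#' @export
fixture_panel <- function(seed = 1, k = 4, noise_sd = 0.03) {
  grid <- grid_gdsc_nine_point()
  with_seed(seed, {
    panels <- purrr::map_dfr(seq_len(k), function(i) {
      sub_seed <- sample.int(2^30, 5)
      lv <- simulate_curve(
        truth = list(model = "hill", i_max = 1 - stats::runif(1, 0.18, 0.25),
                     ic50_star = 1e-6, n = 1),
        grid = grid, noise_sd = 0.02, replicates = 2, seed = sub_seed[1],
        cell_line = sprintf("LV_%02d", i), drug = "dasatinib"
      )
      ni <- simulate_curve(
        truth = list(model = "biphasic", f1 = 0, kd1 = 1, kd2 = 1e8),
        grid = grid, noise_sd = 0.02, replicates = 2, seed = sub_seed[2],
        cell_line = sprintf("NI_%02d", i), drug = "dasatinib"
      )
      mp <- simulate_curve(
        truth = list(model = "monophasic",
                     ic50 = 10^stats::runif(1, log10(20), log10(80))),
        grid = grid, noise_sd = noise_sd, replicates = 2, seed = sub_seed[3],
        cell_line = sprintf("MP_%02d", i), drug = "dasatinib"
      )
      bp <- simulate_curve(
        truth = list(model = "biphasic", f1 = stats::runif(1, 0.40, 0.60),
                     kd1 = 10^stats::runif(1, log10(10), log10(40)),
                     kd2 = 1e5),
        grid = grid, noise_sd = noise_sd, replicates = 2, seed = sub_seed[4],
        cell_line = sprintf("BP_%02d", i), drug = "dasatinib"
      )
      sc <- simulate_curve(
        truth = list(model = "biphasic", f1 = 0.3, kd1 = 50, kd2 = 1e6),
        grid = grid, noise_sd = 0.30, replicates = 2, seed = sub_seed[5],
        cell_line = sprintf("SC_%02d", i), drug = "dasatinib"
      )
      dplyr::bind_rows(
        dplyr::mutate(lv, true_category = "LV"),
        dplyr::mutate(ni, true_category = "NI"),
        dplyr::mutate(mp, true_category = "MP"),
        dplyr::mutate(bp, true_category = "BP"),
        dplyr::mutate(sc, true_category = "scattered")
      )
    })
    panels
  })
}
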