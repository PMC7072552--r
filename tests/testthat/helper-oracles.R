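# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own closed forms and optimizer internals.

# bisection root-finder for the inhibition level x of any inhibition
# function, on a log10 concentration bracket
bisect_icx <- function(inhib_fn, x, lower = 1e-8, upper = 1e12,
                       tol = 1e-12) {
  f <- function(ld) inhib_fn(10^ld) - x
  lo <- log10(lower); hi <- log10(upper)
  stopifnot(f(lo) < 0, f(hi) > 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  10^((lo + hi) / 2)
}

# plain RMSE between observed viability and a predicted inhibition vector
oracle_rmse <- function(viability, inhibition) {
  sqrt(mean((viability - (1 - inhibition))^2))
}

# dense 1-D grid search for the best monophasic RMSE (log-spaced IC50s)
oracle_best_mono_rmse <- function(d, v, n_grid = 2000) {
  ic50s <- 10^seq(log10(min(d)) - 2, log10(max(d)) + 2,
                  length.out = n_grid)
  min(vapply(ic50s, function(k) {
    oracle_rmse(v, d / (d + k))
  }, numeric(1)))
}

# brute-force biphasic lattice search: >= 50 log-spaced points per Kd axis
# across the same bounds the fitter uses, 51 F1 values; returns the best
# lattice RMSE. Straightforward triple structure, no local refinement.
oracle_best_biphasic_rmse <- function(d, v, n_kd = 50, n_f1 = 51) {
  lo <- log10(min(d) / 100)
  hi <- log10(max(d) * 1e6)
  kds <- 10^seq(lo, hi, length.out = n_kd)
  f1s <- seq(0, 1, length.out = n_f1)
  phase <- sapply(kds, function(k) d / (d + k))   # m x n_kd
  best <- Inf
  for (i in seq_len(n_kd)) {
    for (j in i:n_kd) {
      for (f1 in f1s) {
        pred <- f1 * phase[, i] + (1 - f1) * phase[, j]
        r <- oracle_rmse(v, pred)
        if (r < best) best <- r
      }
    }
  }
  best
}

# random curve generator for property tests: mixed truth models, mixed
# grids and noise, fully determined by the seed
random_curve <- function(seed, grid = NULL) {
  set.seed(seed)
  model <- sample(c("monophasic", "hill", "biphasic"), 1)
  if (is.null(grid)) {
    grid <- sample(c("sixteen_point", "gdsc_nine_point"), 1)
  }
  g <- if (grid == "sixteen_point") grid_sixteen_point()
       else grid_gdsc_nine_point()
  truth <- switch(model,
    monophasic = list(model = "monophasic",
                      ic50 = 10^runif(1, log10(min(g)), log10(max(g)))),
    hill = list(model = "hill", i_max = runif(1, 0.3, 1),
                ic50_star = 10^runif(1, log10(min(g)), log10(max(g))),
                n = runif(1, 0.3, 2)),
    biphasic = list(model = "biphasic", f1 = runif(1, 0.1, 0.9),
                    kd1 = 10^runif(1, log10(min(g)), log10(max(g)) - 1),
                    kd2 = 10^runif(1, log10(max(g)), log10(max(g)) + 4))
  )
  simulate_curve(truth, grid = grid, noise_sd = runif(1, 0, 0.1),
                 replicates = sample(1:3, 1), seed = seed + 10000L)
}
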