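# biphasr

Quantitative dissection of cell-viability dose–response curves in
targeted-therapy screens.

Many cancer cell lines are **multi-driver**: their proliferation rests on
several independent oncogenic kinases, so a single targeted inhibitor
removes only the fraction of viability its target supports. The resulting
dose–response is *biphasic* — a nanomolar, target-specific phase followed
by a micromolar off-target phase — and the classical single-target IC50
badly mischaracterizes it. `biphasr` fits, compares and exploits three
nested inhibition models:

| model | equation | parameters |
|---|---|---|
| monophasic | `I = D / (D + IC50)` | `IC50` |
| modified Hill | `I = Imax·Dⁿ / (IC50*ⁿ + Dⁿ)` | `Imax`, `IC50*`, `n` |
| biphasic | `I = F1·D/(D + Kd1) + (1 − F1)·D/(D + Kd2)` | `F1`, `Kd1`, `Kd2` (with `F2 = 1 − F1`, `Kd1 ≤ Kd2`) |

where `I` is the inhibition of relative viability (`V = 1 − I`) at drug
concentration `D`. Fitting minimizes the RMSE between observed and
predicted viability with deterministic multi-start bounded optimization,
so `F1`/`Kd1` (target-specific potency and the fraction of viability it
controls) separate cleanly from `Kd2` (off-target toxicity).

On top of the fits the package provides:

* **screen classification** — normalization of raw readings against
  controls (including the highest-reading rule for low-dose growth
  upticks), scatter QC, and per-curve labeling as LV (low viability),
  NI (no inhibition), MP (monophasic, `F1 ≥ 0.85`) or BP (biphasic);
* **combination synergy** — ICx estimation from single-agent and 1:1
  combination curves and the aggregate dose reduction index
  `DRI = ICx_a·ICx_b / (ICx_ab·(ICx_a + ICx_b))`;
* **seeded synthetic data generators** for curves, combinations and
  labeled classifier panels, so the whole pipeline is testable offline.

Everything is tibble-in / tibble-out with `tidy()`, `glance()` and
`autoplot()` methods, plus a `biphasr` shell executable (`exec/biphasr`)
with `fit`, `synergy`, `classify` and `simulate` subcommands.

## Worked example

Fit a noisy biphasic curve (truth: `F1 = 0.57`, `Kd1 = 19.8` nM,
resistant off-target phase) and compare models:

```r
library(biphasr)

curve <- simulate_curve(
  truth = list(model = "biphasic", f1 = 0.57, kd1 = 19.8, kd2 = 2e6),
  grid = "sixteen_point", noise_sd = 0.03, replicates = 3, seed = 42,
  cell_line = "HT-29", drug = "HG6-64-1")

compare_models(curve)
#> <model comparison> preferred: biphasic (monophasic/biphasic RMSE ratio 6.93)
#> <monophasic dose-response fit>
#>   ic50 = 282.7 nM
#>   RMSE 0.2366 on 48 points (16 concentrations)
#> <hill dose-response fit>
#>   i_max = 0.5736
#>   ic50_star = 19.42 nM
#>   n = 1.103
#>   RMSE 0.03351 on 48 points (16 concentrations)
#> <biphasic dose-response fit>
#>   f1 = 0.5795
#>   kd1 = 20.16 nM
#>   kd2 = > 1000 uM [at bound]
#>   RMSE 0.03417 on 48 points (16 concentrations)
```

Read: the single-target fit is poor (RMSE 0.24) and its IC50 (283 nM)
describes neither phase. The biphasic fit recovers the generating truth —
58% of viability is controlled by a 20 nM target, the remainder is
essentially resistant (`Kd2` beyond the tested range, displayed as
`> 1000 uM` and flagged `at_bound`). The Hill fit (`Imax ≈ 0.57 < 1`)
independently confirms partial maximal inhibition.

Synergy of a 1:1 combination over independent driver subpopulations:

```r
combo <- simulate_combination(f_a = 0.45, f_b = 0.45, f_shared = 0,
                              f_resistant = 0.1, kd_a = 50, kd_b = 80,
                              kd2_a = 2e4, kd2_b = 2e4,
                              noise_sd = 0.02, seed = 42)
dri_table(subset(combo, role == "a"), subset(combo, role == "b"),
          subset(combo, role == "ab"), levels = c(0.4, 0.5, 0.6))
#>     x icx_a icx_b icx_ab icx_ab_per_drug attainable   dri
#> 1 0.4   286   510   99.5            49.8       TRUE  1.84
#> 2 0.5  1693  2413  145.9            72.9       TRUE  6.82
#> 3 0.6  7179  8402  239.1           119.5       TRUE 16.19
```

Each single agent needs micromolar doses for 50–60% inhibition (its
target controls under half of viability), while the combination reaches
the same levels at nanomolar total dose — a 7- to 16-fold dose reduction,
the quantitative signature of independent drivers.

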