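# auxintor

Quantitative analysis of how indole-3-acetic acid (IAA, the auxin
phytohormone) limits growth through TORC1 in budding yeast.

Yeast accumulates IAA as it approaches stationary phase, and IAA behaves as
an ATP-competitive inhibitor of the TORC1 kinase. Whether that matters in a
living cell depends on three numbers: the inhibitor's affinity
(K<sub>i</sub>), the kinase's Michaelis constant for ATP
(K<sub>m,ATP</sub>), and the prevailing ATP concentration. `auxintor`
implements the full analysis chain that connects raw screen and assay data
to that physiological conclusion:

* **SATAY fitness scoring** — per-gene fitness from saturated transposon
  insertion libraries: gene assignment of insertion sites, normalized
  log2(treated/control) scores
  `log2(((t + pc)/T) / ((c + pc)/C))`, and 10th/90th-percentile banding
  into depleted / neutral / enriched genes.
* **Chemical-genetic screening** — colony-size tables → plate-normalized
  drug/control ratios → robust z-scores
  `z = (median(r) − r) / (1.4826 · MAD(r))`, sensitivity calls at
  z ≥ 1.88, and exact hypergeometric set-overlap (Venn) statistics between
  drug profiles.
* **Inhibition kinetics** — global nonlinear least-squares fits of the
  classical steady-state rate laws (competitive
  `v = V_max S / (K_m(1 + I/K_i) + S)`, noncompetitive, uncompetitive,
  mixed) across all inhibitor levels at once, mechanism discrimination by
  AICc, case-resampling bootstrap intervals, and four-parameter logistic
  (4PL) IC50 fitting.
* **Physiology** — the Cheng–Prusoff effective IC50
  `IC50 = K_i (1 + [ATP]/K_m,ATP)`, percent inhibition
  `100·[I]/([I] + IC50)`, intracellular concentrations from
  isotope-dilution LC-MS amounts (pmol, cell counts, fL cell volumes), and
  growth bookkeeping (generations ↔ copies per founder).
* **Synthetic data** — seeded generators for every input above with a
  ground-truth record, so each stage has recovery tests.

The package is tidyverse-native: functions take data frames and return
tibbles, fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

The physiological argument in three calls. In exponential cells ATP sits
near 3 mM, so the effective IC50 for an ATP-competitive inhibitor with
K<sub>i</sub> = 2.4 µM and K<sub>m,ATP</sub> = 50.5 µM is high:

```r
library(auxintor)

effective_ic50(ki = 2.4, atp = 3000, km_atp = 50.5)
#> [1] 144.9743   # ~145 uM; sub-micromolar IAA is irrelevant here

predict_state(2.4, 50.5, atp = 56, iaa = 10, round_ic50 = TRUE)
#> # A tibble: 1 × 6
#>   label atp_uM iaa_uM ic50_effective_uM pct_inhibition round_ic50
#>   <chr>  <dbl>  <dbl>             <dbl>          <dbl> <lgl>
#> 1 NA        56     10               5.1           66.2 TRUE
```

When ATP collapses to ~56 µM in stationary phase, the effective IC50 drops
to 5.1 µM and the ~10 µM of accumulated IAA inhibits TORC1 by 66.2% — the
same compound goes from irrelevant to dominant purely through the ATP/Km
ratio.

The kinetic constants themselves come from a global fit. On synthetic data
(here standing in for a TORC1 in vitro assay; 8 ATP concentrations × IAA at
0/20/40 µM × 3 replicates, 5% noise):

```r
truth <- kinetic_params("competitive", Vmax = 100, Km = 50.5, Ki = 2.4)
sim <- simulate_kinetics(truth, cv = 0.05, replicates = 3, seed = 7)
select_mechanism(sim$data, c("competitive", "noncompetitive", "uncompetitive"))
#> <mechanism_selection> best: competitive
#> # A tibble: 3 × 5
#>   mechanism       aicc delta_aicc    sse n_params
#>   <chr>          <dbl>      <dbl>  <dbl>    <int>
#> 1 competitive     98.7         0    260.        3
#> 2 noncompetitive 322.        223.  5736.        3
#> 3 uncompetitive  366.        267. 10661.        3

fit_kinetics(sim$data, "competitive")
#> <kinetic_fit> competitive
#> <kinetic_params> competitive  Vmax = 101.8, Km = 51.04 uM, Ki = 2.416 uM
#>   SSE 259.6 on 72 obs; AICc 98.7; converged: TRUE
```

AICc picks the generating mechanism by a wide margin and the fit recovers
Km and Ki within a few percent. `reproduce_findings()` runs the analytic
checks (145 µM, 5.1 µM, 66.2%, the 85-of-156 = 54.5% screen overlap,
2^12.7 ≈ 7×10³ copies per founder) plus seeded recovery checks, and reports
each with a pass flag.

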