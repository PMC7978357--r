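---
title: "Models and methods behind auxintor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind auxintor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxintor)
```

`auxintor` chains four analyses — transposon-library fitness scoring,
colony-size chemical-genetic screening, enzyme-kinetic mechanism
discrimination, and a Cheng–Prusoff physiological model — into one
question: can the auxin IAA, an ATP-competitive inhibitor of the TORC1
kinase, meaningfully inhibit TORC1 inside a yeast cell? This vignette
records the models, the parameters that matter, the numerical choices, and
the limits of what the synthetic-data tests demonstrate.

## Transposon-library (SATAY) fitness scoring

**Model.** A saturated transposon library is a pool of clones, each
disrupted at one genomic position. After `g` generations of growth a clone
with relative fitness `f` (1 = wild type) is represented in proportion to
`2^(g·f)`; sequencing is a multinomial draw over clones with those
abundances as weights. The per-gene score compares read (or insertion-site)
shares between a treated and a control culture:

$$\mathrm{score} = \log_2 \frac{(t + pc)/T}{(c + pc)/C}$$

with `t`, `c` the per-gene counts, `T`, `C` the library totals and `pc` a
pseudocount. Genes at or below the 10th percentile of scores are banded
*depleted*, at or above the 90th *enriched*.

**Fitness applies under treatment only.** The generator interprets the
per-gene fitness map as fitness *in the presence of the drug*; in the
control culture every knockout grows neutrally. This is the standard
chemogenomic reading, and it is also forced by the arithmetic: if the same
`f` scaled growth in both cultures, any gene with `f < 1` would appear
*enriched* whenever the control ran for more generations than the treatment
(as in the experiment this emulates: 5.46 control vs 4.17 treated
generations), inverting the depletion signal the score is built to detect.

**Parameters.**

| parameter | default | unit | rationale |
|---|---|---|---|
| `pseudocount` | 1 | counts | bounds scores for zero-count genes |
| `low_pct` / `high_pct` | 10 / 90 | percentile | the decile bands used for depletion calls |
| `mode` | `"reads"` | — | read shares; `"sites"` (distinct insertions) also reported |
| `g_control` / `g_treated` | 5.46 / 4.17 | generations | the expansion of the experiment this emulates |
| `intergenic_fraction` | 0.1 | proportion | a minority of insertions misses coding sequence |

Both read- and site-based scores are carried in every output because assay
descriptions alternate between "reads per coding sequence" and
"transposition events"; the default is reads, and no claim is made about
which variant any particular published figure used.

**Numerical choices.** Percentile cutoffs use nearest-rank quantiles
(`stats::quantile(type = 1)`); ties at a cutoff fall into the extreme band.
If the score distribution is degenerate (cutoffs coincide) every gene would
satisfy both extreme rules, so the bands are returned all-neutral with a
warning instead. Genes with zero counts in both libraries score exactly 0.
The count-scale pseudocount means scores are not *exactly* invariant under
rescaling one library: the deviation is bounded by `log2(1 + pc/c)` for a
gene with `c` counts, negligible for covered genes and by design bounded
for empty ones; the test suite asserts exact invariance in the limit of a
vanishing pseudocount and the bound at `pc = 1`.

Insertion-to-gene assignment is 1-based inclusive on both ends,
strand-agnostic (a transposon disrupts an ORF on either strand), and an
insertion inside overlapping genes counts for each of them. Interval
queries go through `IRanges::findOverlaps`; a brute-force membership oracle
cross-checks it in the tests.

## Colony-size chemical-genetic screen

Colony sizes are normalized by their plate median (absorbing
plate-to-plate scale), averaged over replicate spots, and the per-strain
drug/control ratio `r` is standardized robustly:

$$z = \frac{\mathrm{median}(r) - r}{1.4826 \cdot \mathrm{MAD}(r)}$$

so a growth deficit gives a positive z; strains with `z ≥ 1.88` are called
sensitive, the screening platform's published cutoff. The original
platform's exact score construction is not public, so this module defines
its own: plate-median normalization plus median/MAD standardization was
chosen because it is scale-free (rescaling any plate changes nothing) and
robust to the sensitive tail itself. When drug and control behave
identically all ratios coincide; that case returns `z = 0` for every strain
rather than dividing by a zero MAD, while a zero MAD with *differing*
ratios is reported as a degenerate population error.

Overlaps between sensitivity profiles are counted exactly:
`overlap_stats()` reports both conditional percentages and an exact
hypergeometric upper-tail p-value, and `multi_set_report()` tabulates every
Venn region (the regions always partition the union).

**What the recovery test shows.** The generator plants a sensitive
subpopulation with a 50% growth deficit under 5% multiplicative noise. At
those settings a sensitive strain sits ~10 standardized units from the null
— recall is not the interesting question. Precision is: the null z
distribution is approximately standard normal, so ~1–3% of insensitive
strains always clear 1.88. The recovery test therefore uses a
candidate-enriched mini-screen (200 mutants, 15% sensitive), sized *a
priori* so the expected false positives (~1) are small against 30 true
positives. In a genome-scale screen (~4,800 strains, ~3% sensitive) the
same threshold would necessarily hand back tens of false positives and
precision near 0.6 — a property of one-sided z thresholds, not of this
implementation.

## Inhibition kinetics

**Rate laws.** The four classical reversible schemes, all reducing to
Michaelis–Menten at zero inhibitor:

* competitive: $v = V_{max} S / (K_m(1 + I/K_i) + S)$
* noncompetitive: $v = V_{max} S / ((1 + I/K_i)(K_m + S))$
* uncompetitive: $v = V_{max} S / (K_m + S(1 + I/K_i))$
* mixed: $v = V_{max} S / (K_m(1 + I/K_i) + S(1 + I/(\alpha K_i)))$

**Global fitting.** One parameter set is fitted across all inhibitor levels
jointly — that is how `K_i` is defined, and on a small grid (8 substrate ×
3 inhibitor levels is typical) per-curve fits would waste most of the
identifying information. Least squares runs in log-parameter space (BFGS,
relative tolerance 1e-12), which enforces positivity without a constrained
solver, from a multi-start grid: `Km` at the minimum / median / maximum of
the substrate grid, `Vmax` at 1.1× the largest observed velocity, `Ki` at
0.1× / 1× / 10× the median non-zero inhibitor level (α starts at 1). The
best SSE over all starts wins and the convergence flag is reported
honestly. Unweighted SSE is the default; `1/v²` weighting is available for
assays whose error scales with signal.

**Mechanism discrimination.** Candidates are ranked by the small-sample
corrected Akaike criterion

$$\mathrm{AICc} = n\ln(\mathrm{SSE}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

ascending, with ties broken toward fewer parameters (which is how
inhibitor-free data correctly falls back to plain Michaelis–Menten
against the 3-parameter schemes). Diagnostic signatures are verified in the
tests: under competitive inhibition the apparent `Km` from per-level fits
rises linearly in `I` with slope `Km/Ki` while `Vmax` is flat; under
noncompetitive inhibition `Vmax` scales as `1/(1 + I/Ki)` while `Km` is
flat.

**Uncertainty.** `bootstrap_ci()` does case-resampling with percentile
intervals. Resample refits warm-start at the full-data estimate (falling
back to the multi-start grid on failure); resamples with fewer than two
distinct substrate levels are skipped and counted. A 200-dataset simulation
study in the test suite checks that nominal 95% intervals cover the true
`Km` at ≥ 88%.

**Dose–response.** `fit_ic50()` fits the descending four-parameter
logistic `bottom + (top − bottom)/(1 + (d/IC50)^h)` by multi-start
L-BFGS-B with `bottom ≥ 0`, `top` initialised at the zero-dose mean, IC50
starts at the quartiles of the positive doses, and hill starts
{0.5, 1, 2}. A profile whose high-dose mean has not dropped at least 5%
below the zero-dose mean is refused as flat rather than returning an
unstable extrapolated IC50.

## Physiology: from constants to percent inhibition

For an ATP-competitive inhibitor the effective IC50 at a given ATP level is
the Cheng–Prusoff relation `IC50 = Ki(1 + [ATP]/Km)`, affine in ATP with
intercept `Ki`; occupancy then gives `% inhibition = 100·I/(I + IC50)`.
`predict_state()` chains the two. With `round_ic50 = TRUE` the
effective IC50 is rounded to two significant figures before the occupancy
step — with `Ki` = 2.4 µM, `Km` = 50.5 µM, ATP = 56 µM and IAA = 10 µM
this yields exactly 66.2%, while the unrounded chain gives 66.4%; the flag
makes the difference explicit instead of hiding it. (Note the
exponential-phase effective IC50, 144.97 µM, is conventionally quoted as
145 — three significant figures, unlike the 5.1.)

Unit conversions are centralized in `pmol_per_fl_to_uM()` (1 pmol per 10⁶
fL = 1 mM) and tested dimensionally. Intracellular concentrations assume
4 fL per exponentially growing cell and a 50% reduced volume (2 fL) for
G1-arrested stationary cells. Isotope-dilution quantification is an
unweighted OLS calibration of area ratio on amount ratio (6-point series)
with back-calculation `amount = (ratio − intercept)/slope · IS`; negative
back-calculations are clipped to zero and flagged. Growth bookkeeping is
`g = log2(n_end/n_start)` and `copies = 2^g` (12.7 generations ≈ 6.7×10³,
i.e. 7×10³ at one significant figure).

## What the generators emulate — and what they do not

The generators reproduce the *structure* of each assay with known truth:
clonal expansion with multinomial sequencing, a planted sensitive
subpopulation, rate-law velocities, 4PL curves and linear calibration, all
under multiplicative Gaussian noise truncated at zero (CV-style noise is
the natural first model for plate readers, densitometry and peak areas).
They deliberately omit: PCR and sequencing bias, positional insertion
preferences within ORFs and essential-gene margins, plate edge effects and
spatial gradients, signal-dependent error structure, chromatographic drift,
and carryover. Passing recovery tests therefore demonstrates that the
*estimators* are correct and well-conditioned at realistic noise levels —
not that real screens are free of the systematic effects the generators
exclude. All generators take a mandatory seed and never touch the global
RNG stream; identical seeds give byte-identical tables.

Problem sizes in the test suite are chosen to exercise each estimator well
inside a desk-scale run: the SATAY recovery uses 1,000 genes (50 planted at
`f = 0.5`), 10⁵ clones and 5×10⁶ reads per library; the kinetics
mechanism-selection study runs 100 seeded repeats at the 72-observation
design; the bootstrap coverage study uses 200 datasets of 18 observations
with 100 resamples each.

## Known limitations

* The z-score construction is this package's own robust definition; counts
  from screens scored by other platforms will not reproduce exactly even at
  the same 1.88 threshold.
* AICc-based selection assumes i.i.d. Gaussian residuals on the chosen
  weighting scale; strongly heteroscedastic assays should use `1/v²`
  weighting.
* The 4PL fit refuses non-decreasing profiles rather than fitting
  stimulatory (rising) dose–response curves.
* Tight-binding corrections (inhibitor depletion at `Ki` comparable to
  enzyme concentration) and progress-curve kinetics are out of scope.
* Cheng–Prusoff assumes purely competitive, rapid-equilibrium inhibition;
  it is exactly the regime the kinetic module's mechanism call is meant to
  establish first.
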