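#' Effective IC50 of an ATP-competitive inhibitor (Cheng-Prusoff)
#'
#' For a competitive inhibitor, the half-maximal inhibitory concentration at
#' a given concentration of the competing substrate follows the
#' Cheng-Prusoff relation `IC50 = Ki * (1 + [ATP]/Km_ATP)`: potency is set
#' jointly by the inhibitor's affinity and by how far the kinase sits above
#' its Km for ATP. The function is affine in `atp` with intercept `ki`.
#'
#' @param ki Inhibition constant, uM (> 0).
#' @param atp Competing ATP concentration, uM (>= 0).
#' @param km_atp Michaelis constant for ATP, uM (> 0).
#'
#' @return Effective IC50 in uM.
#' @export
#'
#' @examples
#' effective_ic50(2.4, 3000, 50.5)  # ~145 uM in exponential phase
#' effective_ic50(2.4, 56, 50.5)    # ~5.1 uM in stationary phase
effective_ic50 <- function(ki, atp, km_atp) {
  if (ki <= 0 || km_atp <= 0) rlang::abort("ki and km_atp must be > 0")
  if (any(atp < 0)) rlang::abort("atp must be >= 0")
  ki * (1 + atp / km_atp)
}

#' Percent inhibition from inhibitor concentration and IC50
#'
#' Single-site occupancy model: `% inhibition = 100 * I / (I + IC50)`,
#' strictly increasing in `I` and bounded below 100.
#'
#' @param inhibitor Inhibitor concentration, uM (>= 0).
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#'
#' @return Percent inhibition in `[0, 100)`.
#' @export
#'
#' @examples
#' percent_inhibition(10, 5.1)  # 66.2%
percent_inhibition <- function(inhibitor, ic50) {
  if (any(ic50 <= 0)) rlang::abort("ic50 must be > 0")
  if (any(inhibitor < 0)) rlang::abort("inhibitor must be >= 0")
  100 * inhibitor / (inhibitor + ic50)
}

#' Convert pmol amounts to micromolar concentration
#'
#' Unit helper shared by the physiology calculations: an amount in pmol
#' distributed over a volume in fL gives `amount/volume * 1e9` uM
#' (equivalently, 1 pmol per 1e6 fL is 1 mM).
#'
#' @param amount_pmol Amount in pmol.
#' @param volume_fL Volume in fL (> 0).
#' @return Concentration in uM.
#' @export
pmol_per_fl_to_uM <- function(amount_pmol, volume_fL) {
  if (any(volume_fL <= 0)) rlang::abort("volume must be > 0")
  amount_pmol / volume_fL * 1e9
}

#' Intracellular concentration from a cell-extract measurement
#'
#' Divides the measured analyte amount by the total cell volume of the
#' sample. Exponentially growing yeast cells are taken to have a volume of
#' 4 fL; G1-arrested stationary-phase cells a 50% reduced volume (2 fL).
#'
#' @param amount_pmol Analyte amount in the extract, pmol (>= 0).
#' @param n_cells Number of cells extracted (> 0).
#' @param cell_volume_fL Volume per cell, fL (default 4).
#'
#' @return Concentration in uM.
#' @export
#'
#' @examples
#' intracellular_concentration(4e-3, 1e6)              # 1 uM, exponential
#' intracellular_concentration(4e-3, 1e6, cell_volume_fL = 2)  # 2 uM, stationary
intracellular_concentration <- function(amount_pmol, n_cells,
                                        cell_volume_fL = 4) {
  if (any(n_cells <= 0)) rlang::abort("n_cells must be > 0")
  if (any(amount_pmol < 0)) rlang::abort("amount must be >= 0")
  pmol_per_fl_to_uM(amount_pmol, n_cells * cell_volume_fL)
}

#' Fit an isotope-dilution calibration curve
#'
#' Ordinary least squares of observed area ratios (analyte / internal
#' standard) on known amount ratios; the assay runs a 6-point series in
#' parallel with sample extraction.
#'
#' @param calibration Data frame with columns `amount_ratio`, `area_ratio`
#'   (>= 2 points).
#'
#' @return A `calibration_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points`. A non-positive slope is a calibration failure and errors.
#' @export
fit_calibration <- function(calibration) {
  calibration <- tibble::as_tibble(calibration)
  stopifnot(all(c("amount_ratio", "area_ratio") %in% names(calibration)))
  if (nrow(calibration) < 2) rlang::abort("need >= 2 calibration points")
  fit <- stats::lm(area_ratio ~ amount_ratio, data = calibration)
  slope <- unname(stats::coef(fit)[["amount_ratio"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  if (slope <= 0) {
    rlang::abort("calibration failure: non-positive slope",
                 class = "auxintor_calibration_failure")
  }
  sst <- sum((calibration$area_ratio - mean(calibration$area_ratio))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = nrow(calibration)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope %.4g, intercept %.4g (R^2 %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Absolute quantification by isotope dilution
#'
#' Back-calculates analyte amounts from analyte / internal-standard peak
#' areas: `amount = (area_ratio - intercept)/slope * is_amount`. Negative
#' back-calculations (below-blank signals) are clipped to 0 and flagged.
#'
#' @param measurements Data frame with columns `analyte_area` and `is_area`
#'   (internal-standard area, > 0); other columns pass through.
#' @param calibration A `calibration_fit` from [fit_calibration()], or a raw
#'   calibration table which is fitted on the fly.
#' @param is_amount Internal-standard spike, pmol (> 0); 10 pmol for cell
#'   extracts, 50 pmol for media in the assay this emulates.
#'
#' @return `measurements` with columns `area_ratio`, `amount_pmol` and
#'   `clipped` (TRUE where a negative back-calculation was clipped to 0)
#'   added.
#' @export
quantify_isotope_dilution <- function(measurements, calibration, is_amount = 10) {
  if (is_amount <= 0) rlang::abort("is_amount must be > 0")
  if (!inherits(calibration, "calibration_fit")) {
    calibration <- fit_calibration(calibration)
  }
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("analyte_area", "is_area") %in% names(measurements)))
  if (any(measurements$is_area <= 0)) {
    rlang::abort("internal-standard area must be > 0")
  }
  ratio <- measurements$analyte_area / measurements$is_area
  amount <- (ratio - calibration$intercept) / calibration$slope * is_amount
  measurements |>
    dplyr::mutate(area_ratio = ratio,
                  clipped = amount < 0,
                  amount_pmol = pmax(0, amount))
}

#' Growth bookkeeping: generations and copies per founder
#'
#' From start and end cell counts, the number of generations is
#' `g = log2(n_end/n_start)` and each founder cell is represented by `2^g`
#' copies. The transposon library expansion that motivates this bookkeeping
#' ran for 12.7 cell cycles, i.e. about 7e3 copies per founder.
#'
#' @param n_start,n_end Cell counts (> 0).
#'
#' @return One-row tibble `n_start`, `n_end`, `generations`,
#'   `copies_per_founder`.
#' @export
#'
#' @examples
#' growth_bookkeeping(1e6, 8e6)      # 3 generations, 8 copies
#' copies_from_generations(12.7)     # ~6654, i.e. 7e3 to 1 significant figure
growth_bookkeeping <- function(n_start, n_end) {
  if (any(n_start <= 0) || any(n_end <= 0)) {
    rlang::abort("cell counts must be > 0")
  }
  g <- log2(n_end / n_start)
  tibble::tibble(n_start = n_start, n_end = n_end, generations = g,
                 copies_per_founder = 2^g)
}

#' @rdname growth_bookkeeping
#' @param g Generations (>= 0).
#' @export
copies_from_generations <- function(g) {
  if (any(g < 0)) rlang::abort("generations must be >= 0")
  2^g
}

#' Predict TORC1 inhibition for a physiological state
#'
#' Chains [effective_ic50()] and [percent_inhibition()] for a cellular state
#' given by its ATP and inhibitor (IAA) concentrations. With
#' `round_ic50 = TRUE` the effective IC50 is rounded to 2 significant
#' figures before the inhibition step, matching how the headline numbers are
#' usually quoted; the unrounded chain differs slightly (66.4% vs 66.2% in
#' the stationary-phase example) and both are reported.
#'
#' @param ki Inhibition constant, uM.
#' @param km_atp Michaelis constant for ATP, uM.
#' @param atp ATP concentration of the state, uM.
#' @param iaa Inhibitor (IAA) concentration of the state, uM.
#' @param label Optional state label (e.g. "exponential", "stationary day 3").
#' @param round_ic50 Round the effective IC50 to 2 significant figures
#'   before computing percent inhibition.
#'
#' @return One-row tibble `label`, `atp_uM`, `iaa_uM`, `ic50_effective_uM`,
#'   `pct_inhibition`, `round_ic50`.
#' @export
#'
#' @examples
#' predict_state(2.4, 50.5, atp = 56, iaa = 10, round_ic50 = TRUE)  # 66.2%
#' predict_state(2.4, 50.5, atp = 3000, iaa = 0.2)  # negligible (~0.14%)
predict_state <- function(ki, km_atp, atp, iaa, label = NA_character_,
                          round_ic50 = FALSE) {
  ic50 <- effective_ic50(ki, atp, km_atp)
  ic50_used <- if (round_ic50) signif(ic50, 2) else ic50
  tibble::tibble(
    label = label, atp_uM = atp, iaa_uM = iaa,
    ic50_effective_uM = ic50_used,
    pct_inhibition = percent_inhibition(iaa, ic50_used),
    round_ic50 = round_ic50
  )
}
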