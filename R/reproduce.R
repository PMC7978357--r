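#' Recompute the headline analytic results and seeded recovery checks
#'
#' Runs the package end to end on its own inputs and reports each check with
#' its computed value, the expected value and a pass flag:
#' \itemize{
#'   \item the Cheng-Prusoff effective IC50 at exponential (3 mM) and
#'     stationary (56 uM) ATP,
#'   \item percent TORC1 inhibition at 10 uM IAA with the 2-significant-figure
#'     IC50,
#'   \item the sensitive-set overlap percentage (85 of 156),
#'   \item copies per founder after 12.7 generations,
#'   \item optionally, seeded simulation-recovery checks (competitive-fit Km
#'     and Ki, dose-response IC50) which take a few seconds.
#' }
#'
#' @param ki,km_atp Kinetic constants, uM.
#' @param seed Integer seed for the simulation-recovery checks.
#' @param include_simulations Run the seeded recovery checks as well.
#'
#' @return Tibble `check`, `computed`, `expected`, `tolerance`, `pass`, with
#'   attribute `all_pass`.
#' @export
#'
#' @examples
#' reproduce_findings(include_simulations = FALSE)
reproduce_findings <- function(ki = 2.4, km_atp = 50.5, seed = 1,
                               include_simulations = TRUE) {
  checks <- list()
  add <- function(check, computed, expected, tolerance) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, computed = computed, expected = expected,
      tolerance = tolerance,
      pass = abs(computed - expected) <= tolerance
    )
  }
  ic_exp <- effective_ic50(ki, 3000, km_atp)
  add("effective IC50, exponential ATP 3 mM (uM)", signif(ic_exp, 3), 145, 0.5)
  ic_stat <- effective_ic50(ki, 56, km_atp)
  add("effective IC50, stationary ATP 56 uM (uM)", signif(ic_stat, 2), 5.1, 0.05)
  pct <- predict_state(ki, km_atp, atp = 56, iaa = 10,
                       round_ic50 = TRUE)$pct_inhibition
  add("TORC1 inhibition at 10 uM IAA, stationary (%)", round(pct, 1), 66.2, 0.05)
  ov <- overlap_stats(sprintf("s%03d", 1:156),
                      sprintf("s%03d", c(1:85, 157:347)),
                      sprintf("s%03d", 1:999))
  add("IAA-sensitive strains also rapamycin-sensitive (%)",
      round(ov$pct_a_in_b, 1), 54.5, 0.05)
  add("copies per founder after 12.7 generations (1 s.f.)",
      signif(copies_from_generations(12.7), 1), 7e3, 0.5)
  if (include_simulations) {
    truth <- kinetic_params("competitive", Vmax = 100, Km = km_atp, Ki = ki)
    sim <- simulate_kinetics(truth, cv = 0.05, replicates = 3, seed = seed)
    fit <- fit_kinetics(sim$data, "competitive")
    add("seeded recovery: fitted Km (uM)", fit$params$Km, km_atp, 0.15 * km_atp)
    add("seeded recovery: fitted Ki (uM)", fit$params$Ki, ki, 0.15 * ki)
    dr <- simulate_dose_response(ic50 = 0.6, cv = 0.05, replicates = 3,
                                 seed = seed)
    dfit <- fit_ic50(dr$data)
    add("seeded recovery: growth IC50 (mM)", dfit$ic50, 0.6, 0.15 * 0.6)
  }
  out <- dplyr::bind_rows(checks)
  attr(out, "all_pass") <- all(out$pass)
  out
}
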