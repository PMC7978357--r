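#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter (`term`, `estimate`).
#' @export
tidy.kinetic_fit <- function(x, ...) {
  p <- x$params
  est <- c(Vmax = p$Vmax, Km = p$Km)
  if (!is.null(p$Ki)) est <- c(est, Ki = p$Ki)
  if (!is.null(p$alpha)) est <- c(est, alpha = p$alpha)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' Glance at a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return One-row tibble `mechanism`, `sse`, `aicc`, `n_obs`, `n_params`,
#'   `converged`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(mechanism = x$mechanism, sse = x$sse, aicc = x$aicc,
                 n_obs = x$n_obs, n_params = x$n_params,
                 converged = x$converged)
}

#' Tidy a dose-response fit
#'
#' @param x A `dose_response_fit` from [fit_ic50()].
#' @param ... Unused.
#' @return Tibble of `term`/`estimate` rows (ic50, hill, top, bottom).
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(term = c("ic50", "hill", "top", "bottom"),
                 estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' Glance at a dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return One-row tibble `ic50`, `hill`, `sse`, `n_obs`, `converged`.
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill = x$hill, sse = x$sse,
                 n_obs = x$n_obs, converged = x$converged)
}

#' Tidy a mechanism selection
#'
#' @param x A `mechanism_selection` from [select_mechanism()].
#' @param ... Unused.
#' @return The AICc ranking tibble.
#' @export
tidy.mechanism_selection <- function(x, ...) {
  x$ranking
}
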