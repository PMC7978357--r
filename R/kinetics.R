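#' Steady-state inhibition mechanisms
#'
#' Mechanisms supported by the rate-law machinery: plain Michaelis-Menten
#' (`"MM"`), and the four classical reversible inhibition schemes.
#' @export
kinetic_mechanisms <- c("MM", "competitive", "noncompetitive", "uncompetitive", "mixed")

#' Construct a set of kinetic parameters
#'
#' @param mechanism One of [kinetic_mechanisms].
#' @param Vmax Maximal velocity (signal units, > 0).
#' @param Km Michaelis constant, uM (> 0).
#' @param Ki Inhibition constant, uM (> 0; required unless `mechanism = "MM"`).
#' @param alpha Mixed-inhibition interaction factor (> 0; `mixed` only).
#'
#' @return An object of class `kinetic_params`.
#' @export
#'
#' @examples
#' kinetic_params("competitive", Vmax = 100, Km = 50.5, Ki = 2.4)
kinetic_params <- function(mechanism = kinetic_mechanisms, Vmax, Km,
                           Ki = NULL, alpha = NULL) {
  mechanism <- match.arg(mechanism)
  if (Vmax <= 0 || Km <= 0) rlang::abort("Vmax and Km must be > 0")
  if (mechanism != "MM") {
    if (is.null(Ki) || Ki <= 0) rlang::abort("Ki must be > 0 for inhibition mechanisms")
  }
  if (mechanism == "mixed") {
    if (is.null(alpha) || alpha <= 0) rlang::abort("alpha must be > 0 for the mixed mechanism")
  }
  structure(list(mechanism = mechanism, Vmax = Vmax, Km = Km,
                 Ki = Ki, alpha = alpha),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>", x$mechanism,
      sprintf(" Vmax = %.4g, Km = %.4g uM", x$Vmax, x$Km))
  if (!is.null(x$Ki)) cat(sprintf(", Ki = %.4g uM", x$Ki))
  if (!is.null(x$alpha)) cat(sprintf(", alpha = %.4g", x$alpha))
  cat("\n")
  invisible(x)
}

#' Steady-state velocity under a reversible inhibition mechanism
#'
#' Evaluates the classical steady-state rate laws. With inhibitor
#' concentration `I` and substrate `S`:
#' \describe{
#'   \item{MM}{`v = Vmax S / (Km + S)`}
#'   \item{competitive}{`v = Vmax S / (Km (1 + I/Ki) + S)`}
#'   \item{noncompetitive}{`v = Vmax S / ((1 + I/Ki) (Km + S))`}
#'   \item{uncompetitive}{`v = Vmax S / (Km + S (1 + I/Ki))`}
#'   \item{mixed}{`v = Vmax S / (Km (1 + I/Ki) + S (1 + I/(alpha Ki)))`}
#' }
#' All mechanisms reduce to Michaelis-Menten at `I = 0`.
#'
#' @param params A [kinetic_params()].
#' @param S Substrate concentration(s), uM (> 0).
#' @param I Inhibitor concentration(s), uM (>= 0). Recycled against `S`.
#'
#' @return Numeric vector of velocities.
#' @export
#'
#' @examples
#' p <- kinetic_params("competitive", Vmax = 100, Km = 50.5, Ki = 2.4)
#' velocity(p, S = 300, I = 20)  # 38.90
velocity <- function(params, S, I = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(S <= 0)) rlang::abort("substrate concentration must be > 0")
  if (any(I < 0)) rlang::abort("inhibitor concentration must be >= 0")
  rate_law(params$mechanism, S, I, Vmax = params$Vmax, Km = params$Km,
           Ki = params$Ki, alpha = params$alpha)
}

#' @keywords internal
rate_law <- function(mechanism, S, I, Vmax, Km, Ki = NULL, alpha = NULL) {
  switch(mechanism,
    MM = Vmax * S / (Km + S),
    competitive = Vmax * S / (Km * (1 + I / Ki) + S),
    noncompetitive = Vmax * S / ((1 + I / Ki) * (Km + S)),
    uncompetitive = Vmax * S / (Km + S * (1 + I / Ki)),
    mixed = Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki))),
    rlang::abort(paste0("unknown mechanism: ", mechanism))
  )
}

#' @keywords internal
n_mechanism_params <- function(mechanism) {
  switch(mechanism, MM = 2L, mixed = 4L, 3L)
}

#' Fit a steady-state rate law globally across inhibitor levels
#'
#' Fits one set of parameters (Vmax, Km and, for inhibition mechanisms, Ki
#' and alpha) to all velocity observations jointly, rather than fitting each
#' inhibitor level separately. Least squares is minimised in log-parameter
#' space (which enforces positivity) from a grid of multiple starting points:
#' Km at the minimum, median and maximum of the substrate grid; Vmax at 1.1x
#' the maximal observed velocity; Ki at 0.1x, 1x and 10x the median non-zero
#' inhibitor level. The best SSE over all starts is kept.
#'
#' @param data Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `velocity` (a `replicate` column is allowed and ignored).
#' @param mechanism One of [kinetic_mechanisms].
#' @param weighting `"none"` (default) for unweighted SSE, or `"1/v2"` for
#'   relative (1/velocity^2) weighting.
#'
#' @return A `kinetic_fit` object: list with `params` ([kinetic_params()]),
#'   `sse`, `n_obs`, `n_params`, `aicc`, `converged`, `mechanism`, `data`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_kinetics <- function(data, mechanism = kinetic_mechanisms,
                         weighting = c("none", "1/v2")) {
  mechanism <- match.arg(mechanism)
  weighting <- match.arg(weighting)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("substrate_uM", "inhibitor_uM", "velocity") %in% names(data)))
  k <- n_mechanism_params(mechanism)
  n <- nrow(data)
  if (n < k + 2) rlang::abort("need at least n_params + 2 observations")
  if (length(unique(data$substrate_uM)) < 2) {
    rlang::abort("need at least 2 distinct substrate levels")
  }
  S <- data$substrate_uM
  I <- data$inhibitor_uM
  v <- data$velocity
  w <- if (weighting == "1/v2") 1 / pmax(v, 1e-8)^2 else rep(1, n)

  obj <- function(lp) {
    pred <- do.call(rate_law, c(list(mechanism, S, I), lp_to_list(mechanism, lp)))
    sum(w * (v - pred)^2)
  }
  starts <- fit_starts(mechanism, S, I, v)
  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    res <- tryCatch(
      stats::optim(log(st), obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    rlang::abort("rate-law fit failed from every starting point")
  }
  est <- lp_to_list(mechanism, best$par)
  params <- kinetic_params(mechanism, Vmax = est$Vmax, Km = est$Km,
                           Ki = est$Ki, alpha = est$alpha)
  sse <- best$value
  aicc <- if (n > k + 1) n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  structure(list(params = params, sse = sse, n_obs = n, n_params = k,
                 aicc = aicc, converged = any_conv, mechanism = mechanism,
                 weighting = weighting, data = data),
            class = "kinetic_fit")
}

#' @keywords internal
lp_to_list <- function(mechanism, lp) {
  p <- exp(lp)
  out <- list(Vmax = p[[1]], Km = p[[2]], Ki = NULL, alpha = NULL)
  if (mechanism != "MM") out$Ki <- p[[3]]
  if (mechanism == "mixed") out$alpha <- p[[4]]
  out
}

#' @keywords internal
fit_starts <- function(mechanism, S, I, v) {
  km0 <- unique(c(min(S), stats::median(S), max(S)))
  vmax0 <- 1.1 * max(v)
  if (vmax0 <= 0) vmax0 <- 1
  if (mechanism == "MM") {
    return(lapply(km0, function(km) c(Vmax = vmax0, Km = km)))
  }
  med_i <- stats::median(I[I > 0])
  if (!is.finite(med_i) || med_i <= 0) med_i <- 1
  ki0 <- med_i * c(0.1, 1, 10)
  starts <- list()
  for (km in km0) for (ki in ki0) {
    st <- c(Vmax = vmax0, Km = km, Ki = ki)
    if (mechanism == "mixed") st <- c(st, alpha = 1)
    starts[[length(starts) + 1]] <- st
  }
  starts
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", x$mechanism, "\n")
  print(x$params)
  cat(sprintf("  SSE %.4g on %d obs; AICc %.4g; converged: %s\n",
              x$sse, x$n_obs, x$aicc, x$converged))
  invisible(x)
}

#' Rank candidate inhibition mechanisms by AICc
#'
#' Fits each candidate rate law to the same dataset and ranks the fits by
#' the small-sample corrected Akaike criterion
#' `AICc = n log(SSE/n) + 2k + 2k(k+1)/(n - k - 1)`, ascending. Ties (within
#' `1e-8`) break toward the mechanism with fewer parameters. Candidates whose
#' fits fail are dropped; if all fail, an error is raised.
#'
#' @param data As for [fit_kinetics()].
#' @param candidates Character vector of mechanisms to compare.
#' @param weighting Passed to [fit_kinetics()].
#'
#' @return A `mechanism_selection` object: list with `ranking` (tibble
#'   `mechanism`, `aicc`, `delta_aicc`, `sse`, `n_params`), `fits` (named
#'   list of `kinetic_fit`s) and `best` (the top-ranked mechanism).
#' @export
select_mechanism <- function(data, candidates = kinetic_mechanisms,
                             weighting = c("none", "1/v2")) {
  weighting <- match.arg(weighting)
  fits <- list()
  for (m in candidates) {
    f <- tryCatch(fit_kinetics(data, m, weighting), error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) == 0) rlang::abort("all candidate fits failed")
  ranking <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(mechanism = f$mechanism, aicc = f$aicc, sse = f$sse,
                   n_params = f$n_params)
  })
  ranking <- ranking |>
    dplyr::arrange(.data$aicc + 1e-8 * .data$n_params, .data$n_params) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc)) |>
    dplyr::relocate("mechanism", "aicc", "delta_aicc")
  structure(list(ranking = ranking, fits = fits,
                 best = ranking$mechanism[[1]]),
            class = "mechanism_selection")
}

#' @export
print.mechanism_selection <- function(x, ...) {
  cat("<mechanism_selection> best:", x$best, "\n")
  print(x$ranking)
  invisible(x)
}

#' Case-resampling bootstrap confidence intervals for kinetic parameters
#'
#' Resamples observations with replacement, refits the rate law (warm-started
#' at the full-data estimate, falling back to the multi-start grid when the
#' warm start fails) and returns percentile intervals. Degenerate resamples
#' (fewer than two distinct substrate levels, or failed refits) are skipped
#' and counted.
#'
#' @param data As for [fit_kinetics()].
#' @param mechanism One of [kinetic_mechanisms].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#'
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`; attribute `n_skipped` counts skipped resamples.
#' @export
bootstrap_ci <- function(data, mechanism = kinetic_mechanisms, n_boot = 200,
                         seed, level = 0.95) {
  mechanism <- match.arg(mechanism)
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  if (n_boot < 100) rlang::abort("n_boot must be >= 100")
  data <- tibble::as_tibble(data)
  fit <- fit_kinetics(data, mechanism)
  p0 <- fit$params
  start <- c(Vmax = p0$Vmax, Km = p0$Km,
             if (mechanism != "MM") c(Ki = p0$Ki),
             if (mechanism == "mixed") c(alpha = p0$alpha))
  k <- length(start)
  n <- nrow(data)
  draws <- matrix(NA_real_, n_boot, k)
  skipped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- data[idx, ]
      if (length(unique(d$substrate_uM)) < 2) { skipped <- skipped + 1L; next }
      est <- refit_warm(d, mechanism, start)
      if (is.null(est)) { skipped <- skipped + 1L; next }
      draws[b, ] <- est
    }
  })
  ok <- stats::complete.cases(draws)
  if (!any(ok)) rlang::abort("all bootstrap resamples were degenerate")
  alpha2 <- (1 - level) / 2
  out <- tibble::tibble(
    term = names(start),
    estimate = unname(start),
    conf.low = apply(draws[ok, , drop = FALSE], 2, stats::quantile, alpha2),
    conf.high = apply(draws[ok, , drop = FALSE], 2, stats::quantile, 1 - alpha2)
  )
  attr(out, "n_skipped") <- skipped
  attr(out, "n_boot") <- n_boot
  out
}

#' @keywords internal
refit_warm <- function(d, mechanism, start) {
  S <- d$substrate_uM; I <- d$inhibitor_uM; v <- d$velocity
  obj <- function(lp) {
    pred <- do.call(rate_law, c(list(mechanism, S, I), lp_to_list(mechanism, lp)))
    sum((v - pred)^2)
  }
  res <- tryCatch(
    stats::optim(log(start), obj, method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    f <- tryCatch(fit_kinetics(d, mechanism), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    p <- f$params
    return(c(p$Vmax, p$Km, p$Ki, p$alpha)[seq_along(start)])
  }
  exp(res$par)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `response = bottom + (top - bottom)/(1 + (dose/ic50)^hill)` by
#' multi-start least squares with `bottom` constrained non-negative and `top`
#' initialised at the mean zero-dose response. The IC50 is reported in the
#' input dose units.
#'
#' @param data Data frame with columns `dose` and `response` (a `replicate`
#'   column is allowed and ignored); at least 5 dose levels including 0.
#'
#' @return A `dose_response_fit`: list with `ic50`, `hill`, `top`, `bottom`,
#'   `sse`, `n_obs`, `converged`, `data`. Supports tidy/glance/autoplot.
#'   If the responses show no decrease across doses the fit is refused with
#'   an error of class `auxintor_flat_curve`.
#' @export
#'
#' @examples
#' sim <- simulate_dose_response(ic50 = 0.6, cv = 0, seed = 1)
#' fit_ic50(sim$data)
fit_ic50 <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("dose", "response") %in% names(data)))
  if (any(data$response < 0)) rlang::abort("responses must be >= 0")
  dose_levels <- sort(unique(data$dose))
  if (length(dose_levels) < 5 || min(dose_levels) != 0) {
    rlang::abort("need at least 5 dose levels including dose 0")
  }
  means <- data |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(m = mean(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$dose)
  top0 <- means$m[means$dose == 0]
  # refuse curves with no decrease: highest-dose mean must fall below the
  # zero-dose mean by more than a sliver
  if (dplyr::last(means$m) >= 0.95 * top0 || stats::sd(means$m) == 0) {
    rlang::abort("responses do not decrease across doses: flat or rising curve",
                 class = "auxintor_flat_curve")
  }
  d <- data$dose
  r <- data$response
  # parameters: top (free), bottom (>= 0), log ic50, log hill
  obj <- function(p) {
    pred <- logistic4(d, exp(p[[3]]), exp(p[[4]]), p[[1]], p[[2]])
    sum((r - pred)^2)
  }
  pos_doses <- dose_levels[dose_levels > 0]
  ic50_starts <- stats::quantile(pos_doses, c(0.25, 0.5, 0.75), names = FALSE)
  best <- NULL
  any_conv <- FALSE
  for (ic in ic50_starts) for (h in c(0.5, 1, 2)) {
    p0 <- c(top0, max(min(r), 1e-6), log(ic), log(h))
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(-Inf, 0, -Inf, -Inf),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) rlang::abort("dose-response fit failed from every start")
  p <- best$par
  top <- p[[1]]; bottom <- p[[2]]
  if (bottom > top) { tmp <- top; top <- bottom; bottom <- tmp }
  structure(list(ic50 = exp(p[[3]]), hill = exp(p[[4]]), top = top,
                 bottom = bottom, sse = best$value, n_obs = length(r),
                 converged = any_conv, data = data),
            class = "dose_response_fit")
}

#' @keywords internal
logistic4 <- function(dose, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g, hill = %.3g, top = %.4g, bottom = %.4g (SSE %.4g, n = %d)\n",
              x$ic50, x$hill, x$top, x$bottom, x$sse, x$n_obs))
  invisible(x)
}

#' Normalize blot signals to relative activities
#'
#' Densitometry plumbing for kinase-activity readouts: divides each lane's
#' target signal (e.g. a phospho-site band) by its loading signal (total
#' protein) and rescales so the reference condition is exactly 100%.
#'
#' @param data Data frame with columns `condition`, `target_signal`,
#'   `loading_signal`.
#' @param reference Value of `condition` to anchor at 100%.
#'
#' @return Input tibble with columns `normalized` and `activity_pct` added.
#' @export
relative_activity <- function(data, reference) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("condition", "target_signal", "loading_signal") %in% names(data)))
  if (any(data$loading_signal <= 0)) {
    rlang::abort("loading_signal must be > 0 in every lane")
  }
  if (!reference %in% data$condition) {
    rlang::abort("reference condition not present in data")
  }
  data <- dplyr::mutate(data, normalized = .data$target_signal / .data$loading_signal)
  ref <- mean(data$normalized[data$condition == reference])
  if (ref <= 0) rlang::abort("reference condition has zero normalized signal")
  dplyr::mutate(data, activity_pct = 100 * .data$normalized / ref)
}
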