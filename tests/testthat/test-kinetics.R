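# Rate laws, global fitting, mechanism selection, dose-response fitting.

comp_params <- function() kinetic_params("competitive", Vmax = 100, Km = 50.5, Ki = 2.4)

test_that("rate laws hit their closed-form anchors", {
  expect_equal(velocity(comp_params(), S = 300, I = 20),
               100 * 300 / (50.5 * (1 + 20 / 2.4) + 300))
  expect_equal(round(velocity(comp_params(), S = 300, I = 20), 2), 38.89)
  # half-saturation at S = Km, I = 0, every mechanism
  for (m in c("MM", "competitive", "noncompetitive", "uncompetitive")) {
    p <- kinetic_params(m, Vmax = 80, Km = 40,
                        Ki = if (m == "MM") NULL else 5)
    expect_equal(velocity(p, S = 40, I = 0), 40)
  }
  pm <- kinetic_params("mixed", Vmax = 80, Km = 40, Ki = 5, alpha = 2)
  expect_equal(velocity(pm, S = 40, I = 0), 40)
  # competitive inhibition is surmountable: S -> 1e6 Km approaches Vmax
  expect_equal(velocity(comp_params(), S = 1e6 * 50.5, I = 40), 100,
               tolerance = 1e-3)
})

test_that("every mechanism reduces to Michaelis-Menten at zero inhibitor", {
  S <- c(1, 5, 20, 50.5, 100, 500, 2000)
  mm <- velocity(kinetic_params("MM", Vmax = 100, Km = 50.5), S)
  for (m in c("competitive", "noncompetitive", "uncompetitive")) {
    p <- kinetic_params(m, Vmax = 100, Km = 50.5, Ki = 2.4)
    expect_equal(velocity(p, S, I = 0), mm, tolerance = 1e-15)
  }
  pm <- kinetic_params("mixed", Vmax = 100, Km = 50.5, Ki = 2.4, alpha = 3)
  expect_equal(velocity(pm, S, I = 0), mm, tolerance = 1e-15)
  expect_error(velocity(comp_params(), S = -1), "substrate")
  expect_error(velocity(comp_params(), S = 10, I = -1), "inhibitor")
})

test_that("noiseless data are recovered to high relative precision", {
  sim <- simulate_kinetics(comp_params(), cv = 0, replicates = 1, seed = 1)
  fit <- fit_kinetics(sim$data, "competitive")
  expect_lt(abs(fit$params$Vmax - 100) / 100, 1e-4)
  expect_lt(abs(fit$params$Km - 50.5) / 50.5, 1e-4)
  expect_lt(abs(fit$params$Ki - 2.4) / 2.4, 1e-4)
  expect_lt(fit$sse, 1e-4)
  expect_true(fit$converged)
  mm <- simulate_kinetics(kinetic_params("MM", Vmax = 100, Km = 50.5),
                          inhibitor_levels = 0, cv = 0, replicates = 1,
                          seed = 1)
  fmm <- fit_kinetics(mm$data, "MM")
  expect_equal(fmm$params$Km, 50.5, tolerance = 1e-4)
})

test_that("noisy global fits recover Km and Ki and beat a grid-search oracle", {
  sim <- simulate_kinetics(comp_params(), cv = 0.05, replicates = 3, seed = 9)
  fit <- fit_kinetics(sim$data, "competitive")
  expect_lt(abs(fit$params$Km - 50.5) / 50.5, 0.15)
  expect_lt(abs(fit$params$Ki - 2.4) / 2.4, 0.15)
  # independent oracle: coarse log-grid search refined by Nelder-Mead on the
  # plain (untransformed) parameterization
  d <- sim$data
  sse_of <- function(p) {
    pred <- p[1] * d$substrate_uM /
      (p[2] * (1 + d$inhibitor_uM / p[3]) + d$substrate_uM)
    sum((d$velocity - pred)^2)
  }
  grid <- expand.grid(Vmax = c(50, 100, 200),
                      Km = 10^seq(0, 3, length.out = 10),
                      Ki = 10^seq(-1, 2, length.out = 10))
  sses <- apply(grid, 1, sse_of)
  best <- as.numeric(grid[which.min(sses), ])
  oracle <- optim(best, sse_of, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
  expect_lte(fit$sse, oracle$value * (1 + 1e-6))
  expect_equal(fit$params$Km, oracle$par[2], tolerance = 0.01)
  expect_equal(fit$params$Ki, oracle$par[3], tolerance = 0.01)
})

test_that("fit preconditions are enforced", {
  sim <- simulate_kinetics(comp_params(), substrate_grid = c(10, 100),
                           cv = 0, replicates = 1, seed = 1)
  expect_error(fit_kinetics(sim$data[1:3, ], "competitive"), "observations")
  one_s <- sim$data[sim$data$substrate_uM == 10, ]
  expect_error(fit_kinetics(dplyr::bind_rows(one_s, one_s, one_s),
                            "competitive"), "distinct substrate")
})

test_that("AICc selects the generating mechanism and parsimony at I = 0", {
  sim <- simulate_kinetics(comp_params(), cv = 0.05, replicates = 3, seed = 17)
  sel <- select_mechanism(sim$data,
                          c("competitive", "noncompetitive", "uncompetitive"))
  expect_identical(sel$best, "competitive")
  nc <- simulate_kinetics(
    kinetic_params("noncompetitive", Vmax = 100, Km = 50.5, Ki = 10),
    cv = 0.05, replicates = 3, seed = 18)
  sel_nc <- select_mechanism(nc$data,
                             c("competitive", "noncompetitive", "uncompetitive"))
  expect_identical(sel_nc$best, "noncompetitive")
  # MM data observed only at I = 0: the 2-parameter model wins on AICc
  mm <- simulate_kinetics(kinetic_params("MM", Vmax = 100, Km = 50.5),
                          inhibitor_levels = 0, cv = 0.02, replicates = 3,
                          seed = 19)
  sel_mm <- select_mechanism(mm$data, c("MM", "competitive", "noncompetitive"))
  expect_identical(sel_mm$best, "MM")
})

test_that("mechanism selection is reliable over repeated noisy simulations", {
  correct <- c(noncompetitive = 0L, uncompetitive = 0L)
  n_rep <- 30
  for (m in names(correct)) {
    p <- kinetic_params(m, Vmax = 100, Km = 50.5, Ki = 10)
    for (i in seq_len(n_rep)) {
      sim <- simulate_kinetics(p, cv = 0.05, replicates = 3, seed = 1000 + i)
      sel <- select_mechanism(sim$data,
                              c("competitive", "noncompetitive", "uncompetitive"))
      if (sel$best == m) correct[m] <- correct[m] + 1L
    }
  }
  expect_gte(correct[["noncompetitive"]], round(0.9 * n_rep))
  expect_gte(correct[["uncompetitive"]], round(0.9 * n_rep))
})

test_that("competitive and noncompetitive signatures show in per-level MM fits", {
  levels_i <- c(0, 10, 20, 40)
  per_level_mm <- function(params) {
    purrr::map_dfr(levels_i, function(ii) {
      sim <- simulate_kinetics(params,
                               substrate_grid = signif(10^seq(0.5, 3.5, length.out = 10), 4),
                               inhibitor_levels = ii, cv = 0, replicates = 1,
                               seed = 1)
      f <- fit_kinetics(sim$data, "MM")
      tibble::tibble(I = ii, Km_app = f$params$Km, Vmax_app = f$params$Vmax)
    })
  }
  comp <- per_level_mm(comp_params())
  # apparent Km rises linearly with slope Km/Ki; Vmax invariant
  slope <- coef(lm(Km_app ~ I, data = comp))[["I"]]
  expect_equal(slope, 50.5 / 2.4, tolerance = 1e-3)
  expect_equal(comp$Vmax_app, rep(100, 4), tolerance = 1e-4)
  nc <- per_level_mm(kinetic_params("noncompetitive", Vmax = 100, Km = 50.5,
                                    Ki = 10))
  expect_equal(nc$Vmax_app, 100 / (1 + levels_i / 10), tolerance = 1e-4)
  expect_equal(nc$Km_app, rep(50.5, 4), tolerance = 1e-3)
})

test_that("bootstrap intervals are reproducible, contain the estimate and shrink at cv = 0", {
  sim <- simulate_kinetics(comp_params(), cv = 0.05, replicates = 2, seed = 23)
  ci1 <- bootstrap_ci(sim$data, "competitive", n_boot = 100, seed = 5)
  ci2 <- bootstrap_ci(sim$data, "competitive", n_boot = 100, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$conf.low <= ci1$estimate & ci1$estimate <= ci1$conf.high))
  exact <- simulate_kinetics(comp_params(), cv = 0, replicates = 2, seed = 1)
  ci0 <- bootstrap_ci(exact$data, "competitive", n_boot = 100, seed = 5)
  expect_lt(max(ci0$conf.high - ci0$conf.low), 1e-3 * max(ci0$estimate))
})

test_that("bootstrap 95% intervals cover the true Km at near-nominal rate", {
  p <- kinetic_params("MM", Vmax = 100, Km = 50.5)
  n_data <- 200
  covered <- 0L
  for (i in seq_len(n_data)) {
    sim <- simulate_kinetics(p, substrate_grid = c(10, 30, 60, 120, 300, 1000),
                             inhibitor_levels = 0, cv = 0.05, replicates = 3,
                             seed = 5000 + i)
    ci <- bootstrap_ci(sim$data, "MM", n_boot = 100, seed = i)
    km <- ci[ci$term == "Km", ]
    if (km$conf.low <= 50.5 && 50.5 <= km$conf.high) covered <- covered + 1L
  }
  expect_gte(covered / n_data, 0.88)
})

test_that("4PL fitting recovers exact and noisy dose-response curves", {
  exact <- simulate_dose_response(ic50 = 0.6, hill = 1, cv = 0,
                                  replicates = 1, seed = 1)
  f <- fit_ic50(exact$data)
  expect_equal(f$ic50, 0.6, tolerance = 1e-4)
  expect_equal(f$hill, 1, tolerance = 1e-3)
  expect_equal(f$top, 100, tolerance = 1e-3)
  noisy <- simulate_dose_response(ic50 = 2.35, hill = 1,
                                  doses = c(0, signif(10^seq(log10(0.2), log10(20),
                                                             length.out = 8), 3)),
                                  cv = 0.05, replicates = 3, seed = 29)
  fn <- fit_ic50(noisy$data)
  expect_lt(abs(fn$ic50 - 2.35) / 2.35, 0.15)
})

test_that("flat or rising response profiles refuse to fit", {
  flat <- tidyr::expand_grid(dose = c(0, 0.1, 0.3, 1, 3), replicate = 1:2)
  flat$response <- 100
  expect_error(fit_ic50(flat), class = "auxintor_flat_curve")
  expect_error(fit_ic50(tibble::tibble(dose = c(0, 1, 2), response = c(3, 2, 1))),
               "5 dose levels")
})

test_that("relative activity normalizes to the reference lane", {
  tab <- tibble::tibble(condition = c("ref", "a", "b"),
                        target_signal = c(4, 4, 2),
                        loading_signal = c(4, 4, 4))
  out <- relative_activity(tab, reference = "ref")
  expect_equal(out$activity_pct, c(100, 100, 50))
  set.seed(41)
  rnd <- tibble::tibble(condition = paste0("c", 1:10),
                        target_signal = runif(10, 1, 5),
                        loading_signal = runif(10, 1, 5))
  out2 <- relative_activity(rnd, reference = "c1")
  hand <- (rnd$target_signal / rnd$loading_signal) /
    (rnd$target_signal[1] / rnd$loading_signal[1]) * 100
  expect_equal(out2$activity_pct, hand)
  bad <- dplyr::mutate(tab, loading_signal = c(0, 4, 4))
  expect_error(relative_activity(bad, reference = "ref"), "loading_signal")
})
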