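#' @keywords internal
new_simulation_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> seed =", x$seed, "\n")
  cat("  fields:", paste(setdiff(names(x), "seed"), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a paired SATAY transposon library (control vs treated)
#'
#' Emulates the selection experiment behind saturated transposon analysis in
#' yeast (SATAY): a pooled library of transposon insertion clones is split
#' into a control and a drug-treated culture and regrown. Each clone carries
#' an insertion at a fixed genomic position; its abundance after `g`
#' generations is proportional to `2^(g * f)`, where `f` is the clone's
#' relative fitness in that condition (1 = wild-type growth rate). The
#' per-gene fitness map describes fitness *under treatment*; in the control
#' culture all knockouts grow neutrally (`f = 1`), so control read shares
#' reflect library composition only. Sequencing is modelled as a multinomial
#' draw of `library_reads` reads with clone abundances as weights.
#'
#' Insertion positions are uniform within the body of the clone's target gene
#' (or within intergenic space for the intergenic fraction); genes are chosen
#' uniformly at random.
#'
#' @param genome A [genome_spec()].
#' @param per_gene_fitness Named numeric vector or list mapping gene_id to
#'   relative fitness under treatment (>= 0). Genes not named default to 1.
#' @param n_clones Number of independent insertion clones in the library.
#' @param library_reads Total sequencing reads per condition (exact).
#' @param g_control,g_treated Generations of growth in each condition (>= 0).
#' @param intergenic_fraction Fraction of clones with intergenic insertions,
#'   in `[0, 1)`.
#' @param seed Integer seed (mandatory; the generator never touches the
#'   global RNG stream).
#'
#' @return A list with insertion tibbles `control` and `treated` (columns
#'   `chrom`, `pos`, `strand`, `reads`; one row per distinct insertion site)
#'   and `truth`, a `simulation_truth` carrying the seed, the fitness map and
#'   the generation counts.
#' @export
simulate_satay_pair <- function(genome, per_gene_fitness = NULL,
                                n_clones = 1e5, library_reads = 5e6,
                                g_control = 5.46, g_treated = 4.17,
                                intergenic_fraction = 0.1, seed) {
  stopifnot(inherits(genome, "genome_spec"))
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  if (n_clones < 1 || library_reads < 1) {
    rlang::abort("n_clones and library_reads must be >= 1")
  }
  if (intergenic_fraction < 0 || intergenic_fraction >= 1) {
    rlang::abort("intergenic_fraction must lie in [0, 1)")
  }
  genes <- genome$genes
  if (nrow(genes) == 0 && intergenic_fraction == 0) {
    rlang::abort("empty gene set with intergenic_fraction = 0: nothing to insert into")
  }
  fit <- rep(1, nrow(genes))
  names(fit) <- genes$gene_id
  if (!is.null(per_gene_fitness)) {
    pf <- unlist(per_gene_fitness)
    unknown <- setdiff(names(pf), genes$gene_id)
    if (length(unknown) > 0) {
      rlang::abort(paste0("fitness given for unknown genes: ",
                          paste(unknown, collapse = ", ")))
    }
    if (any(pf < 0)) rlang::abort("fitness must be >= 0")
    fit[names(pf)] <- pf
  }
  if (g_control < 0 || g_treated < 0) rlang::abort("generations must be >= 0")

  intergenic <- intergenic_intervals(genome)
  withr::with_seed(seed, {
    is_intergenic <- stats::runif(n_clones) < intergenic_fraction &
      nrow(intergenic) > 0
    gene_idx <- sample.int(max(nrow(genes), 1L), n_clones, replace = TRUE)
    pos <- integer(n_clones)
    chrom <- character(n_clones)
    clone_fit <- rep(1, n_clones)
    genic <- which(!is_intergenic)
    if (length(genic) > 0) {
      gi <- gene_idx[genic]
      pos[genic] <- genes$start[gi] +
        floor(stats::runif(length(genic)) * (genes$end[gi] - genes$start[gi] + 1))
      chrom[genic] <- genes$chrom[gi]
      clone_fit[genic] <- fit[gi]
    }
    inter <- which(is_intergenic)
    if (length(inter) > 0) {
      w <- intergenic$end - intergenic$start + 1
      ii <- sample.int(nrow(intergenic), length(inter), replace = TRUE, prob = w)
      pos[inter] <- intergenic$start[ii] +
        floor(stats::runif(length(inter)) * w[ii])
      chrom[inter] <- intergenic$chrom[ii]
    }
    strand <- sample(c("+", "-"), n_clones, replace = TRUE)

    # clonal expansion: weights 2^(g*f); control knockouts are neutral
    w_control <- rep(2^g_control, n_clones)
    w_treated <- 2^(g_treated * clone_fit)
    reads_control <- as.vector(stats::rmultinom(1, library_reads,
                                                prob = w_control))
    reads_treated <- as.vector(stats::rmultinom(1, library_reads,
                                                prob = w_treated))
    clones <- tibble::tibble(chrom = chrom, pos = pos, strand = strand,
                             reads_control = reads_control,
                             reads_treated = reads_treated)
  })
  collapse <- function(col) {
    clones |>
      dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
      dplyr::summarise(reads = sum(.data[[col]]), .groups = "drop") |>
      dplyr::arrange(.data$chrom, .data$pos)
  }
  truth <- new_simulation_truth(
    seed = seed,
    per_gene_fitness = fit,
    generations_control = g_control,
    generations_treated = g_treated,
    n_clones = n_clones,
    library_reads = library_reads
  )
  list(control = collapse("reads_control"),
       treated = collapse("reads_treated"),
       truth = truth)
}

#' @keywords internal
intergenic_intervals <- function(genome) {
  purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(i) {
    cc <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    g <- genome$genes[genome$genes$chrom == cc, ]
    if (nrow(g) == 0) {
      return(tibble::tibble(chrom = cc, start = 1L, end = as.integer(len)))
    }
    ir <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = as.integer(len))
    if (length(gaps) == 0) return(tibble::tibble())
    tibble::tibble(chrom = cc, start = IRanges::start(gaps),
                   end = IRanges::end(gaps))
  })
}

#' Simulate a colony-size chemical-genetic screen
#'
#' Emulates a deletion-collection screen in which each mutant strain is
#' spotted in replicate on control and drug plates and colony sizes are
#' measured. A random subset of strains (drawn without replacement) is
#' drug-sensitive: their expected colony size on drug is `(1 - effect)` times
#' the control expectation. Sizes carry multiplicative Gaussian noise with
#' relative SD `noise_sd`, truncated at zero.
#'
#' @param n_mutants Number of deletion strains.
#' @param sensitive_fraction Fraction of strains that are drug-sensitive.
#' @param effect Mean relative growth deficit of sensitive strains on drug
#'   (e.g. 0.5 halves colony size); must be > 0.
#' @param noise_sd Relative (CV-style) standard deviation of colony sizes.
#' @param plates Number of plates the strains are distributed over.
#' @param replicates Spots per strain per condition (the screen used
#'   quadruplicates).
#' @param seed Integer seed.
#'
#' @return List with colony tibbles `control` and `drug` (columns `strain`,
#'   `plate`, `replicate`, `size`) and `truth` carrying `sensitive_strains`
#'   and `effect`.
#' @export
simulate_colony_screen <- function(n_mutants = 384, sensitive_fraction = 0.1,
                                   effect = 0.5, noise_sd = 0.05,
                                   plates = 4, replicates = 4, seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  if (replicates < 1) rlang::abort("replicates must be >= 1")
  if (sensitive_fraction < 0 || sensitive_fraction > 1) {
    rlang::abort("sensitive_fraction must lie in [0, 1]")
  }
  if (effect <= 0) rlang::abort("effect must be > 0")
  strains <- sprintf("strain%04d", seq_len(n_mutants))
  plate_of <- sprintf("plate%02d", (seq_len(n_mutants) - 1L) %% plates + 1L)
  withr::with_seed(seed, {
    n_sens <- round(n_mutants * sensitive_fraction)
    sensitive <- sort(sample(strains, n_sens))
    base <- 1  # arbitrary colony-size unit
    grid <- tidyr::expand_grid(idx = seq_len(n_mutants),
                               replicate = seq_len(replicates))
    noisy <- function(mu) pmax(0, mu * (1 + stats::rnorm(nrow(grid), 0, noise_sd)))
    control <- tibble::tibble(
      strain = strains[grid$idx], plate = plate_of[grid$idx],
      replicate = grid$replicate, size = noisy(rep(base, nrow(grid)))
    )
    mu_drug <- ifelse(strains[grid$idx] %in% sensitive, base * (1 - effect), base)
    drug <- tibble::tibble(
      strain = strains[grid$idx], plate = plate_of[grid$idx],
      replicate = grid$replicate, size = noisy(mu_drug)
    )
  })
  truth <- new_simulation_truth(seed = seed, sensitive_strains = sensitive,
                                effect = effect, noise_sd = noise_sd)
  list(control = control, drug = drug, truth = truth)
}

#' Simulate steady-state kinase velocity data under an inhibition mechanism
#'
#' Generates initial-velocity observations on a substrate-by-inhibitor grid
#' from the chosen steady-state rate law (see [velocity()]), with
#' multiplicative Gaussian noise (`v * (1 + e)`, `e ~ N(0, cv)`, truncated at
#' zero). Defaults mirror the in vitro TORC1 kinase assay: inhibitor levels
#' 0, 20 and 40 uM and triplicate measurements.
#'
#' @param params A [kinetic_params()].
#' @param substrate_grid Substrate (e.g. ATP) concentrations, uM; all > 0.
#' @param inhibitor_levels Inhibitor concentrations, uM; 0 allowed.
#' @param cv Relative SD of the multiplicative noise (>= 0).
#' @param replicates Replicates per grid point.
#' @param seed Integer seed.
#'
#' @return List with `data` (tibble `substrate_uM`, `inhibitor_uM`,
#'   `velocity`, `replicate`) and `truth` carrying the generating parameters.
#' @export
simulate_kinetics <- function(params,
                              substrate_grid = signif(10^seq(1, 3, length.out = 8), 3),
                              inhibitor_levels = c(0, 20, 40),
                              cv = 0.05, replicates = 3, seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  stopifnot(inherits(params, "kinetic_params"))
  if (cv < 0) rlang::abort("cv must be >= 0")
  if (length(substrate_grid) == 0 || length(inhibitor_levels) == 0) {
    rlang::abort("substrate and inhibitor grids must be non-empty")
  }
  if (any(substrate_grid <= 0)) rlang::abort("substrate concentrations must be > 0")
  if (any(inhibitor_levels < 0)) rlang::abort("inhibitor concentrations must be >= 0")
  grid <- tidyr::expand_grid(substrate_uM = substrate_grid,
                             inhibitor_uM = inhibitor_levels,
                             replicate = seq_len(replicates))
  v0 <- velocity(params, grid$substrate_uM, grid$inhibitor_uM)
  withr::with_seed(seed, {
    v <- pmax(0, v0 * (1 + stats::rnorm(nrow(grid), 0, cv)))
  })
  data <- dplyr::mutate(grid, velocity = v)
  truth <- new_simulation_truth(seed = seed, kinetic_params = params, cv = cv)
  list(data = data, truth = truth)
}

#' Simulate a four-parameter logistic dose-response table
#'
#' Responses follow `bottom + (top - bottom) / (1 + (dose/ic50)^hill)` so the
#' curve starts at `top` at dose zero and passes through the midpoint
#' `(top + bottom)/2` at `dose = ic50`. Noise is multiplicative Gaussian,
#' truncated at zero.
#'
#' @param ic50 Half-maximal inhibitory concentration (> 0), in dose units.
#' @param hill Hill slope (non-zero; positive for descending curves).
#' @param top,bottom Asymptotes (response units, e.g. % of control).
#' @param doses Dose levels (>= 0); include 0 for the untreated anchor.
#' @param cv Relative SD of the noise.
#' @param replicates Replicates per dose.
#' @param seed Integer seed.
#'
#' @return List with `data` (tibble `dose`, `response`, `replicate`) and
#'   `truth` carrying `dose_response_params`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   doses = c(0, signif(10^seq(log10(0.05), log10(5),
                                                              length.out = 8), 3)),
                                   cv = 0.05, replicates = 3, seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  if (ic50 <= 0) rlang::abort("ic50 must be > 0")
  if (hill == 0) rlang::abort("hill slope must be non-zero")
  if (any(doses < 0)) rlang::abort("doses must be >= 0")
  grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
  mu <- logistic4(grid$dose, ic50, hill, top, bottom)
  withr::with_seed(seed, {
    resp <- pmax(0, mu * (1 + stats::rnorm(nrow(grid), 0, cv)))
  })
  truth <- new_simulation_truth(
    seed = seed,
    dose_response_params = list(ic50 = ic50, hill = hill, top = top, bottom = bottom)
  )
  list(data = dplyr::mutate(grid, response = resp), truth = truth)
}

#' Simulate isotope-dilution LC-MS measurements with a calibration series
#'
#' Each sample yields an analyte and an internal-standard (stable-isotope
#' labelled) peak area; the expected area ratio is
#' `slope * amount / is_amount + intercept`, with multiplicative noise on the
#' ratio. A 6-point calibration series spanning the working range is
#' generated alongside, as in parallel-extracted calibration curves.
#'
#' @param true_amounts Analyte amounts per sample, pmol.
#' @param is_amount Internal-standard spike, pmol (> 0). 10 pmol for cell
#'   extracts, 50 pmol for culture media in the assay this emulates.
#' @param slope Response factor (> 0); intercept the area-ratio offset.
#' @param intercept Area-ratio offset at zero analyte.
#' @param cv Relative SD of the area-ratio noise.
#' @param seed Integer seed.
#'
#' @return List with `measurements` (tibble `sample`, `analyte_area`,
#'   `is_area`), `calibration` (tibble `amount_ratio`, `area_ratio`, 6 rows)
#'   and `truth` carrying `true_amounts`.
#' @export
simulate_lcms <- function(true_amounts, is_amount = 10, slope = 1,
                          intercept = 0, cv = 0.02, seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  if (is_amount <= 0) rlang::abort("is_amount must be > 0")
  if (slope <= 0) rlang::abort("slope must be > 0")
  if (cv < 0) rlang::abort("cv must be >= 0")
  n <- length(true_amounts)
  cal_ratios <- c(0.05, 0.1, 0.25, 0.5, 1, 2)  # 6-point series
  withr::with_seed(seed, {
    is_area <- 1e6 * (1 + stats::rnorm(n, 0, cv))
    ratio <- (slope * true_amounts / is_amount + intercept) *
      (1 + stats::rnorm(n, 0, cv))
    ratio <- pmax(0, ratio)
    measurements <- tibble::tibble(
      sample = sprintf("sample%02d", seq_len(n)),
      analyte_area = ratio * is_area,
      is_area = is_area
    )
    cal_obs <- pmax(0, (slope * cal_ratios + intercept) *
                      (1 + stats::rnorm(length(cal_ratios), 0, cv)))
    calibration <- tibble::tibble(amount_ratio = cal_ratios, area_ratio = cal_obs)
  })
  truth <- new_simulation_truth(seed = seed, true_amounts = true_amounts,
                                is_amount = is_amount, slope = slope,
                                intercept = intercept)
  list(measurements = measurements, calibration = calibration, truth = truth)
}
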