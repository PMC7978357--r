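#' Z-score sensitivity calls for a colony-size chemical-genetic screen
#'
#' For each strain, colony sizes are first normalized by the median size of
#' their plate (removing plate-to-plate scale), then averaged over
#' replicates, separately in the drug and control conditions. The per-strain
#' ratio `r = drug / control` is standardized robustly over all strains,
#' `z = (median(r) - r) / (1.4826 * MAD(r))`, so that a growth deficit on
#' drug gives a positive z. Strains with `z >=` the threshold are called
#' sensitive; 1.88 is the screening platform's published cutoff.
#'
#' @param drug,control Colony tibbles with columns `strain`, `plate`,
#'   `replicate`, `size`.
#' @param threshold Sensitivity cutoff on z (default 1.88).
#'
#' @return Tibble `strain`, `ratio`, `z`, `sensitive`, sorted by decreasing
#'   z. Strains missing from the control table are dropped with a warning;
#'   a zero MAD (degenerate population) is an error.
#' @export
compute_zscores <- function(drug, control, threshold = 1.88) {
  if (threshold <= 0) rlang::abort("threshold must be > 0")
  drug <- tibble::as_tibble(drug)
  control <- tibble::as_tibble(control)
  need <- c("strain", "plate", "replicate", "size")
  stopifnot(all(need %in% names(drug)), all(need %in% names(control)))
  if (any(drug$size < 0) || any(control$size < 0)) {
    rlang::abort("colony sizes must be >= 0")
  }
  strain_means <- function(tab) {
    tab |>
      dplyr::group_by(.data$plate) |>
      dplyr::mutate(norm = .data$size / stats::median(.data$size)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(mean_size = mean(.data$norm), .groups = "drop")
  }
  md <- strain_means(drug)
  mc <- strain_means(control)
  missing <- setdiff(md$strain, mc$strain)
  if (length(missing) > 0) {
    rlang::warn(paste0(length(missing),
                       " strain(s) absent from the control plates were dropped"))
  }
  common <- intersect(md$strain, mc$strain)
  if (length(common) == 0) rlang::abort("no strains shared between drug and control")
  r <- md$mean_size[match(common, md$strain)] /
    mc$mean_size[match(common, mc$strain)]
  s <- stats::mad(r)  # 1.4826 * median absolute deviation
  if (s == 0) {
    if (all(r == stats::median(r))) {
      # identical drug and control behaviour: no spread, nothing sensitive
      z <- rep(0, length(r))
    } else {
      rlang::abort("MAD of drug/control ratios is zero: degenerate population")
    }
  } else {
    z <- (stats::median(r) - r) / s
  }
  tibble::tibble(strain = common, ratio = r, z = z,
                 sensitive = z >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$z))
}

#' Overlap statistics between two strain sets
#'
#' Computes the Venn accounting used to compare drug-sensitivity profiles:
#' set sizes, intersection, both conditional percentages, and an exact
#' hypergeometric enrichment p-value (upper tail: probability of an
#' intersection at least this large when `set_b` is drawn at random from the
#' universe).
#'
#' @param set_a,set_b Character vectors of strain ids (deduplicated).
#' @param universe Character vector containing both sets.
#'
#' @return One-row tibble `n_a`, `n_b`, `n_intersect`, `pct_a_in_b`,
#'   `pct_b_in_a`, `p_hyper`, `universe_size`. An empty `set_a` gives
#'   `pct_a_in_b = NaN` with a warning (likewise for `set_b`).
#' @export
#'
#' @examples
#' # 85 of 156 IAA-sensitive strains are also rapamycin-sensitive (54.5%)
#' a <- paste0("s", 1:156); b <- paste0("s", c(1:85, 200:390))
#' overlap_stats(a, b, paste0("s", 1:4800))
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    rlang::abort("both sets must be subsets of the universe")
  }
  n_a <- length(set_a); n_b <- length(set_b)
  n_int <- length(intersect(set_a, set_b))
  if (n_a == 0 || n_b == 0) {
    rlang::warn("empty set: conditional percentage undefined (NaN)")
  }
  N <- length(universe)
  # exact upper-tail sum: P(X >= n_int), X ~ Hypergeometric(N, n_a, n_b)
  p <- stats::phyper(n_int - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  tibble::tibble(
    n_a = n_a, n_b = n_b, n_intersect = n_int,
    pct_a_in_b = 100 * n_int / n_a,
    pct_b_in_a = 100 * n_int / n_b,
    p_hyper = p,
    universe_size = N
  )
}

#' Venn region counts for two or more named sets
#'
#' Tabulates every membership region (e.g. `A&B&!C`) of the union of the
#' given sets. Regions partition the union, so their counts always sum to
#' the union's cardinality.
#'
#' @param sets Named list (>= 2 elements, unique names) of character
#'   vectors.
#'
#' @return Tibble `region` (e.g. `"A&!B&C"`), `count`, plus a column per set
#'   with its membership flag; attribute `union_size`.
#' @export
#'
#' @examples
#' multi_set_report(list(A = c("x", "y"), B = c("y", "z"), C = "y"))
multi_set_report <- function(sets) {
  if (length(sets) < 2) rlang::abort("need at least 2 sets")
  nms <- names(sets)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms) > 0) {
    rlang::abort("sets must have unique, non-empty names")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nms))
  sig <- apply(member, 1, function(row) {
    paste(ifelse(row, nms, paste0("!", nms)), collapse = "&")
  })
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(nms)))
  names(combos) <- nms
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  region <- apply(combos, 1, function(row) {
    paste(ifelse(row, nms, paste0("!", nms)), collapse = "&")
  })
  counts <- vapply(region, function(rg) sum(sig == rg), integer(1))
  out <- tibble::as_tibble(combos)
  out$region <- region
  out$count <- unname(counts)
  out <- dplyr::relocate(out, "region", "count")
  attr(out, "union_size") <- length(universe)
  out
}
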