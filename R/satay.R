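#' Read a transposon insertion table
#'
#' Reads a TSV with header `chrom pos strand reads` describing the distinct
#' transposon insertion sites of one library/condition, with 1-based
#' positions. Malformed rows (position < 1, negative or non-integer reads,
#' strand outside `+`, `-`, `.`) are rejected with their line numbers.
#'
#' @param path Path to the TSV.
#' @param condition_label Optional label stored as the `condition` attribute.
#'
#' @return A tibble (`chrom`, `pos`, `strand`, `reads`) with attributes
#'   `condition` and `total_reads`.
#' @export
read_insertion_table <- function(path, condition_label = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    strand = readr::col_character(),
    reads = readr::col_double()
  ))
  bad <- which(tab$pos < 1 | tab$pos != floor(tab$pos) |
                 tab$reads < 0 | tab$reads != floor(tab$reads) |
                 !tab$strand %in% c("+", "-", "."))
  if (length(bad) > 0) {
    # +1 for the header line
    rlang::abort(paste0("malformed insertion rows at line(s): ",
                        paste(bad + 1L, collapse = ", ")))
  }
  tab$pos <- as.integer(tab$pos)
  tab$reads <- as.integer(tab$reads)
  attr(tab, "condition") <- condition_label
  attr(tab, "total_reads") <- sum(tab$reads)
  tab
}

#' Write a transposon insertion table
#'
#' @param table Tibble with columns `chrom`, `pos`, `strand`, `reads`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertion_table <- function(table, path) {
  stopifnot(all(c("chrom", "pos", "strand", "reads") %in% names(table)))
  readr::write_tsv(table[, c("chrom", "pos", "strand", "reads")], path)
  invisible(path)
}

#' Assign transposon insertions to genes
#'
#' Counts, for every gene, the distinct insertion sites and summed reads
#' whose position falls within the gene's `[start, end]` interval (1-based
#' inclusive, strand-agnostic: a transposon disrupts the ORF on either
#' strand). Insertions that overlap several genes are counted for each of
#' them; insertions in no gene are tallied as intergenic.
#'
#' @param table Insertion tibble (`chrom`, `pos`, `strand`, `reads`).
#' @param genome A [genome_spec()]; every chromosome in `table` must be
#'   declared in it.
#'
#' @return A `gene_counts` tibble with one row per gene (`gene_id`,
#'   `n_sites`, `n_reads`) and attributes `library_total_reads`,
#'   `library_total_sites`, `intergenic_sites`, `intergenic_reads`.
#' @export
assign_insertions <- function(table, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  table <- tibble::as_tibble(table)
  unknown <- setdiff(unique(table$chrom), genome$chromosomes$name)
  if (length(unknown) > 0) {
    rlang::abort(paste0("insertions on chromosomes absent from the genome: ",
                        paste(unknown, collapse = ", ")))
  }
  genes <- genome$genes
  hits_list <- vector("list", length(unique(table$chrom)))
  assigned <- rep(FALSE, nrow(table))
  out <- tibble::tibble(gene_id = genes$gene_id, n_sites = 0L, n_reads = 0L)
  for (cc in unique(table$chrom)) {
    ti <- which(table$chrom == cc)
    gi <- which(genes$chrom == cc)
    if (length(gi) == 0 || length(ti) == 0) next
    q <- IRanges::IRanges(table$pos[ti], width = 1L)
    s <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    qh <- ti[S4Vectors::queryHits(ov)]
    sh <- gi[S4Vectors::subjectHits(ov)]
    assigned[qh] <- TRUE
    per_gene <- tibble::tibble(g = sh,
                               site = paste0(table$chrom[qh], ":", table$pos[qh]),
                               reads = table$reads[qh]) |>
      dplyr::group_by(.data$g) |>
      dplyr::summarise(n_sites = dplyr::n_distinct(.data$site),
                       n_reads = sum(.data$reads), .groups = "drop")
    out$n_sites[per_gene$g] <- out$n_sites[per_gene$g] + per_gene$n_sites
    out$n_reads[per_gene$g] <- out$n_reads[per_gene$g] + per_gene$n_reads
  }
  site_key <- paste0(table$chrom, ":", table$pos)
  attr(out, "library_total_reads") <- sum(table$reads)
  attr(out, "library_total_sites") <- dplyr::n_distinct(site_key)
  attr(out, "intergenic_sites") <- dplyr::n_distinct(site_key[!assigned])
  attr(out, "intergenic_reads") <- sum(table$reads[!assigned])
  class(out) <- c("gene_counts", class(out))
  out
}

#' Score genes by normalized treated/control insertion ratio
#'
#' Computes, per gene, the fitness score
#' `log2( ((t + pc)/T) / ((c + pc)/C) )` where `t`, `c` are the gene's counts
#' in the treated and control libraries, `T`, `C` the library totals, and
#' `pc` a pseudocount that bounds the score for zero-count genes. Counts are
#' either summed reads (`mode = "reads"`, the default) or distinct insertion
#' sites (`mode = "sites"`); both columns are carried in the output. Genes
#' with zero counts in both libraries score exactly 0 and are banded neutral.
#'
#' @param treated,control `gene_counts` objects from [assign_insertions()]
#'   over the same gene universe.
#' @param mode `"reads"` or `"sites"`: which counts define the primary score.
#' @param pseudocount Pseudocount added to each gene's counts (> 0).
#'
#' @return Tibble `gene_id`, `score_reads`, `score_sites`, `score` (the
#'   chosen mode) — not yet banded; see [classify_percentiles()].
#' @export
score_genes <- function(treated, control, mode = c("reads", "sites"),
                        pseudocount = 1) {
  mode <- match.arg(mode)
  if (pseudocount <= 0) rlang::abort("pseudocount must be > 0")
  if (!setequal(treated$gene_id, control$gene_id)) {
    diff <- c(setdiff(treated$gene_id, control$gene_id),
              setdiff(control$gene_id, treated$gene_id))
    rlang::abort(paste0("gene sets differ between libraries: ",
                        paste(diff, collapse = ", ")))
  }
  control <- control[match(treated$gene_id, control$gene_id), ]
  one_score <- function(t, Tt, c, Ct) {
    s <- log2(((t + pseudocount) / Tt) / ((c + pseudocount) / Ct))
    s[t == 0 & c == 0] <- 0
    s
  }
  Tr <- attr(treated, "library_total_reads")
  Cr <- attr(control, "library_total_reads")
  Ts <- attr(treated, "library_total_sites")
  Cs <- attr(control, "library_total_sites")
  if (is.null(Tr) || is.null(Cr) || is.null(Ts) || is.null(Cs)) {
    rlang::abort("inputs must be gene_counts objects with library totals")
  }
  out <- tibble::tibble(
    gene_id = treated$gene_id,
    score_reads = one_score(treated$n_reads, Tr, control$n_reads, Cr),
    score_sites = one_score(treated$n_sites, Ts, control$n_sites, Cs)
  )
  out$score <- if (mode == "reads") out$score_reads else out$score_sites
  attr(out, "mode") <- mode
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Band fitness scores by percentile
#'
#' Classifies each gene as `depleted` (score at or below the low-percentile
#' cutoff), `enriched` (at or above the high cutoff) or `neutral`. Cutoffs
#' use nearest-rank quantiles (`stats::quantile(type = 1)`); ties at a cutoff
#' fall in the extreme band. If the score distribution is degenerate (low and
#' high cutoffs coincide) every gene would land in both extreme bands, so all
#' genes are returned neutral with a warning.
#'
#' @param scores Tibble from [score_genes()] (needs columns `gene_id`,
#'   `score`).
#' @param low_pct,high_pct Percentile cutoffs, `0 <= low < high <= 100`.
#'
#' @return `scores` with a `band` factor column added; attributes
#'   `cutoff_low`, `cutoff_high`.
#' @export
classify_percentiles <- function(scores, low_pct = 10, high_pct = 90) {
  scores <- tibble::as_tibble(scores)
  stopifnot("score" %in% names(scores))
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    rlang::abort("need 0 <= low_pct < high_pct <= 100")
  }
  if (nrow(scores) < 10) {
    rlang::warn("fewer than 10 genes: percentile bands are unstable")
  }
  lo <- stats::quantile(scores$score, low_pct / 100, type = 1, names = FALSE)
  hi <- stats::quantile(scores$score, high_pct / 100, type = 1, names = FALSE)
  if (lo >= hi) {
    rlang::warn("degenerate score distribution: cutoffs coincide, all genes banded neutral")
    band <- rep("neutral", nrow(scores))
  } else {
    band <- dplyr::case_when(
      scores$score <= lo ~ "depleted",
      scores$score >= hi ~ "enriched",
      TRUE ~ "neutral"
    )
  }
  scores$band <- factor(band, levels = c("depleted", "neutral", "enriched"))
  attr(scores, "cutoff_low") <- lo
  attr(scores, "cutoff_high") <- hi
  scores
}

#' Compare fitness scores between two treatments
#'
#' Reports Pearson and Spearman correlations of the per-gene scores and the
#' set of genes classified depleted under both treatments (the joint
#' bottom-decile set when the default bands are in force).
#'
#' @param scores_a,scores_b Banded score tibbles over the same gene universe
#'   (from [classify_percentiles()]; unbanded inputs are banded with the
#'   defaults first).
#'
#' @return List with `pearson`, `spearman`, `depleted_both` (character
#'   vector of gene ids) and `n_genes`.
#' @export
compare_treatments <- function(scores_a, scores_b) {
  if (!setequal(scores_a$gene_id, scores_b$gene_id)) {
    rlang::abort("treatments cover different gene universes")
  }
  if (nrow(scores_a) < 3) {
    rlang::abort("correlation undefined with fewer than 3 genes")
  }
  if (!"band" %in% names(scores_a)) scores_a <- classify_percentiles(scores_a)
  if (!"band" %in% names(scores_b)) scores_b <- classify_percentiles(scores_b)
  scores_b <- scores_b[match(scores_a$gene_id, scores_b$gene_id), ]
  list(
    pearson = stats::cor(scores_a$score, scores_b$score, method = "pearson"),
    spearman = stats::cor(scores_a$score, scores_b$score, method = "spearman"),
    depleted_both = intersect(scores_a$gene_id[scores_a$band == "depleted"],
                              scores_b$gene_id[scores_b$band == "depleted"]),
    n_genes = nrow(scores_a)
  )
}

#' One-call SATAY scoring pipeline
#'
#' Convenience wrapper: assigns both insertion tables to genes, scores in
#' both modes and bands by percentiles.
#'
#' @param treated,control Insertion tibbles.
#' @param genome A [genome_spec()].
#' @inheritParams score_genes
#' @inheritParams classify_percentiles
#' @return Banded score tibble.
#' @export
satay_score <- function(treated, control, genome, mode = "reads",
                        pseudocount = 1, low_pct = 10, high_pct = 90) {
  gc_t <- assign_insertions(treated, genome)
  gc_c <- assign_insertions(control, genome)
  score_genes(gc_t, gc_c, mode = mode, pseudocount = pseudocount) |>
    classify_percentiles(low_pct = low_pct, high_pct = high_pct)
}
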