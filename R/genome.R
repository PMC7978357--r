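#' Construct a genome specification
#'
#' A genome specification holds chromosome lengths and gene coordinates and is
#' the annotation object against which transposon insertions are assigned to
#' coding sequences. Coordinates are 1-based inclusive on both ends, the
#' convention used by GFF3.
#'
#' @param chromosomes A data frame with columns `name` and `length` (bp).
#' @param genes A data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and `strand` (`"+"`, `"-"` or `"."`).
#'
#' @return An object of class `genome_spec`: a list with tibbles
#'   `chromosomes` and `genes`.
#' @export
#'
#' @examples
#' genome_spec(
#'   chromosomes = data.frame(name = "chrI", length = 10000),
#'   genes = data.frame(gene_id = "YAL001C", chrom = "chrI",
#'                      start = 1000, end = 2000, strand = "+")
#' )
genome_spec <- function(chromosomes, genes) {
  chromosomes <- tibble::as_tibble(chromosomes)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(chromosomes$name) > 0) {
    rlang::abort("duplicated chromosome names in genome specification")
  }
  if (anyDuplicated(genes$gene_id) > 0) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    rlang::abort(paste0("duplicated gene_ids: ", paste(dup, collapse = ", ")))
  }
  if (any(genes$start > genes$end)) {
    rlang::abort("gene start must be <= end (1-based inclusive coordinates)")
  }
  if (!all(genes$chrom %in% chromosomes$name)) {
    bad <- setdiff(unique(genes$chrom), chromosomes$name)
    rlang::abort(paste0("genes on unknown chromosomes: ", paste(bad, collapse = ", ")))
  }
  chrlen <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(genes$start < 1L) || any(genes$end > chrlen[genes$chrom])) {
    rlang::abort("gene intervals must lie within their chromosome")
  }
  structure(list(chromosomes = chromosomes, genes = genes), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

#' Simulate a compact yeast-like genome annotation
#'
#' Builds a single-chromosome genome with `n_genes` equal-length genes
#' separated by fixed intergenic gaps. Used as the annotation backbone for
#' simulated transposon libraries; it is deliberately regular so per-gene
#' expectations are easy to reason about.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp.
#' @param spacing Intergenic gap between consecutive genes in bp.
#' @param chrom_name Chromosome name.
#'
#' @return A [genome_spec()].
#' @export
simulate_genome <- function(n_genes, gene_length = 1000L, spacing = 200L,
                            chrom_name = "chrSim") {
  stopifnot(n_genes >= 1, gene_length >= 1, spacing >= 0)
  starts <- spacing + (seq_len(n_genes) - 1L) * (gene_length + spacing) + 1L
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom_name,
    start = starts,
    end = starts + gene_length - 1L,
    strand = rep(c("+", "-"), length.out = n_genes)
  )
  len <- max(genes$end) + spacing
  genome_spec(
    chromosomes = tibble::tibble(name = chrom_name, length = len),
    genes = genes
  )
}

#' Read a gene annotation into a genome specification
#'
#' Accepts either a GFF3 file (`dialect = "gff3"`, requires the rtracklayer
#' package) or a 5-column TSV with header
#' `gene_id chrom start end strand` (`dialect = "tsv"`, 1-based inclusive) or
#' the same TSV in BED-style 0-based half-open coordinates
#' (`dialect = "bed-tsv"`, converted on read).
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"tsv"`, `"bed-tsv"`, `"gff3"`.
#' @param chromosome_lengths Optional named vector of chromosome lengths; when
#'   absent, each chromosome is assumed to end at the last annotated gene.
#'
#' @return A [genome_spec()].
#' @export
read_annotation <- function(path, dialect = c("tsv", "bed-tsv", "gff3"),
                            chromosome_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      rlang::abort("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    genes <- tibble::tibble(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
    genes$strand[genes$strand == "*"] <- "."
  } else {
    genes <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      strand = readr::col_character()
    ))
    if (dialect == "bed-tsv") {
      # 0-based half-open -> 1-based inclusive
      genes$start <- genes$start + 1
    }
  }
  chroms <- unique(genes$chrom)
  if (is.null(chromosome_lengths)) {
    lens <- vapply(chroms, function(cc) max(genes$end[genes$chrom == cc]), numeric(1))
  } else {
    lens <- chromosome_lengths[chroms]
  }
  genome_spec(
    chromosomes = tibble::tibble(name = chroms, length = as.numeric(lens)),
    genes = genes
  )
}

#' Write a genome specification's genes as a 5-column annotation TSV
#'
#' @param genome A [genome_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genome, path) {
  stopifnot(inherits(genome, "genome_spec"))
  readr::write_tsv(genome$genes, path)
  invisible(path)
}
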