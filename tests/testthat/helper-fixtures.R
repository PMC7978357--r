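# Shared fixtures, built in code.

# Two-chromosome toy genome with one overlapping gene pair on chrA.
tiny_genome <- function() {
  genome_spec(
    chromosomes = data.frame(name = c("chrA", "chrB"),
                             length = c(5000, 3000)),
    genes = data.frame(
      gene_id = c("gA1", "gA2", "gA3", "gB1"),
      chrom = c("chrA", "chrA", "chrA", "chrB"),
      start = c(100, 900, 1500, 500),
      end   = c(1000, 1400, 2500, 1500),
      strand = c("+", "-", "+", "+")
    )
  )
}

# Fabricate a gene_counts object without going through assign_insertions.
make_counts <- function(gene_id, n_reads, n_sites = pmin(n_reads, 1L),
                        total_reads = sum(n_reads),
                        total_sites = sum(n_sites)) {
  out <- tibble::tibble(gene_id = gene_id,
                        n_sites = as.integer(n_sites),
                        n_reads = as.integer(n_reads))
  attr(out, "library_total_reads") <- total_reads
  attr(out, "library_total_sites") <- total_sites
  class(out) <- c("gene_counts", class(out))
  out
}

# Brute-force interval membership: reads/sites per gene by exhaustive check.
oracle_assign <- function(table, genome) {
  genes <- genome$genes
  res <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- table$chrom == genes$chrom[i] &
      table$pos >= genes$start[i] & table$pos <= genes$end[i]
    c(n_sites = length(unique(paste0(table$chrom[hit], ":", table$pos[hit]))),
      n_reads = sum(table$reads[hit]))
  })
  tibble::tibble(gene_id = genes$gene_id,
                 n_sites = vapply(res, `[[`, numeric(1), "n_sites"),
                 n_reads = vapply(res, `[[`, numeric(1), "n_reads"))
}
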