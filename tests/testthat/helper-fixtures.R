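## Tiny in-code fixtures shared across test files.

## 12-bp chromosome with a two-exon gene: CDS = ATGAAA + CCC
tiny_reference <- function() {
  Biostrings::DNAStringSet(c(chr1 = "ATGAAATTTCCC"))
}

tiny_gene_model <- function(strand = "+") {
  tibble::tibble(gene_id = "gA", transcript_id = "gA.1", chrom = "chr1",
                 strand = strand, exon_start = c(1L, 10L),
                 exon_end = c(6L, 12L))
}

## five-variety panel over two populations
tiny_panel <- function() {
  tibble::tibble(
    variety_id = paste0("v", 1:5),
    population = c("Xian", "Xian", "Xian", "Geng", "Geng"),
    subpopulation = c("XI-1A", "XI-1A", "XI-2", "GJ-tmp", "GJ-tmp"),
    improvement = c("LAN", "LAN", "MV", "LAN", "MV"))
}

## long-format variant table: one SNP at pos 4 (A>G) carried by v4, v5
tiny_variants <- function(alleles = c(0L, 0L, 0L, 1L, 1L)) {
  tibble::tibble(chrom = "chr1", pos = 4L, ref = "A", alt = "G",
                 variety_id = paste0("v", 1:5), allele = alleles)
}

## assignment table with chosen per-population haplotype counts
counts_to_assignments <- function(counts_by_pop, gene = "g1") {
  ## counts_by_pop: named list population -> named integer vector hap -> n
  rows <- list()
  i <- 0
  for (pop in names(counts_by_pop)) {
    for (hap in names(counts_by_pop[[pop]])) {
      n <- counts_by_pop[[pop]][[hap]]
      if (n == 0) next
      ids <- sprintf("%s_%05d", pop, i + seq_len(n))
      i <- i + n
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = gene, variety_id = ids, hap_id = hap, population = pop)
    }
  }
  out <- dplyr::bind_rows(rows)
  list(assignments = dplyr::select(out, "gene_id", "variety_id", "hap_id"),
       panel = tibble::tibble(variety_id = out$variety_id,
                              population = out$population,
                              subpopulation = out$population,
                              improvement = "other"))
}

## small simulated study reused by several files (cheap: 2 genes)
small_sim_study <- function(seed = 11) {
  cfg <- gchap_sim_config(
    seed = seed,
    populations = tibble::tibble(
      name = c("Xian", "Geng"), n = c(120L, 80L),
      lan_frac = c(0.5, 0.5), mv_frac = c(0.5, 0.5)),
    genes = tibble::tibble(
      gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
      strand = c("+", "-"), n_exons = c(2L, 1L),
      cds_length = c(300L, 210L), n_haplotypes = c(4L, 3L)),
    effects = tibble::tibble(gene_id = "g1", hap_id = "Hap2",
                             trait = "TGW", effect = 2))
  simulate_gchap_study(cfg)
}
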