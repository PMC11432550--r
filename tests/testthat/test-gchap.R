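test_that("CDS extraction concatenates exons and honours strand", {
  ref <- tiny_reference()
  expect_equal(build_cds_sequence(ref, tiny_gene_model("+")), "ATGAAACCC")
  ## SNP at genomic pos 4 (A>G)
  subs <- tibble::tibble(pos = 4L, ref = "A", alt = "G")
  expect_equal(build_cds_sequence(ref, tiny_gene_model("+"), subs), "ATGGAACCC")
  ## minus strand: reverse complement of the concatenation
  gm_minus <- tibble::tibble(gene_id = "gB", transcript_id = "gB.1",
                             chrom = "chr1", strand = "-",
                             exon_start = 1L, exon_end = 6L)
  expect_equal(build_cds_sequence(ref, gm_minus), "TTTCAT")
})

test_that("CDS substitution errors are specific", {
  ref <- tiny_reference()
  gm <- tiny_gene_model("+")
  expect_error(build_cds_sequence(ref, gm, tibble::tibble(
    pos = 4L, ref = "C", alt = "G")), "REF allele mismatch")
  expect_error(build_cds_sequence(ref, gm, tibble::tibble(
    pos = c(4L, 4L), ref = c("A", "A"), alt = c("G", "T"))), "overlapping")
  expect_error(build_cds_sequence(ref, gm, tibble::tibble(
    pos = 8L, ref = "T", alt = "A")), "outside CDS")
  ## deletion running over the exon edge
  expect_error(build_cds_sequence(ref, gm, tibble::tibble(
    pos = 5L, ref = "AATTT", alt = "A")), "beyond its CDS exon")
})

test_that("indels shift downstream substitution offsets", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATTTCCCGGG"))
  gm <- tibble::tibble(gene_id = "g", transcript_id = "g.1", chrom = "chr1",
                       strand = "+", exon_start = 1L, exon_end = 15L)
  ## 3-bp deletion at pos 3 (ref GAAA -> G), then SNP at pos 13 G>T
  subs <- tibble::tibble(pos = c(3L, 13L), ref = c("GAAA", "G"),
                         alt = c("G", "T"))
  expect_equal(build_cds_sequence(ref, gm, subs), "ATGTTTCCCTGG")
})

test_that("haplotype calling collapses identical sequences and ranks by count", {
  ref <- tiny_reference()
  gm <- tiny_gene_model("+")
  panel <- tiny_panel()
  gchaps <- call_gchaps(ref, gm, tiny_variants(), panel)
  expect_equal(nrow(gchaps$haplotypes), 2)
  expect_equal(gchaps$haplotypes$n_carriers, c(3L, 2L))
  expect_equal(gchaps$haplotypes$hap_seq[1], "ATGAAACCC")  # Hap1 = count 3
  expect_equal(gchaps$haplotypes$hap_seq[2], "ATGGAACCC")
  expect_equal(nrow(gchaps$excluded), 0)
  ## partition property: carriers + excluded = panel
  expect_setequal(c(gchaps$assignments$variety_id, gchaps$excluded$variety_id),
                  panel$variety_id)
})

test_that("missing genotypes exclude the variety with a reason", {
  gchaps <- call_gchaps(tiny_reference(), tiny_gene_model("+"),
                        tiny_variants(c(0L, NA, 0L, 1L, 1L)), tiny_panel())
  expect_equal(gchaps$excluded$variety_id, "v2")
  expect_equal(gchaps$excluded$reason, "missing_genotype")
  expect_equal(sum(gchaps$haplotypes$n_carriers), 4)
  ## frequencies are over non-excluded varieties
  expect_equal(gchaps$haplotypes$freq, c(0.5, 0.5))
})

test_that("calling is invariant to variety and record order, and to all-REF sites", {
  ref <- tiny_reference(); gm <- tiny_gene_model("+"); panel <- tiny_panel()
  base <- call_gchaps(ref, gm, tiny_variants(), panel)
  shuffled <- call_gchaps(ref, gm,
                          tiny_variants()[c(3, 5, 1, 4, 2), ], panel)
  expect_equal(base$assignments, shuffled$assignments)
  ## adding a site where everyone is REF changes nothing
  allref <- dplyr::bind_rows(
    tiny_variants(),
    tibble::tibble(chrom = "chr1", pos = 11L, ref = "C", alt = "T",
                   variety_id = paste0("v", 1:5), allele = 0L))
  expect_equal(call_gchaps(ref, gm, allref, panel)$assignments,
               base$assignments)
})

test_that("multiallelic sites are handled natively", {
  vars <- tibble::tibble(chrom = "chr1", pos = 4L, ref = "A", alt = "G,T",
                         variety_id = paste0("v", 1:5),
                         allele = c(0L, 0L, 1L, 2L, 2L))
  gchaps <- call_gchaps(tiny_reference(), tiny_gene_model("+"), vars,
                        tiny_panel())
  expect_equal(nrow(gchaps$haplotypes), 3)
  expect_setequal(gchaps$haplotypes$hap_seq,
                  c("ATGAAACCC", "ATGGAACCC", "ATGTAACCC"))
})

test_that("major classification applies the frequency threshold", {
  fx <- counts_to_assignments(list(Xian = c(Hap1 = 980, Hap2 = 15, Hap3 = 5)))
  majors <- major_gchaps(fx$assignments, threshold = 0.01)
  expect_setequal(majors$hap_id, c("Hap1", "Hap2"))
  ## threshold 1 keeps only a unanimous haplotype
  one <- counts_to_assignments(list(Xian = c(Hap1 = 10)))
  expect_equal(major_gchaps(one$assignments, threshold = 1)$hap_id, "Hap1")
  ## pigeonhole: the top haplotype is always major at threshold <= 1/N
  expect_gte(nrow(major_gchaps(fx$assignments, threshold = 1 / 1000)), 1)
  expect_error(major_gchaps(fx$assignments, threshold = 0), "0, 1")
})

test_that("frequency vectors sum to one and ignore input order", {
  fx <- counts_to_assignments(list(Xian = c(Hap1 = 3, Hap2 = 2)))
  fr <- hap_frequencies(fx$assignments)
  expect_equal(fr$freq, c(0.6, 0.4))
  perm <- fx$assignments[sample(nrow(fx$assignments)), ]
  expect_equal(hap_frequencies(perm), fr)
  expect_error(hap_frequencies(fx$assignments, subset = "nope"), "empty")
})

test_that("panel gcHapN dominates any subpopulation gcHapN", {
  study <- small_sim_study()
  gchaps <- call_gchaps(study$reference, study$gene_models, study$variants,
                        study$panel)
  div <- diversity_summary(gchaps$assignments, study$panel)
  for (g in unique(div$gene_id)) {
    panel_n <- div$gcHapN[div$gene_id == g & div$population == "All"]
    expect_true(all(div$gcHapN[div$gene_id == g] <= panel_n))
  }
})
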