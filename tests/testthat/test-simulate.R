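test_that("panel counts match the configuration exactly and deterministically", {
  cfg <- gchap_sim_config(seed = 1, populations = tibble::tibble(
    name = "Xian", n = 100L, lan_frac = 0.7, mv_frac = 0.3))
  panel <- simulate_panel(cfg)
  expect_equal(nrow(panel), 100)
  expect_equal(sum(panel$improvement == "LAN"), 70)
  expect_equal(sum(panel$improvement == "MV"), 30)
  expect_identical(panel, simulate_panel(cfg))
  expect_error(gchap_sim_config(populations = tibble::tibble(
    name = "Xian", n = 10L, lan_frac = 1.2, mv_frac = 0)), "\\[0, 1\\]")
})

test_that("simulated haplotypes are distinct and respect pairwise Hamming >= 1", {
  cfg <- gchap_sim_config(seed = 3, genes = tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", n_exons = 1L,
    cds_length = 300L, n_haplotypes = 4L))
  panel <- simulate_panel(cfg)
  gh <- simulate_gene_haplotypes(cfg, panel)
  seqs <- gh$truth$haplotypes$hap_seq
  expect_equal(length(seqs), 4)
  expect_equal(anyDuplicated(seqs), 0)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gte(sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]]), 1)
  }
  ## a single haplotype emits no variant records
  cfg1 <- gchap_sim_config(seed = 3, genes = tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", n_exons = 1L,
    cds_length = 300L, n_haplotypes = 1L))
  gh1 <- simulate_gene_haplotypes(cfg1, simulate_panel(cfg1))
  expect_equal(nrow(gh1$variants), 0)
})

test_that("dominant-haplotype sampling stays inside the binomial interval", {
  ## two haplotypes at 0.9/0.1, n = 2000: 99% interval for the dominant
  cfg <- gchap_sim_config(
    seed = 5,
    populations = tibble::tibble(name = "Xian", n = 2000L, lan_frac = 1,
                                 mv_frac = 0),
    genes = tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           n_exons = 1L, cds_length = 300L,
                           n_haplotypes = 2L),
    drift = c(g1 = 0), freq_concentration = 1e9)
  ## pin the frequency vector exactly
  cfg$hap_freqs$freqs <- rep(list(c(0.9, 0.1)), nrow(cfg$hap_freqs))
  panel <- simulate_panel(cfg)
  gh <- simulate_gene_haplotypes(cfg, panel)
  p_obs <- mean(gh$truth$assignments$hap_id == "Hap1")
  interval <- stats::qbinom(c(0.005, 0.995), 2000, 0.9) / 2000
  expect_gte(p_obs, interval[1])
  expect_lte(p_obs, interval[2])
})

test_that("phenotypes follow the additive model with planted effects", {
  ## zero effects, zero noise: value = mu + population offset exactly
  cfg0 <- gchap_sim_config(
    seed = 2, effects = tibble::tibble(gene_id = character(),
                                       hap_id = character(),
                                       trait = character(),
                                       effect = numeric()),
    trait_sds = stats::setNames(rep(0, 14), names(default_trait_means())))
  study0 <- simulate_gchap_study(cfg0)
  ph <- dplyr::left_join(study0$phenotypes,
                         dplyr::select(study0$panel, "variety_id", "population"),
                         by = "variety_id")
  offs <- dplyr::left_join(ph, default_pop_offsets(),
                           by = c("population", "trait"))
  expected <- default_trait_means()[offs$trait] +
    tidyr::replace_na(offs$offset, 0)
  expect_equal(ph$value, unname(expected))

  ## planted +2 g TGW on one haplotype, sd 1: group difference within 0.2
  cfg <- gchap_sim_config(
    seed = 4,
    populations = tibble::tibble(name = "Xian", n = 1000L, lan_frac = 1,
                                 mv_frac = 0),
    genes = tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           n_exons = 1L, cds_length = 300L,
                           n_haplotypes = 2L),
    drift = c(g1 = 0),
    effects = tibble::tibble(gene_id = "g1", hap_id = "Hap2", trait = "TGW",
                             effect = 2),
    trait_sds = stats::setNames(rep(1, 14), names(default_trait_means())))
  cfg$hap_freqs$freqs <- rep(list(c(0.5, 0.5)), nrow(cfg$hap_freqs))
  study <- simulate_gchap_study(cfg)
  tg <- dplyr::inner_join(
    dplyr::filter(study$phenotypes, .data$trait == "TGW"),
    study$truth$assignments, by = "variety_id")
  diff <- mean(tg$value[tg$hap_id == "Hap2"]) -
    mean(tg$value[tg$hap_id == "Hap1"])
  expect_equal(diff, 2, tolerance = 0.2 / 2)
  ## a different seed changes values but not the planted structure
  cfg_b <- cfg; cfg_b$seed <- 99L
  study_b <- simulate_gchap_study(cfg_b)
  expect_false(identical(study$phenotypes$value, study_b$phenotypes$value))
})

test_that("effects naming an unknown trait are rejected", {
  expect_error(simulate_phenotypes(
    gchap_sim_config(effects = tibble::tibble(
      gene_id = "g1", hap_id = "Hap1", trait = "YIELD", effect = 1)),
    tiny_panel(), list(assignments = tibble::tibble())), "YIELD")
})

test_that("fixture files are byte-identical across reruns and seed-sensitive", {
  study <- small_sim_study(seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixture_set(study, d1)
  m2 <- write_fixture_set(small_sim_study(seed = 17), d2)
  expect_equal(nrow(m1), 5)
  expect_equal(m1$md5, m2$md5)
  d3 <- withr::local_tempdir()
  m3 <- write_fixture_set(small_sim_study(seed = 18), d3)
  expect_false(m3$md5[m3$file == "variants.vcf"] ==
                 m1$md5[m1$file == "variants.vcf"])
})

test_that("fixtures round-trip through the standard readers to the same calls", {
  study <- small_sim_study(seed = 23)
  td <- withr::local_tempdir()
  write_fixture_set(study, td)
  ref <- read_reference(file.path(td, "reference.fa"))
  models <- read_gene_models(file.path(td, "genes.gff3"), reference = ref)
  panel <- read_variety_panel(file.path(td, "panel.tsv"))
  vars <- read_variants(file.path(td, "variants.vcf"), panel = panel)
  expect_equal(dplyr::arrange(vars, .data$chrom, .data$pos, .data$variety_id),
               dplyr::arrange(dplyr::select(study$variants, names(vars)),
                              .data$chrom, .data$pos, .data$variety_id))
  direct <- call_gchaps(study$reference, study$gene_models, study$variants,
                        study$panel)
  from_files <- call_gchaps(ref, models, vars, panel)
  expect_equal(direct$assignments, from_files$assignments)
  expect_equal(direct$haplotypes, from_files$haplotypes)
})
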