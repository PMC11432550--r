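## helper: assignments + phenotype values per haplotype group
make_assoc_data <- function(group_values, gene = "g1", trait = "TGW") {
  rows <- purrr::imap_dfr(group_values, function(v, hap) {
    tibble::tibble(hap_id = hap, value = v)
  })
  rows$variety_id <- sprintf("a%04d", seq_len(nrow(rows)))
  list(
    assignments = tibble::tibble(gene_id = gene, variety_id = rows$variety_id,
                                 hap_id = rows$hap_id),
    phenotypes = tibble::tibble(variety_id = rows$variety_id, trait = trait,
                                value = rows$value))
}

test_that("ANOVA F and p match the brute-force sums-of-squares route", {
  set.seed(21)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    sizes <- sample(12:40, k, replace = TRUE)
    dat <- make_assoc_data(stats::setNames(
      lapply(sizes, function(n) rnorm(n, mean = runif(1, 0, 2))),
      paste0("Hap", seq_len(k))))
    res <- gchap_trait_anova(dat$assignments, dat$phenotypes, "g1", "TGW",
                             min_n = 5, threshold = 0.001)
    values <- dat$phenotypes$value
    groups <- dat$assignments$hap_id[match(dat$phenotypes$variety_id,
                                           dat$assignments$variety_id)]
    expect_equal(res$f_statistic, anova_f_brute(values, groups),
                 tolerance = 1e-10)
  }
})

test_that("equal groups share a letter; a planted outlier group gets its own", {
  dat <- make_assoc_data(list(Hap1 = rep(5, 12), Hap2 = rep(5, 12)))
  res <- gchap_trait_anova(dat$assignments, dat$phenotypes, "g1", "TGW",
                           min_n = 5)
  expect_equal(res$f_statistic, 0)
  expect_equal(unname(unique(res$groups$letters)), "a")

  set.seed(77)
  dat3 <- make_assoc_data(list(Hap1 = rnorm(15, 0), Hap2 = rnorm(15, 0),
                               Hap3 = rnorm(15, 5)))
  res3 <- gchap_trait_anova(dat3$assignments, dat3$phenotypes, "g1", "TGW",
                            min_n = 5)
  l3 <- res3$groups$letters[res3$groups$hap_id == "Hap3"]
  others <- res3$groups$letters[res3$groups$hap_id != "Hap3"]
  expect_false(any(grepl(l3, others, fixed = TRUE)))
  expect_equal(res3$p_value < 1e-7, res3$very_significant)
})

test_that("letters share iff Tukey accepts, exhaustively for up to 6 groups", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    means <- runif(k, 0, 4)
    dat <- make_assoc_data(stats::setNames(
      lapply(means, function(m) rnorm(14, m)), paste0("Hap", seq_len(k))))
    res <- gchap_trait_anova(dat$assignments, dat$phenotypes, "g1", "TGW",
                             min_n = 5)
    cld <- stats::setNames(res$groups$letters, res$groups$hap_id)
    for (r in seq_len(nrow(res$tukey))) {
      a <- res$tukey$group_a[r]; b <- res$tukey$group_b[r]
      share <- any(strsplit(cld[[a]], "")[[1]] %in% strsplit(cld[[b]], "")[[1]])
      expect_equal(share, res$tukey$p_adj[r] >= res$alpha)
    }
  }
})

test_that("below-minimum groups are dropped and recorded", {
  dat <- make_assoc_data(list(Hap1 = rnorm(30), Hap2 = rnorm(30),
                              Hap3 = rnorm(4)))
  res <- gchap_trait_anova(dat$assignments, dat$phenotypes, "g1", "TGW",
                           min_n = 10, threshold = 0.001)
  expect_equal(res$dropped, "Hap3")
  expect_setequal(res$groups$hap_id, c("Hap1", "Hap2"))
  dat1 <- make_assoc_data(list(Hap1 = rnorm(30), Hap2 = rnorm(4)))
  expect_error(gchap_trait_anova(dat1$assignments, dat1$phenotypes, "g1",
                                 "TGW", min_n = 10), "fewer than 2")
})

test_that("favorable/unfavorable labelling uses frequency extremes of majors", {
  fx <- counts_to_assignments(list(Xian = c(Hap1 = 600, Hap2 = 300,
                                            Hap3 = 50, Hap4 = 5)))
  fav <- label_favorable_unfavorable(fx$assignments, threshold = 0.01)
  expect_equal(fav$favorable_hap, "Hap1")
  expect_equal(fav$unfavorable_hap, "Hap3")  # Hap4 below 1%
  expect_gte(fav$favorable_freq, fav$unfavorable_freq)
  two <- counts_to_assignments(list(Xian = c(Hap1 = 60, Hap2 = 40)))
  fav2 <- label_favorable_unfavorable(two$assignments)
  expect_equal(c(fav2$favorable_hap, fav2$unfavorable_hap), c("Hap1", "Hap2"))
  one <- counts_to_assignments(list(Xian = c(Hap1 = 99, Hap2 = 1)))
  expect_error(label_favorable_unfavorable(one$assignments, threshold = 0.05),
               "contrast undefined")
})

test_that("trait contrasts detect a planted effect and report insufficiency", {
  set.seed(13)
  dat <- make_assoc_data(list(Hap1 = rnorm(200, 27), Hap2 = rnorm(200, 25)))
  fav <- label_favorable_unfavorable(dat$assignments, threshold = 0.01)
  ct <- contrast_traits(fav, dat$assignments, dat$phenotypes, traits = "TGW")
  expect_equal(ct$status, "ok")
  expect_true(ct$significant)
  expect_equal(ct$mean_diff, 2, tolerance = 0.3)

  ## identical values: zero difference, not significant
  same <- make_assoc_data(list(Hap1 = rep(25, 20), Hap2 = rep(25, 20)))
  favs <- label_favorable_unfavorable(same$assignments, threshold = 0.01)
  cts <- contrast_traits(favs, same$assignments, same$phenotypes,
                         traits = "TGW")
  expect_equal(cts$mean_diff, 0)
  expect_false(cts$significant)

  ## one group all-missing: insufficient data, not an error
  ph <- dat$phenotypes
  ph$value[ph$variety_id %in%
             dat$assignments$variety_id[dat$assignments$hap_id == "Hap2"]] <- NA
  ct2 <- contrast_traits(fav, dat$assignments, ph, traits = "TGW")
  expect_equal(ct2$status, "insufficient data")
})

test_that("trait-favorable haplotypes follow the declared direction", {
  set.seed(19)
  dat <- make_assoc_data(list(Hap1 = rnorm(60, 22), Hap2 = rnorm(60, 25)))
  best <- favorable_hap_for_trait(dat$assignments, dat$phenotypes, "g1",
                                  "TGW")
  expect_equal(best$hap_id, "Hap2")
  low <- favorable_hap_for_trait(dat$assignments, dat$phenotypes, "g1", "TGW",
                                 direction = c(TGW = "lower"))
  expect_equal(low$hap_id, "Hap1")
  expect_error(favorable_hap_for_trait(dat$assignments, dat$phenotypes, "g1",
                                       "DTH"), "direction")
})

test_that("favorable-allele frequencies cover subpopulations with zeros", {
  fx <- counts_to_assignments(list(Xian = c(Hap1 = 90, Hap2 = 10),
                                   Geng = c(Hap1 = 50)))
  fav <- tibble::tibble(gene_id = "g1", trait = "TGW", hap_id = "Hap2")
  freq <- favorable_allele_frequencies(fx$assignments, fx$panel, fav)
  pops <- freq[freq$level == "population", ]
  expect_equal(pops$freq[pops$group == "Xian"], 0.1)
  expect_equal(pops$freq[pops$group == "Geng"], 0)
  expect_equal(pops$n_accessions[pops$group == "Geng"], 0)
})
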