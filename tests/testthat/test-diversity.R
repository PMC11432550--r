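test_that("Shannon evenness matches the normalised-entropy definition", {
  expect_equal(shannon_evenness(rep(0.25, 4)), 1)
  expect_equal(shannon_evenness(1), 0)
  ## direct evaluation: H = 0.80181, ln 3 = 1.09861
  expect_equal(shannon_evenness(c(0.7, 0.2, 0.1)), 0.72985, tolerance = 1e-5)
  ## zeros are dropped; counts equivalent to frequencies
  expect_equal(shannon_evenness(c(0.7, 0.2, 0.1, 0)),
               shannon_evenness(c(7, 2, 1)))
  expect_error(shannon_evenness(c(0.5, -0.1)), "non-negative")
})

test_that("evenness is relabeling-invariant and rises under equalising transfers", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    p <- as.numeric(rmultinom(1, 500, rep(1 / k, k))) + 1
    p <- p / sum(p)
    expect_equal(shannon_evenness(p), shannon_evenness(sample(p)))
    ## move mass from the most to the least frequent haplotype
    hi <- which.max(p); lo <- which.min(p)
    if (p[hi] - p[lo] > 0.02) {
      q <- p
      eps <- (p[hi] - p[lo]) / 4
      q[hi] <- q[hi] - eps; q[lo] <- q[lo] + eps
      expect_gt(shannon_evenness(q), shannon_evenness(p))
    }
  }
})

test_that("Nei identity handles the boundary and worked cases", {
  expect_equal(nei_identity(c(0.6, 0.4), c(0.6, 0.4)), 1)
  expect_equal(nei_identity(c(1, 0), c(0, 1)), 0)
  expect_equal(nei_identity(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 0.5,
               tolerance = 1e-12)
  expect_error(nei_identity(c(0, 0), c(1, 0)), "all zero")
  expect_error(nei_identity(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("Nei identity is symmetric and invariant to count scaling", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    x <- stats::rgamma(k, 2); y <- stats::rgamma(k, 2)
    expect_equal(nei_identity(x / sum(x), y / sum(y)),
                 nei_identity(y / sum(y), x / sum(x)))
    ## multiplying raw counts by a constant leaves I unchanged
    expect_equal(nei_identity(x, y), nei_identity(x * 13, y * 0.4))
  }
})

test_that("diversity summary reports per-population and panel records", {
  fx <- counts_to_assignments(list(
    Xian = c(Hap1 = 600, Hap2 = 400),
    Geng = c(Hap1 = 90, Hap3 = 10)))
  div <- diversity_summary(fx$assignments, fx$panel)
  expect_setequal(div$population, c("Xian", "Geng", "All"))
  xi <- div[div$population == "Xian", ]
  expect_equal(xi$gcHapN, 2)
  expect_equal(xi$E_H, -(0.6 * log(0.6) + 0.4 * log(0.4)) / log(2),
               tolerance = 1e-12)
  expect_equal(xi$dominant_hap, "Hap1")
  expect_equal(xi$F_P, 0.6)
  all_row <- div[div$population == "All", ]
  expect_equal(all_row$gcHapN, 3)
  expect_equal(all_row$n_varieties, 1100)
  ## monomorphic population: E_H 0, F_P 1
  fx1 <- counts_to_assignments(list(Xian = c(Hap1 = 50)))
  div1 <- diversity_summary(fx1$assignments, fx1$panel)
  expect_true(all(div1$E_H == 0) && all(div1$F_P == 1))
})

test_that("E_H and I_Nei match a direct recomputation from raw tables", {
  study <- small_sim_study()
  gchaps <- call_gchaps(study$reference, study$gene_models, study$variants,
                        study$panel)
  div <- diversity_summary(gchaps$assignments, study$panel)
  for (r in seq_len(nrow(div))) {
    ids <- if (div$population[r] == "All") study$panel$variety_id else
      study$panel$variety_id[study$panel$population == div$population[r]]
    haps <- gchaps$assignments$hap_id[
      gchaps$assignments$gene_id == div$gene_id[r] &
        gchaps$assignments$variety_id %in% ids]
    tab <- table(haps)
    p <- as.numeric(tab) / sum(tab)
    manual <- if (length(p) == 1) 0 else -sum(p * log(p)) / log(length(p))
    expect_equal(div$E_H[r], manual, tolerance = 1e-12)
  }
  diff <- pairwise_differentiation(gchaps$assignments, study$panel)
  for (r in seq_len(nrow(diff))) {
    one_pop_freq <- function(pop) {
      ids <- study$panel$variety_id[study$panel$population == pop]
      haps <- gchaps$assignments$hap_id[
        gchaps$assignments$gene_id == diff$gene_id[r] &
          gchaps$assignments$variety_id %in% ids]
      table(haps) / length(haps)
    }
    fa <- one_pop_freq(diff$pop_a[r]); fb <- one_pop_freq(diff$pop_b[r])
    u <- union(names(fa), names(fb))
    x <- ifelse(u %in% names(fa), as.numeric(fa[u]), 0)
    y <- ifelse(u %in% names(fb), as.numeric(fb[u]), 0)
    manual <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    expect_equal(diff$i_nei[r], manual, tolerance = 1e-12)
  }
})

test_that("differentiation flags strong divergence and respects thresholds", {
  fx <- counts_to_assignments(list(
    Xian = c(Hap1 = 95, Hap2 = 5),
    Geng = c(Hap1 = 5, Hap2 = 95)))
  diff <- pairwise_differentiation(fx$assignments, fx$panel, threshold = 0.35)
  ## (0.95*0.05*2) / (0.95^2 + 0.05^2)
  expect_equal(diff$i_nei, 0.0950 / 0.9050, tolerance = 1e-4)
  expect_true(diff$differentiated)
  diff0 <- pairwise_differentiation(fx$assignments, fx$panel, threshold = 0)
  expect_false(any(diff0$differentiated))
  same <- counts_to_assignments(list(
    Xian = c(Hap1 = 60, Hap2 = 40), Geng = c(Hap1 = 60, Hap2 = 40)))
  d2 <- pairwise_differentiation(same$assignments, same$panel)
  expect_equal(d2$i_nei, 1)
  expect_false(d2$differentiated)
  expect_error(pairwise_differentiation(fx$assignments, fx$panel,
                                        populations = c("Xian", "Bas")),
               "absent")
})
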