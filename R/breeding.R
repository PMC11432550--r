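## Landrace (LAN) vs modern variety (MV) breeding signatures per locus:
## change in Shannon evenness with a bootstrap Z test, change in gcHapN,
## new haplotypes gained, dominant-haplotype frequency drift with a
## chi-square test, and an artificial-selection label.

#' Select a panel group
#'
#' Convenience filter returning the variety ids of one breeding group,
#' e.g. `panel_group(panel, "Xian", "LAN")` for the Xian landraces.
#'
#' @param panel Variety panel tibble.
#' @param population Population label (or `NULL` for all).
#' @param improvement Improvement class `"LAN"`, `"MV"` or `"other"`
#'   (or `NULL` for all).
#' @return Character vector of variety ids.
#' @export
panel_group <- function(panel, population = NULL, improvement = NULL) {
  x <- panel
  if (!is.null(population)) x <- dplyr::filter(x, .data$population %in% !!population)
  if (!is.null(improvement)) x <- dplyr::filter(x, .data$improvement %in% !!improvement)
  x$variety_id
}

#' Bootstrap Z test for a difference in Shannon evenness
#'
#' Tests `E_H(B) - E_H(A)` between two groups of haplotype assignments.
#' The standard error of each group's evenness is estimated by a seeded
#' nonparametric bootstrap over varieties within the group (equivalently,
#' multinomial resampling of the haplotype counts), and
#' `Z = (E_H_B - E_H_A) / sqrt(SE_A^2 + SE_B^2)` is referred to the
#' standard normal (two-sided).
#'
#' @param haps_a,haps_b Character vectors: the haplotype id of each
#'   variety in group A and group B at one locus.
#' @param n_boot Number of bootstrap resamples (>= 200; default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `e_h_a`, `e_h_b`, `delta_e_h`, `se_a`, `se_b`,
#'   `z`, `p`.
#' @export
evenness_z_test <- function(haps_a, haps_b, n_boot = 1000, seed = 1) {
  if (n_boot < 200) stop_gchap("n_boot must be at least 200")
  counts_a <- table(haps_a)
  counts_b <- table(haps_b)
  e_a <- shannon_evenness(as.numeric(counts_a))
  e_b <- shannon_evenness(as.numeric(counts_b))
  boot_se <- function(counts) {
    n <- sum(counts)
    draws <- rmultinom(n_boot, n, prob = counts / n)
    stats::sd(apply(draws, 2, shannon_evenness))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  se_a <- boot_se(counts_a)
  se_b <- boot_se(counts_b)
  delta <- e_b - e_a
  denom <- sqrt(se_a^2 + se_b^2)
  z <- if (denom > 0) delta / denom else if (delta == 0) 0 else NA_real_
  p <- if (is.na(z)) NA_real_ else if (denom == 0) 1 else 2 * pnorm(-abs(z))
  tibble::tibble(e_h_a = e_a, e_h_b = e_b, delta_e_h = delta,
                 se_a = se_a, se_b = se_b, z = z, p = p)
}

## save/restore the global RNG state so seeded helpers do not disturb
## the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Chi-square test of haplotype frequency drift
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2
#' carriers/non-carriers table of one haplotype in two groups. Degenerate
#' tables (a zero margin) return `NA` with `flagged = TRUE`.
#'
#' @param carriers_a,n_a Carrier count and group size in group A.
#' @param carriers_b,n_b Carrier count and group size in group B.
#' @return One-row tibble: `chi2`, `p`, `df`, `flagged`.
#' @export
#' @examples
#' frequency_drift_test(30, 100, 60, 100)  # chi2 = 18.18, p = 2e-5
frequency_drift_test <- function(carriers_a, n_a, carriers_b, n_b) {
  stopifnot(carriers_a >= 0, carriers_b >= 0,
            carriers_a <= n_a, carriers_b <= n_b)
  tab <- matrix(c(carriers_a, n_a - carriers_a,
                  carriers_b, n_b - carriers_b), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(chi2 = NA_real_, p = NA_real_, df = 1L, flagged = TRUE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ht$statistic), p = unname(ht$p.value),
                 df = 1L, flagged = FALSE)
}

#' Artificial-selection effect label
#'
#' `"up"` for a positive change in evenness (MV minus LAN), `"down"` for a
#' negative change, `"none"` for exactly zero.
#'
#' @param delta_e_h Numeric vector of evenness differences.
#' @return Character vector of labels.
#' @export
#' @examples
#' selection_effect_label(c(0.079, -0.029, 0))
selection_effect_label <- function(delta_e_h) {
  if (any(!is.finite(delta_e_h))) stop_gchap("delta_e_h must be finite")
  dplyr::case_when(delta_e_h > 0 ~ "up",
                   delta_e_h < 0 ~ "down",
                   TRUE ~ "none")
}

## significance stars matching the comparison-table footnotes
signif_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "ns", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Compare breeding groups at each locus
#'
#' The landrace-vs-modern comparison: per gene, Shannon evenness in each
#' group with a bootstrap Z test on the difference, gcHapN in each group,
#' the number of new haplotypes (present in B, absent from A), the
#' dominant haplotype (most frequent in the two groups combined) with its
#' frequency in each group, and a chi-square test of its frequency drift.
#' The selection-effect label follows the sign of `delta_E_H`
#' (B minus A).
#'
#' @param assignments Assignment tibble (`gene_id`, `variety_id`, `hap_id`).
#' @param panel Variety panel tibble.
#' @param group_a,group_b Character vectors of variety ids (e.g. from
#'   [panel_group()]); A is conventionally the landrace group.
#' @param genes Optional subset of genes.
#' @param n_boot Bootstrap resamples for the Z test (default 1000).
#' @param seed Integer seed.
#' @param min_n Minimum group size for the Z test (default 10); smaller
#'   groups get `z = NA` with a warning.
#' @return Tibble with one row per gene: evenness, gcHapN and dominant-
#'   frequency columns for both groups, deltas, `n_new_gchaps`, `z_stat`,
#'   `z_pvalue`, `chi2_stat`, `chi2_pvalue`, `significance`
#'   (`**`/`*`/`ns`), `selection_effect`.
#' @export
compare_breeding_groups <- function(assignments, panel, group_a, group_b,
                                    genes = NULL, n_boot = 1000, seed = 1,
                                    min_n = 10) {
  genes <- genes %||% sort(unique(assignments$gene_id))
  a <- dplyr::filter(assignments, .data$variety_id %in% group_a)
  b <- dplyr::filter(assignments, .data$variety_id %in% group_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop_gchap("a breeding group is empty")
  purrr::map_dfr(seq_along(genes), function(i) {
    g <- genes[i]
    ha <- a$hap_id[a$gene_id == g]
    hb <- b$hap_id[b$gene_id == g]
    if (length(ha) == 0 || length(hb) == 0) stop_gchap(paste0("gene ", g, ": empty group"))
    small <- length(ha) < min_n || length(hb) < min_n
    if (small) {
      warn(paste0("gene ", g, ": group below ", min_n,
                  " varieties; Z reported as undefined"))
      e_a <- shannon_evenness(as.numeric(table(ha)))
      e_b <- shannon_evenness(as.numeric(table(hb)))
      zt <- tibble::tibble(e_h_a = e_a, e_h_b = e_b, delta_e_h = e_b - e_a,
                           se_a = NA_real_, se_b = NA_real_,
                           z = NA_real_, p = NA_real_)
    } else {
      ## per-gene seed offset keeps runs reproducible while decoupling genes
      zt <- evenness_z_test(ha, hb, n_boot = n_boot, seed = seed + i - 1L)
    }
    dominant <- names(sort(table(c(ha, hb)), decreasing = TRUE))[1]
    drift <- frequency_drift_test(sum(ha == dominant), length(ha),
                                  sum(hb == dominant), length(hb))
    tibble::tibble(
      gene_id = g,
      n_a = length(ha), n_b = length(hb),
      E_H_A = zt$e_h_a, E_H_B = zt$e_h_b, delta_E_H = zt$delta_e_h,
      gcHapN_A = length(unique(ha)), gcHapN_B = length(unique(hb)),
      delta_gcHapN = length(unique(hb)) - length(unique(ha)),
      n_new_gchaps = length(setdiff(unique(hb), unique(ha))),
      dominant_hap = dominant,
      F_P_A = mean(ha == dominant), F_P_B = mean(hb == dominant),
      z_stat = zt$z, z_pvalue = zt$p,
      chi2_stat = drift$chi2, chi2_pvalue = drift$p,
      significance = signif_stars(zt$p),
      selection_effect = ifelse(is.finite(zt$delta_e_h),
                                selection_effect_label(zt$delta_e_h), NA_character_)
    )
  })
}

#' Dominant-haplotype drift table and plot
#'
#' Per major haplotype, its frequency in two groups with a chi-square
#' test of the proportion difference — the numbers behind the LAN/MV
#' drift bar charts.
#'
#' @inheritParams compare_breeding_groups
#' @param threshold Major-haplotype threshold over the combined groups.
#' @return Tibble `gene_id`, `hap_id`, `freq_a`, `freq_b`, `chi2`, `p`,
#'   `stars`.
#' @export
hap_drift_table <- function(assignments, panel, group_a, group_b,
                            genes = NULL, threshold = 0.01) {
  genes <- genes %||% sort(unique(assignments$gene_id))
  both <- dplyr::filter(assignments, .data$variety_id %in% c(group_a, group_b))
  majors <- major_gchaps(both, threshold = threshold)
  purrr::map_dfr(genes, function(g) {
    haps <- majors$hap_id[majors$gene_id == g]
    ha <- assignments$hap_id[assignments$gene_id == g &
                               assignments$variety_id %in% group_a]
    hb <- assignments$hap_id[assignments$gene_id == g &
                               assignments$variety_id %in% group_b]
    purrr::map_dfr(haps, function(h) {
      dr <- frequency_drift_test(sum(ha == h), length(ha), sum(hb == h), length(hb))
      tibble::tibble(gene_id = g, hap_id = h,
                     freq_a = mean(ha == h), freq_b = mean(hb == h),
                     chi2 = dr$chi2, p = dr$p,
                     stars = four_level_stars(dr$p))
    })
  })
}

## four-level star grid used for drift and expression calls
four_level_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "ns", p < 1e-4 ~ "****", p < 1e-3 ~ "***",
                   p < 1e-2 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' @rdname hap_drift_table
#' @param drift Output of [hap_drift_table()].
#' @param labels Group labels for the legend.
#' @return `plot_hap_drift()` returns a ggplot object.
#' @export
plot_hap_drift <- function(drift, labels = c("LAN", "MV")) {
  long <- tidyr::pivot_longer(drift, c("freq_a", "freq_b"),
                              names_to = "group", values_to = "freq")
  long$group <- ifelse(long$group == "freq_a", labels[1], labels[2])
  ggplot2::ggplot(long, ggplot2::aes(.data$hap_id, .data$freq, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(data = drift,
                       ggplot2::aes(.data$hap_id, pmax(.data$freq_a, .data$freq_b),
                                    label = .data$stars),
                       inherit.aes = FALSE, vjust = -0.3, size = 3) +
    ggplot2::facet_wrap(~gene_id, scales = "free_x") +
    ggplot2::labs(x = "major gcHap", y = "frequency", fill = NULL)
}
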