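## Haplotype-trait association: one-way ANOVA across major gcHaps with a
## Tukey HSD multiple-comparison test and a compact letter display, the
## favorable/unfavorable haplotype contrast, and favorable-allele
## frequency profiles across subpopulations.

#' Compact letter display from pairwise decisions
#'
#' Insert-and-absorb letter assignment (the standard algorithm behind
#' multiple-comparison letter displays): start with all groups sharing
#' one letter; for each significantly different pair, split every letter
#' column containing both; finally absorb columns that are subsets of
#' others. Two groups share a letter if and only if they are not
#' significantly different. Letters are ordered so that `"a"` contains
#' the group with the best (highest) mean.
#'
#' @param pairs Tibble with columns `group_a`, `group_b`, `p_adj`.
#' @param means Named numeric vector of group means (all groups).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector: letters per group.
#' @export
compact_letter_display <- function(pairs, means, alpha = 0.05) {
  groups <- names(sort(means, decreasing = TRUE))
  columns <- list(groups)  # each column = set of groups sharing a letter
  sig <- pairs[!is.na(pairs$p_adj) & pairs$p_adj < alpha, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    gi <- sig$group_a[k]; gj <- sig$group_b[k]
    new_cols <- list()
    for (col in columns) {
      if (gi %in% col && gj %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, gi)), list(setdiff(col, gj)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    ## absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[i] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    columns <- unique(new_cols[keep])
  }
  ## order columns by the rank of their best group, then letter them
  best <- vapply(columns, function(col) min(match(col, groups)), numeric(1))
  columns <- columns[order(best)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(columns)) {
    for (g in columns[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA of a trait across major gcHaps
#'
#' Fits a fixed-effects one-way ANOVA of one trait across the major
#' haplotypes of one gene (frequency >= `threshold` in the analysed
#' subset), followed by Tukey's HSD on all pairs and a compact letter
#' display. Haplotype groups with fewer than `min_n` phenotyped carriers
#' are dropped from the model and recorded. No multiple-testing
#' correction is applied across genes and traits; associations with
#' `p < very_significant` are flagged.
#'
#' @param assignments Assignment tibble (`gene_id`, `variety_id`, `hap_id`).
#' @param phenotypes Long phenotype tibble (`variety_id`, `trait`, `value`).
#' @param gene Gene id.
#' @param trait Trait code.
#' @param subset Optional variety-id subset (e.g. one population).
#' @param threshold Major-haplotype frequency threshold (default 0.01).
#' @param min_n Minimum phenotyped carriers per haplotype (default 10).
#' @param alpha Level for the letter display (default 0.05).
#' @param very_significant Flag threshold (default 1e-7).
#' @return An object of class `gchap_anova` with `tidy()`, `glance()`,
#'   `autoplot()` methods; its `groups` element holds per-haplotype `n`,
#'   `mean`, `sd` and `letters`.
#' @export
gchap_trait_anova <- function(assignments, phenotypes, gene, trait,
                              subset = NULL, threshold = 0.01, min_n = 10,
                              alpha = 0.05, very_significant = 1e-7) {
  x <- dplyr::filter(assignments, .data$gene_id == !!gene)
  if (!is.null(subset)) x <- dplyr::filter(x, .data$variety_id %in% subset)
  if (nrow(x) == 0) stop_gchap(paste0("no assignments for gene ", gene))
  majors <- major_gchaps(x, threshold = threshold)
  ph <- dplyr::filter(phenotypes, .data$trait == !!trait, !is.na(.data$value))
  dat <- dplyr::inner_join(x, ph, by = "variety_id")
  dat <- dplyr::filter(dat, .data$hap_id %in% majors$hap_id)
  sizes <- dplyr::count(dat, .data$hap_id)
  dropped <- c(setdiff(majors$hap_id, sizes$hap_id),
               sizes$hap_id[sizes$n < min_n])
  dat <- dplyr::filter(dat, !.data$hap_id %in% dropped)
  eligible <- unique(dat$hap_id)
  if (length(eligible) < 2) {
    stop_gchap(paste0("gene ", gene, " x ", trait,
                      ": fewer than 2 eligible haplotype groups"))
  }
  dat$hap_id <- factor(dat$hap_id)
  fit <- aov(value ~ hap_id, data = dat)
  if (stats::var(dat$value) == 0) {
    ## degenerate: every observation identical -> no effect by convention
    fstat <- 0; pval <- 1
    prs <- utils::combn(levels(dat$hap_id), 2)
    tukey <- tibble::tibble(group_a = prs[2, ], group_b = prs[1, ],
                            diff = 0, p_adj = 1)
  } else {
    av <- summary(fit)[[1]]
    fstat <- av[["F value"]][1]
    pval <- av[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$hap_id
    pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
    tukey <- tibble::tibble(
      group_a = vapply(pair_names, `[`, character(1), 1),
      group_b = vapply(pair_names, `[`, character(1), 2),
      diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"])
    )
  }
  grp <- dplyr::summarise(dplyr::group_by(dat, .data$hap_id),
                          n = dplyr::n(), mean = mean(.data$value),
                          sd = stats::sd(.data$value))
  grp <- dplyr::ungroup(grp)
  grp$hap_id <- as.character(grp$hap_id)
  means <- stats::setNames(grp$mean, grp$hap_id)
  cld <- compact_letter_display(tukey, means, alpha = alpha)
  grp$letters <- unname(cld[grp$hap_id])
  grp <- dplyr::arrange(grp, hap_rank(.data$hap_id))
  structure(
    list(gene_id = gene, trait = trait, groups = grp,
         f_statistic = fstat, p_value = pval, tukey = tukey,
         dropped = dropped, alpha = alpha,
         very_significant = !is.na(pval) && pval < very_significant,
         data = tibble::as_tibble(dat), fit = fit),
    class = "gchap_anova"
  )
}

#' @export
print.gchap_anova <- function(x, ...) {
  cat("<gchap_anova> ", x$gene_id, " x ", x$trait,
      ": F = ", format(x$f_statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      if (x$very_significant) " (very significant)", "\n", sep = "")
  print(x$groups, ...)
  if (length(x$dropped)) cat("dropped (below min_n):",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy gchap_anova
#' @describeIn gchap_trait_anova `tidy()` returns the Tukey pairwise table.
#' @param x A `gchap_anova` object.
#' @param ... Unused.
#' @export
tidy.gchap_anova <- function(x, ...) {
  dplyr::mutate(x$tukey, gene_id = x$gene_id, trait = x$trait,
                .before = 1)
}

#' @method glance gchap_anova
#' @describeIn gchap_trait_anova `glance()` returns a one-row model summary.
#' @export
glance.gchap_anova <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, trait = x$trait,
                 n_groups = nrow(x$groups), n = sum(x$groups$n),
                 f_statistic = x$f_statistic, p_value = x$p_value,
                 very_significant = x$very_significant,
                 n_dropped = length(x$dropped))
}

#' @method autoplot gchap_anova
#' @describeIn gchap_trait_anova `autoplot()` draws the per-haplotype
#'   boxplot annotated with compact letters.
#' @param object A `gchap_anova` object.
#' @export
autoplot.gchap_anova <- function(object, ...) {
  lab <- dplyr::mutate(object$groups,
                       y = max(object$data$value) * 1.02)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$hap_id, .data$value, fill = .data$hap_id)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$hap_id, .data$y, label = .data$letters),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "major gcHap", y = object$trait,
                  title = paste0(object$gene_id, " x ", object$trait,
                                 "  (p = ", format(object$p_value, digits = 3), ")"))
}

#' Favorable and unfavorable haplotype per locus
#'
#' The *favorable* haplotype of a locus is its most frequent major
#' haplotype (the dominant one, presumed favored by selection); the
#' *unfavorable* one is the major haplotype with the lowest frequency.
#' Ties are broken by haplotype rank.
#'
#' @inheritParams major_gchaps
#' @param genes Optional subset of genes.
#' @return Tibble `gene_id`, `favorable_hap`, `favorable_freq`,
#'   `unfavorable_hap`, `unfavorable_freq`. Genes with fewer than two
#'   major haplotypes raise an error naming the gene.
#' @export
label_favorable_unfavorable <- function(assignments, subset = NULL,
                                        threshold = 0.01, genes = NULL) {
  majors <- major_gchaps(assignments, subset = subset, threshold = threshold)
  genes <- genes %||% sort(unique(assignments$gene_id))
  purrr::map_dfr(genes, function(g) {
    m <- dplyr::filter(majors, .data$gene_id == g)
    if (nrow(m) < 2) {
      stop_gchap(paste0("gene ", g,
                        ": contrast undefined (fewer than 2 major gcHaps)"))
    }
    m <- dplyr::arrange(m, -.data$freq, hap_rank(.data$hap_id))
    ## the favorable hap is excluded from the unfavorable candidates so a
    ## frequency tie can never select the same haplotype for both roles
    worst <- dplyr::arrange(m[-1, ], .data$freq, hap_rank(.data$hap_id))
    tibble::tibble(gene_id = g,
                   favorable_hap = m$hap_id[1], favorable_freq = m$freq[1],
                   unfavorable_hap = worst$hap_id[1],
                   unfavorable_freq = worst$freq[1])
  })
}

#' Favorable-vs-unfavorable trait contrasts
#'
#' For each locus and trait, compares the phenotype of carriers of the
#' favorable haplotype against carriers of the unfavorable one with a
#' Welch two-sample test. Missing trait values are dropped pairwise;
#' groups below `min_n` non-missing values yield
#' `status = "insufficient data"` rather than an error.
#'
#' @param fav_pairs Output of [label_favorable_unfavorable()].
#' @param assignments Assignment tibble.
#' @param phenotypes Long phenotype tibble.
#' @param traits Character vector of trait codes to contrast.
#' @param subset Optional variety-id subset.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum non-missing values per group (default 5).
#' @return Tibble `gene_id`, `trait`, `favorable_hap`, `unfavorable_hap`,
#'   `n_fav`, `n_unfav`, `mean_diff` (favorable minus unfavorable), `p`,
#'   `significant`, `status`.
#' @export
contrast_traits <- function(fav_pairs, assignments, phenotypes,
                            traits = names(gchap_traits()), subset = NULL,
                            alpha = 0.05, min_n = 5) {
  x <- assignments
  if (!is.null(subset)) x <- dplyr::filter(x, .data$variety_id %in% subset)
  purrr::map_dfr(seq_len(nrow(fav_pairs)), function(i) {
    g <- fav_pairs$gene_id[i]
    fav <- fav_pairs$favorable_hap[i]; unf <- fav_pairs$unfavorable_hap[i]
    fav_ids <- x$variety_id[x$gene_id == g & x$hap_id == fav]
    unf_ids <- x$variety_id[x$gene_id == g & x$hap_id == unf]
    purrr::map_dfr(traits, function(tr) {
      ph <- dplyr::filter(phenotypes, .data$trait == tr, !is.na(.data$value))
      va <- ph$value[ph$variety_id %in% fav_ids]
      vb <- ph$value[ph$variety_id %in% unf_ids]
      base <- tibble::tibble(gene_id = g, trait = tr, favorable_hap = fav,
                             unfavorable_hap = unf,
                             n_fav = length(va), n_unfav = length(vb))
      if (length(va) < min_n || length(vb) < min_n) {
        return(dplyr::mutate(base, mean_diff = NA_real_, p = NA_real_,
                             significant = NA, status = "insufficient data"))
      }
      diff <- mean(va) - mean(vb)
      p <- welch_p(va, vb)
      dplyr::mutate(base, mean_diff = diff, p = p,
                    significant = !is.na(p) && p < alpha, status = "ok")
    })
  })
}

## Welch two-sample p, robust to zero-variance groups
welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Trait-favorable haplotype of a locus
#'
#' Per trait, the major haplotype whose carriers have the best mean
#' phenotype in the stated direction (`"higher"` or `"lower"` is better).
#' The direction map is explicit configuration; the default covers the
#' yield-related traits TGW, GL, GW, PL and CN as higher-is-better.
#'
#' @inheritParams gchap_trait_anova
#' @param direction Named character vector mapping trait code to
#'   `"higher"` or `"lower"`; an error is raised for traits without a
#'   declared direction.
#' @return One-row tibble `gene_id`, `trait`, `hap_id`, `mean`.
#' @export
favorable_hap_for_trait <- function(assignments, phenotypes, gene, trait,
                                    subset = NULL, threshold = 0.01,
                                    min_n = 10,
                                    direction = default_trait_directions()) {
  if (!trait %in% names(direction)) {
    stop_gchap(paste0("no favorable direction declared for trait ", trait))
  }
  x <- dplyr::filter(assignments, .data$gene_id == !!gene)
  if (!is.null(subset)) x <- dplyr::filter(x, .data$variety_id %in% subset)
  majors <- major_gchaps(x, threshold = threshold)
  ph <- dplyr::filter(phenotypes, .data$trait == !!trait, !is.na(.data$value))
  dat <- dplyr::inner_join(x, ph, by = "variety_id")
  dat <- dplyr::filter(dat, .data$hap_id %in% majors$hap_id)
  stat <- dplyr::summarise(dplyr::group_by(dat, .data$hap_id),
                           n = dplyr::n(), mean = mean(.data$value))
  stat <- dplyr::filter(dplyr::ungroup(stat), .data$n >= min_n)
  if (nrow(stat) == 0) stop_gchap(paste0("no eligible haplotype for ", gene,
                                         " x ", trait))
  best <- if (direction[[trait]] == "higher") {
    dplyr::arrange(stat, -.data$mean, hap_rank(.data$hap_id))
  } else {
    dplyr::arrange(stat, .data$mean, hap_rank(.data$hap_id))
  }
  tibble::tibble(gene_id = gene, trait = trait,
                 hap_id = best$hap_id[1], mean = best$mean[1])
}

#' @rdname favorable_hap_for_trait
#' @export
default_trait_directions <- function() {
  c(TGW = "higher", GL = "higher", GW = "higher", PL = "higher", CN = "higher")
}

#' Favorable-allele frequencies by subpopulation
#'
#' Reports, for each (gene, trait, favorable haplotype) triple, the
#' haplotype's frequency and carrier count (`n_accessions`) in every
#' subpopulation and in every population aggregate. A subpopulation where
#' the haplotype is absent is reported with frequency 0 and count 0.
#'
#' @param assignments Assignment tibble.
#' @param panel Variety panel tibble (with `subpopulation`).
#' @param favorable Tibble `gene_id`, `trait`, `hap_id`, e.g. rows from
#'   [favorable_hap_for_trait()].
#' @return Tibble `gene_id`, `trait`, `hap_id`, `level`
#'   (`"population"`/`"subpopulation"`), `group`, `n_accessions`,
#'   `n_total`, `freq`.
#' @export
favorable_allele_frequencies <- function(assignments, panel, favorable) {
  groups <- dplyr::bind_rows(
    tibble::tibble(level = "population", group = panel$population,
                   variety_id = panel$variety_id),
    tibble::tibble(level = "subpopulation", group = panel$subpopulation,
                   variety_id = panel$variety_id)
  )
  groups <- dplyr::filter(groups, !is.na(.data$group))
  purrr::map_dfr(seq_len(nrow(favorable)), function(i) {
    g <- favorable$gene_id[i]; h <- favorable$hap_id[i]
    asg <- dplyr::filter(assignments, .data$gene_id == g)
    joined <- dplyr::inner_join(groups, asg, by = "variety_id")
    out <- dplyr::summarise(
      dplyr::group_by(joined, .data$level, .data$group),
      n_accessions = sum(.data$hap_id == h),
      n_total = dplyr::n()
    )
    out <- dplyr::ungroup(out)
    dplyr::mutate(out, gene_id = g, trait = favorable$trait[i], hap_id = h,
                  freq = .data$n_accessions / .data$n_total, .before = 1)
  })
}
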