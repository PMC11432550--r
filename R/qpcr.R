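## Livak 2^-ddCt relative expression from qPCR cycle thresholds, with
## technical-replicate averaging and Welch significance calls against the
## control timepoint.

#' Validate a qPCR Ct dataset
#'
#' @param data Tibble with columns `gene`, `condition`, `timepoint`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param reference_gene Id of the internal reference locus; every
#'   (condition, timepoint, bio_rep) sample must have reference rows.
#' @return The data, invisibly, if valid.
#' @export
validate_qpcr <- function(data, reference_gene) {
  needed <- c("gene", "condition", "timepoint", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) stop_gchap(paste0("qPCR data missing column(s): ",
                                          paste(miss, collapse = ", ")))
  if (any(!is.finite(data$ct)) || any(data$ct <= 0)) {
    stop_gchap("Ct values must be finite and positive")
  }
  if (!reference_gene %in% data$gene) {
    stop_gchap(paste0("reference gene ", reference_gene, " absent from data"))
  }
  samples <- dplyr::distinct(
    dplyr::filter(data, .data$gene != reference_gene),
    .data$condition, .data$timepoint, .data$bio_rep)
  refs <- dplyr::distinct(
    dplyr::filter(data, .data$gene == reference_gene),
    .data$condition, .data$timepoint, .data$bio_rep)
  orphan <- dplyr::anti_join(samples, refs,
                             by = c("condition", "timepoint", "bio_rep"))
  if (nrow(orphan) > 0) {
    stop_gchap(paste0("missing reference measurement for sample ",
                      orphan$condition[1], " / t=", orphan$timepoint[1],
                      " / bio_rep ", orphan$bio_rep[1]))
  }
  invisible(data)
}

## technical replicates averaged to one Ct per (gene, sample), then
## dCt = Ct_target - Ct_reference per (condition, timepoint, bio_rep)
delta_ct <- function(data, gene, reference_gene) {
  mean_ct <- dplyr::summarise(
    dplyr::group_by(data, .data$gene, .data$condition, .data$timepoint,
                    .data$bio_rep),
    ct = mean(.data$ct), .groups = "drop")
  tgt <- dplyr::filter(mean_ct, .data$gene == !!gene)
  ref <- dplyr::filter(mean_ct, .data$gene == !!reference_gene)
  joined <- dplyr::inner_join(
    dplyr::select(tgt, -"gene"),
    dplyr::select(ref, -"gene", ref_ct = "ct"),
    by = c("condition", "timepoint", "bio_rep"))
  dplyr::mutate(joined, d_ct = .data$ct - .data$ref_ct)
}

#' Livak 2^-ddCt fold change
#'
#' Technical replicates are averaged to one Ct per sample;
#' `dCt = Ct_target - Ct_reference` per biological replicate;
#' `ddCt = dCt_treated - mean(dCt_control)` where the control is the
#' `control_timepoint` (default 0 h) of the same condition; the fold
#' change is `2^-ddCt` per biological replicate.
#'
#' @param data qPCR tibble (see [validate_qpcr()]).
#' @param gene Target gene id.
#' @param condition Treatment condition.
#' @param timepoint Treated timepoint (h).
#' @param reference_gene Internal reference locus id.
#' @param control_timepoint Control timepoint (default 0).
#' @return One-row tibble: `gene`, `condition`, `timepoint`, `n_rep`,
#'   `fold_mean`, `fold_sd`, and list-column `folds` with the per-
#'   biological-replicate fold changes.
#' @export
#' @examples
#' d <- tidyr::expand_grid(gene = c("target", "ref"), condition = "salt",
#'                         timepoint = c(0, 4), bio_rep = 1:3, tech_rep = 1:2)
#' d$ct <- ifelse(d$gene == "ref", 20, ifelse(d$timepoint == 0, 25, 23))
#' ddct_fold_change(d, "target", "salt", 4, "ref")  # fold 4
ddct_fold_change <- function(data, gene, condition, timepoint,
                             reference_gene, control_timepoint = 0) {
  validate_qpcr(data, reference_gene)
  dat <- dplyr::filter(data, .data$condition == !!condition)
  dct <- delta_ct(dat, gene, reference_gene)
  ctrl <- dplyr::filter(dct, .data$timepoint == control_timepoint)
  trt <- dplyr::filter(dct, .data$timepoint == !!timepoint)
  if (nrow(ctrl) == 0) stop_gchap(paste0("no control (t=", control_timepoint,
                                         ") measurements for ", gene))
  if (nrow(trt) == 0) stop_gchap(paste0("no measurements for ", gene,
                                        " at t=", timepoint))
  dd <- trt$d_ct - mean(ctrl$d_ct)
  folds <- 2^(-dd)
  tibble::tibble(gene = gene, condition = condition, timepoint = timepoint,
                 n_rep = length(folds), fold_mean = mean(folds),
                 fold_sd = if (length(folds) > 1) stats::sd(folds) else NA_real_,
                 folds = list(folds))
}

#' Relative-expression table with significance calls
#'
#' Computes 2^-ddCt fold changes for every (gene, condition, timepoint)
#' against the control timepoint, a Welch two-sided test of treated vs
#' control dCt values per comparison, and stars on the four-level grid
#' (`****` p < 1e-4, `***` p < 1e-3, `**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise; `nd` when a group has a single replicate). A one-way ANOVA
#' of dCt across all timepoints of each (gene, condition) is also
#' reported per row (`anova_p`).
#'
#' @inheritParams ddct_fold_change
#' @param genes Target genes (default: all but the reference).
#' @return Tibble with one row per (gene, condition, treated timepoint).
#' @export
ddct_table <- function(data, reference_gene, control_timepoint = 0,
                       genes = NULL) {
  validate_qpcr(data, reference_gene)
  genes <- genes %||% setdiff(unique(data$gene), reference_gene)
  combos <- dplyr::distinct(
    dplyr::filter(data, .data$gene %in% genes),
    .data$gene, .data$condition)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]; cond <- combos$condition[i]
    dat <- dplyr::filter(data, .data$condition == cond)
    dct <- delta_ct(dat, g, reference_gene)
    ctrl <- dct$d_ct[dct$timepoint == control_timepoint]
    anova_p <- if (length(unique(dct$timepoint)) > 1) {
      av <- summary(aov(d_ct ~ factor(timepoint), data = dct))[[1]]
      av[["Pr(>F)"]][1]
    } else NA_real_
    tps <- setdiff(sort(unique(dct$timepoint)), control_timepoint)
    purrr::map_dfr(tps, function(tp) {
      fc <- ddct_fold_change(data, g, cond, tp, reference_gene,
                             control_timepoint)
      trt <- dct$d_ct[dct$timepoint == tp]
      if (length(trt) < 2 || length(ctrl) < 2) {
        p <- NA_real_; stars <- "nd"
      } else {
        p <- welch_p(trt, ctrl)
        stars <- four_level_stars(p)
      }
      dplyr::mutate(fc, p = p, stars = stars, anova_p = anova_p)
    })
  })
}
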