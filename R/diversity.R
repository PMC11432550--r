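## Per-locus, per-population diversity (Shannon evenness E_H, gcHapN,
## dominant haplotype and its frequency F_P) and pairwise population
## differentiation (Nei's genetic identity I_Nei).

#' Shannon evenness of a haplotype frequency vector
#'
#' `E_H = (-sum p_i log p_i) / log(N)` with natural logarithms, where `N`
#' is the number of haplotypes with positive frequency. By convention
#' `E_H = 0` for a monomorphic locus (`N = 1`) and `0 * log(0) = 0`.
#' `E_H` lies in `[0, 1]`; 1 means all observed haplotypes are equally
#' frequent.
#'
#' @param freqs Numeric vector of non-negative frequencies (zeros allowed;
#'   need not be normalised — it is renormalised over positive entries).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' shannon_evenness(rep(0.25, 4))   # 1
#' shannon_evenness(1)              # 0
#' shannon_evenness(c(0.7, 0.2, 0.1))
shannon_evenness <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) == 0) {
    stop_gchap("freqs must be a non-empty numeric vector")
  }
  if (any(is.na(freqs)) || any(freqs < 0)) {
    stop_gchap("frequencies must be non-negative and non-missing")
  }
  p <- freqs[freqs > 0]
  if (sum(p) == 0) stop_gchap("all frequencies are zero")
  p <- p / sum(p)
  n <- length(p)
  if (n == 1) return(0)
  h <- -sum(p * log(p))
  h / log(n)
}

#' Nei's genetic identity between two populations
#'
#' `I = sum(x_i * y_i) / sqrt(sum(x_i^2) * sum(y_i^2))` over haplotype
#' frequency vectors expressed on the union of haplotypes (absent
#' haplotype = frequency 0). `I` lies in `[0, 1]`: 1 for identical
#' compositions, 0 for disjoint ones. Values below ~0.35 are read as
#' strong differentiation in this package's reporting flag.
#'
#' @param x,y Numeric frequency vectors of equal length, aligned on the
#'   same haplotype order (use named vectors over the union of hap ids).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' nei_identity(c(0.5, 0.5, 0), c(0.5, 0, 0.5))  # 0.5
nei_identity <- function(x, y) {
  if (length(x) != length(y)) {
    stop_gchap("frequency vectors must have equal length (union of haplotypes)")
  }
  if (any(is.na(x)) || any(is.na(y)) || any(x < 0) || any(y < 0)) {
    stop_gchap("frequencies must be non-negative and non-missing")
  }
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop_gchap("a frequency vector is all zero")
  sum(x * y) / sqrt(sx * sy)
}

#' Per-locus, per-population diversity summary
#'
#' One record per (gene, population) plus a whole-panel record
#' (`population = "All"`): number of non-excluded varieties, gcHapN
#' (distinct haplotypes), major gcHapN (frequency >= `threshold`),
#' Shannon evenness `E_H`, the dominant haplotype and its frequency
#' `F_P`. Dominant-haplotype ties are broken by haplotype rank (lowest
#' Hap number). Populations empty after exclusions are skipped with a
#' warning.
#'
#' @param assignments Assignment tibble (`gene_id`, `variety_id`, `hap_id`).
#' @param panel Variety panel tibble.
#' @param populations Populations to summarise (default: those present).
#' @param threshold Major-haplotype frequency threshold (default 0.01).
#' @return Tibble with columns `gene_id`, `population`, `n_varieties`,
#'   `gcHapN`, `major_gcHapN`, `E_H`, `dominant_hap`, `F_P`.
#' @export
diversity_summary <- function(assignments, panel, populations = NULL,
                              threshold = 0.01) {
  populations <- populations %||% unique(panel$population)
  groups <- c(stats::setNames(
    lapply(populations, function(p) panel$variety_id[panel$population == p]),
    populations
  ), list(All = panel$variety_id))
  out <- list()
  for (nm in names(groups)) {
    ids <- groups[[nm]]
    x <- dplyr::filter(assignments, .data$variety_id %in% ids)
    if (nrow(x) == 0) {
      warn(paste0("population ", nm, " empty after exclusions; skipped"))
      next
    }
    freqs <- hap_frequencies(x)
    rec <- dplyr::summarise(
      dplyr::group_by(freqs, .data$gene_id),
      n_varieties = sum(.data$n),
      gcHapN = dplyr::n(),
      major_gcHapN = sum(.data$freq >= threshold),
      E_H = shannon_evenness(.data$freq),
      dominant_hap = .data$hap_id[order(-.data$freq, hap_rank(.data$hap_id))][1],
      F_P = max(.data$freq)
    )
    rec <- dplyr::ungroup(rec)
    rec$population <- nm
    out[[nm]] <- rec
  }
  res <- dplyr::bind_rows(out)
  dplyr::select(res, "gene_id", "population", "n_varieties", "gcHapN",
                "major_gcHapN", "E_H", "dominant_hap", "F_P")
}

## numeric rank of a HapN label, used for deterministic tie-breaks
hap_rank <- function(hap_id) {
  suppressWarnings(r <- as.integer(sub("^Hap", "", hap_id)))
  ifelse(is.na(r), rank(hap_id), r)
}

#' Pairwise population differentiation (Nei's identity)
#'
#' Computes `I_Nei` between every pair of the requested populations for
#' each gene, over the union of haplotypes, and flags pairs with
#' `I_Nei < threshold` as differentiated. The flag is a reporting cutoff,
#' not a hypothesis test.
#'
#' @inheritParams diversity_summary
#' @param threshold Differentiation flag cutoff (default 0.35).
#' @return Tibble `gene_id`, `pop_a`, `pop_b`, `i_nei`, `differentiated`,
#'   one row per unordered population pair per gene.
#' @export
pairwise_differentiation <- function(assignments, panel, populations = NULL,
                                     threshold = 0.35) {
  populations <- populations %||% sort(unique(panel$population))
  absent <- setdiff(populations, unique(panel$population))
  if (length(absent) > 0) {
    stop_gchap(paste0("population(s) absent from panel: ",
                      paste(absent, collapse = ", ")))
  }
  if (length(populations) < 2) stop_gchap("need at least 2 populations")
  freqs <- purrr::map(
    stats::setNames(populations, populations),
    function(p) hap_frequencies(assignments,
                                subset = panel$variety_id[panel$population == p])
  )
  genes <- sort(unique(assignments$gene_id))
  pairs <- utils::combn(populations, 2, simplify = FALSE)
  out <- purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(pairs, function(pr) {
      fa <- dplyr::filter(freqs[[pr[1]]], .data$gene_id == g)
      fb <- dplyr::filter(freqs[[pr[2]]], .data$gene_id == g)
      haps <- union(fa$hap_id, fb$hap_id)
      x <- stats::setNames(rep(0, length(haps)), haps)
      y <- x
      x[fa$hap_id] <- fa$freq
      y[fb$hap_id] <- fb$freq
      tibble::tibble(gene_id = g, pop_a = pr[1], pop_b = pr[2],
                     i_nei = nei_identity(x, y))
    })
  })
  out$differentiated <- out$i_nei < threshold
  out
}

#' Differentiation heatmap
#'
#' Plots the pairwise `I_Nei` matrix per gene as a tile heatmap, marking
#' flagged (strongly differentiated) pairs.
#'
#' @param diff Output of [pairwise_differentiation()].
#' @return A ggplot object.
#' @export
plot_differentiation <- function(diff) {
  sym <- dplyr::bind_rows(
    diff,
    dplyr::rename(diff, pop_a = "pop_b", pop_b = "pop_a")
  )
  ggplot2::ggplot(sym, ggplot2::aes(.data$pop_a, .data$pop_b, fill = .data$i_nei)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$differentiated, "*", "")),
                       colour = "white") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "I_Nei") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise Nei's identity of gcHap composition",
                  subtitle = "* = flagged as strongly differentiated")
}
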