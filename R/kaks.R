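## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, and
## synonymous/non-synonymous annotation of inter-haplotype differences.
## The estimator is isolated here so alternatives can be added.

translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa)) stop_gchap(paste0("ambiguous or invalid codon: ", codon))
  aa
}

is_stop <- function(codon) translate_codon(codon) == "*"

#' Synonymous and non-synonymous site counts of a codon
#'
#' For each codon position, the fraction of the three possible
#' single-base changes that are synonymous; changes to stop codons are
#' excluded from the denominator (standard convention). The synonymous
#' site count is the sum of these fractions over the three positions and
#' the non-synonymous count is the complement (total mutable fractions).
#'
#' @param codon A 3-base string over `A,C,G,T`; not a stop codon.
#' @return Numeric vector `c(syn, nonsyn)`; because fractions are taken
#'   over the non-stop changes of each position, `syn + nonsyn = 3`.
#' @export
#' @examples
#' ng86_site_counts("TTT")  # c(1/3, 8/3)
#' ng86_site_counts("ATG")  # c(0, 3)
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon)) {
    stop_gchap(paste0("codon must be 3 bases over ACGT, got: ", codon))
  }
  if (is_stop(codon)) stop_gchap(paste0("stop codon input: ", codon))
  aa0 <- translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  ## per position: one site split s/(s+n) over the non-stop changes
  syn_sites <- 0; nonsyn_sites <- 0
  for (pos in 1:3) {
    s <- 0; n <- 0
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (is_stop(mut)) next
      if (translate_codon(mut) == aa0) s <- s + 1 else n <- n + 1
    }
    if (s + n > 0) {
      syn_sites <- syn_sites + s / (s + n)
      nonsyn_sites <- nonsyn_sites + n / (s + n)
    }
  }
  c(syn = syn_sites, nonsyn = nonsyn_sites)
}

## split a CDS into codons, validating length and internal stops
split_codons <- function(cds, label) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    stop_gchap(paste0(label, ": CDS length not divisible by 3"))
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  ## a trailing stop codon is allowed and dropped from the comparison
  if (length(codons) > 1 && is_stop(codons[length(codons)])) {
    codons <- codons[-length(codons)]
  }
  if (any(vapply(codons, is_stop, logical(1)))) {
    stop_gchap(paste0(label, ": internal stop codon"))
  }
  codons
}

## average synonymous/non-synonymous differences between two codons over
## all minimal substitution pathways (orders of the differing positions);
## pathways passing through a stop codon are excluded unless all are
sd_nd_codon_pair <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  ndiff <- length(pos)
  if (ndiff == 0) return(c(sd = 0, nd = 0))
  perms <- all_permutations(pos)
  path_counts <- list()
  for (ord in perms) {
    cur <- ca
    sdv <- 0; ndv <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (is_stop(nxt)) { blocked <- TRUE; break }
      if (translate_codon(cur) == translate_codon(nxt)) sdv <- sdv + 1
      else ndv <- ndv + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1]] <-
      c(sd = sdv, nd = ndv, blocked = as.numeric(blocked))
  }
  m <- do.call(rbind, path_counts)
  ok <- m[, "blocked"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori (1986) Ka/Ks between two coding sequences
#'
#' Counts synonymous (S) and non-synonymous (N) sites per sequence
#' (averaged between the two), resolves per-codon differences by
#' averaging over all minimal substitution pathways, and applies the
#' Jukes-Cantor correction `K = -3/4 log(1 - 4p/3)` to the proportions
#' `pS = Sd/S`, `pN = Nd/N`. A ratio below 1 is annotated as purifying
#' selection, 1 as neutral, above 1 as positive selection; the ratio is
#' undefined when `Ks = 0`.
#'
#' @param cds_a,cds_b Codon-aligned coding sequences of equal length,
#'   divisible by 3, without internal stop codons.
#' @param id_a,id_b Optional sequence labels.
#' @return One-row tibble: `seq_a`, `seq_b`, `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka`, `ka_ks`, `selection`. `Ks`/`Ka` are `NA` with
#'   `selection = "undefined"` beyond the correction singularity
#'   (`p >= 3/4`).
#' @export
#' @examples
#' a <- strrep("GGG", 5)
#' b <- paste0(strrep("GGG", 4), "GGA")
#' kaks_ng86(a, b)  # Sd = 1, pS = 0.2, Ks = 0.2326, Ka = 0
kaks_ng86 <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b") {
  if (nchar(cds_a) != nchar(cds_b)) {
    stop_gchap("sequences must be equal length (codon-aligned)")
  }
  ca <- split_codons(cds_a, id_a)
  cb <- split_codons(cds_b, id_b)
  sites_a <- rowSums(vapply(ca, ng86_site_counts, numeric(2)))
  sites_b <- rowSums(vapply(cb, ng86_site_counts, numeric(2)))
  S <- unname(sites_a["syn"] + sites_b["syn"]) / 2
  N <- unname(sites_a["nonsyn"] + sites_b["nonsyn"]) / 2
  dif <- mapply(sd_nd_codon_pair, ca, cb)
  Sd <- sum(dif["sd", ])
  Nd <- sum(dif["nd", ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  selection <- if (is.na(ratio)) "undefined"
  else if (ratio < 1) "purifying" else if (ratio > 1) "positive" else "neutral"
  tibble::tibble(seq_a = id_a, seq_b = id_b,
                 S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka,
                 ka_ks = ratio, selection = selection)
}

#' Annotate codon changes between two haplotype sequences
#'
#' Codon-aware diff of two aligned coding sequences: each differing codon
#' is reported with both amino acids and labelled synonymous or
#' non-synonymous (amino-acid changing).
#'
#' @inheritParams kaks_ng86
#' @return Tibble `codon_index`, `codon_a`, `codon_b`, `aa_a`, `aa_b`,
#'   `n_substitutions`, `type` (`"synonymous"`/`"non-synonymous"`).
#' @export
classify_codon_changes <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    stop_gchap("sequences must be equal length (codon-aligned)")
  }
  ca <- split_codons(cds_a, "seq_a")
  cb <- split_codons(cds_b, "seq_b")
  idx <- which(ca != cb)
  purrr::map_dfr(idx, function(i) {
    aa_a <- translate_codon(ca[i]); aa_b <- translate_codon(cb[i])
    tibble::tibble(
      codon_index = i, codon_a = ca[i], codon_b = cb[i],
      aa_a = aa_a, aa_b = aa_b,
      n_substitutions = sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]]),
      type = if (aa_a == aa_b) "synonymous" else "non-synonymous")
  })
}
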