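## Gene-CDS-haplotype (gcHap) calling: build each variety's CDS sequence
## from reference + gene model + its variant alleles, collapse identical
## sequences into haplotypes, rank them by frequency.

#' Build the CDS sequence of one variety for one gene
#'
#' Extracts the CDS exons in genomic order from the reference,
#' concatenates them, applies the variety's substitutions at the correct
#' transcript offsets (in ascending genomic position, with offsets tracked
#' across indels), and reverse-complements the result for minus-strand
#' genes so the returned sequence is in transcript orientation.
#'
#' @param reference Named [Biostrings::DNAStringSet] (see [read_reference()]).
#' @param gene_model Gene-model tibble rows for a single gene
#'   (see [read_gene_models()]).
#' @param substitutions Tibble with columns `pos`, `ref`, `alt` (plus-strand
#'   genomic alleles, 1-based positions); may be empty. Each substitution
#'   must lie fully inside one CDS exon.
#' @return A single character string: the CDS nucleotide sequence.
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATTTCCC"))
#' gm <- tibble::tibble(gene_id = "g", transcript_id = "g.1", chrom = "chr1",
#'                      strand = "+", exon_start = c(1L, 10L), exon_end = c(6L, 12L))
#' build_cds_sequence(ref, gm)  # "ATGAAACCC"
build_cds_sequence <- function(reference, gene_model,
                               substitutions = NULL) {
  gene_model <- dplyr::arrange(gene_model, .data$exon_start)
  chrom <- gene_model$chrom[1]
  strand <- gene_model$strand[1]
  if (!chrom %in% names(reference)) {
    stop_gchap(paste0("chromosome ", chrom, " absent from reference"))
  }
  chrseq <- reference[[chrom]]
  exons <- Map(function(s, e) as.character(Biostrings::subseq(chrseq, s, e)),
               gene_model$exon_start, gene_model$exon_end)
  cds <- paste0(unlist(exons), collapse = "")

  if (!is.null(substitutions) && nrow(substitutions) > 0) {
    substitutions <- dplyr::arrange(substitutions, .data$pos)
    ## genomic position -> 0-based offset in the (plus-orientation) CDS
    starts <- gene_model$exon_start
    ends <- gene_model$exon_end
    cum <- c(0, cumsum(ends - starts + 1))
    prev_end <- -Inf
    shift <- 0L  # cumulative length change from applied indels
    for (k in seq_len(nrow(substitutions))) {
      pos <- substitutions$pos[k]
      refa <- substitutions$ref[k]
      alta <- substitutions$alt[k]
      if (pos <= prev_end) {
        stop_gchap(paste0("overlapping variants at position ", pos))
      }
      i <- which(pos >= starts & pos <= ends)
      if (length(i) != 1) {
        stop_gchap(paste0("variant position ", pos, " outside CDS exons"))
      }
      if (pos + nchar(refa) - 1 > ends[i]) {
        stop_gchap(paste0("variant at position ", pos,
                          " extends beyond its CDS exon"))
      }
      off <- cum[i] + (pos - starts[i]) + shift
      have <- substr(cds, off + 1, off + nchar(refa))
      if (!identical(have, refa)) {
        stop_gchap(paste0("REF allele mismatch at position ", pos,
                          ": expected ", refa, ", reference has ", have))
      }
      cds <- paste0(substr(cds, 1, off), alta,
                    substr(cds, off + nchar(refa) + 1, nchar(cds)))
      shift <- shift + nchar(alta) - nchar(refa)
      prev_end <- pos + nchar(refa) - 1
    }
  }
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

#' Call gene-CDS-haplotypes for a variety panel
#'
#' For every gene, builds each variety's CDS sequence and collapses
#' identical sequences into haplotypes. Varieties with any missing
#' genotype at a CDS site of the gene (including heterozygotes mapped to
#' missing by the input policy) are excluded with reason
#' `"missing_genotype"`. Haplotypes are numbered `Hap1, Hap2, ...` by
#' descending panel-wide carrier count, ties broken by the panel order of
#' the first carrier.
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param gene_models Gene-model tibble (any number of genes).
#' @param variants Long variant table from [read_variants()] (or the
#'   simulator); may be empty.
#' @param panel Variety panel tibble.
#' @param genes Optional subset of gene ids to call.
#' @return An object of class `gchap_set`: a list with tibbles
#'   `assignments` (`gene_id`, `variety_id`, `hap_id`), `haplotypes`
#'   (`gene_id`, `hap_id`, `hap_seq`, `n_carriers`, `freq`) and `excluded`
#'   (`gene_id`, `variety_id`, `reason`).
#' @export
call_gchaps <- function(reference, gene_models, variants, panel, genes = NULL) {
  validate_gene_models(gene_models)
  genes <- genes %||% unique(gene_models$gene_id)
  varieties <- panel$variety_id

  assignments <- list(); haplotypes <- list(); excluded <- list()
  for (g in genes) {
    gm <- dplyr::filter(gene_models, .data$gene_id == g)
    if (nrow(gm) == 0) stop_gchap(paste0("gene ", g, " absent from gene models"))
    ## variants falling in this gene's CDS footprint
    in_cds <- rep(FALSE, nrow(variants))
    if (nrow(variants) > 0) {
      for (i in seq_len(nrow(gm))) {
        in_cds <- in_cds | (variants$chrom == gm$chrom[i] &
                              variants$pos >= gm$exon_start[i] &
                              variants$pos <= gm$exon_end[i])
      }
    }
    vg <- variants[in_cds, , drop = FALSE]
    sites <- dplyr::distinct(vg, .data$chrom, .data$pos, .data$ref, .data$alt)
    sites <- dplyr::arrange(sites, .data$pos)
    if (any(duplicated(sites$pos))) {
      stop_gchap(paste0("gene ", g, ": multiple variant records at one position"))
    }

    if (nrow(sites) == 0) {
      seqs <- rep(build_cds_sequence(reference, gm), length(varieties))
      signature <- rep("", length(varieties))
      miss <- rep(FALSE, length(varieties))
    } else {
      amat <- matrix(NA_integer_, nrow = length(varieties), ncol = nrow(sites),
                     dimnames = list(varieties, NULL))
      idx <- cbind(match(vg$variety_id, varieties), match(vg$pos, sites$pos))
      known <- !is.na(idx[, 1])
      amat[idx[known, , drop = FALSE]] <- vg$allele[known]
      miss <- apply(amat, 1, function(a) any(is.na(a)))
      signature <- apply(amat, 1, paste, collapse = ",")
      ## one sequence per distinct allele signature among complete varieties
      sig_levels <- unique(signature[!miss])
      seq_by_sig <- vapply(sig_levels, function(sg) {
        alle <- as.integer(strsplit(sg, ",")[[1]])
        carried <- which(alle > 0)
        subs <- tibble::tibble(
          pos = sites$pos[carried],
          ref = sites$ref[carried],
          alt = vapply(carried, function(i) {
            alts <- strsplit(sites$alt[i], ",")[[1]]
            j <- alle[i]
            if (j > length(alts)) {
              stop_gchap(paste0("allele index ", j, " out of range at ",
                                sites$chrom[i], ":", sites$pos[i]))
            }
            alts[j]
          }, character(1))
        )
        build_cds_sequence(reference, gm, subs)
      }, character(1))
      seqs <- rep(NA_character_, length(varieties))
      seqs[!miss] <- seq_by_sig[match(signature[!miss], sig_levels)]
    }

    if (all(miss)) stop_gchap(paste0("gene ", g, ": no varieties with complete genotypes"))
    kept <- varieties[!miss]
    kseq <- seqs[!miss]
    ## frequency-ranked haplotype ids; ties by first-occurrence variety order
    first_seen <- match(unique(kseq), kseq)
    uniq <- unique(kseq)
    counts <- as.integer(table(factor(kseq, levels = uniq)))
    rank_order <- order(-counts, first_seen)
    hap_levels <- uniq[rank_order]
    hap_id <- paste0("Hap", match(kseq, hap_levels))

    assignments[[g]] <- tibble::tibble(gene_id = g, variety_id = kept, hap_id = hap_id)
    haplotypes[[g]] <- tibble::tibble(
      gene_id = g,
      hap_id = paste0("Hap", seq_along(hap_levels)),
      hap_seq = hap_levels,
      n_carriers = counts[rank_order],
      freq = counts[rank_order] / length(kept)
    )
    if (any(miss)) {
      excluded[[g]] <- tibble::tibble(gene_id = g, variety_id = varieties[miss],
                                      reason = "missing_genotype")
    }
  }
  structure(
    list(
      assignments = dplyr::bind_rows(assignments),
      haplotypes = dplyr::bind_rows(haplotypes),
      excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
        tibble::tibble(gene_id = character(), variety_id = character(),
                       reason = character())
    ),
    class = "gchap_set"
  )
}

#' @export
print.gchap_set <- function(x, ...) {
  n_genes <- length(unique(x$haplotypes$gene_id))
  cat("<gchap_set> ", n_genes, " gene(s), ",
      length(unique(x$assignments$variety_id)), " varieties assigned, ",
      nrow(x$excluded), " exclusions\n", sep = "")
  summ <- dplyr::summarise(dplyr::group_by(x$haplotypes, .data$gene_id),
                           gcHapN = dplyr::n(),
                           dominant_freq = max(.data$freq))
  print(summ, ...)
  invisible(x)
}

#' @method tidy gchap_set
#' @describeIn call_gchaps `tidy()` returns the per-variety assignment table.
#' @param x A `gchap_set`.
#' @param ... Unused.
#' @export
tidy.gchap_set <- function(x, ...) x$assignments

#' @method glance gchap_set
#' @describeIn call_gchaps `glance()` returns one row per gene with gcHapN,
#'   dominant haplotype frequency and exclusion count.
#' @export
glance.gchap_set <- function(x, ...) {
  excl <- dplyr::count(x$excluded, .data$gene_id, name = "n_excluded")
  out <- dplyr::summarise(dplyr::group_by(x$haplotypes, .data$gene_id),
                          gcHapN = dplyr::n(),
                          n_assigned = sum(.data$n_carriers),
                          dominant_hap = .data$hap_id[which.max(.data$freq)],
                          dominant_freq = max(.data$freq))
  out <- dplyr::left_join(dplyr::ungroup(out), excl, by = "gene_id")
  out$n_excluded[is.na(out$n_excluded)] <- 0L
  out
}

#' Haplotype frequency vectors
#'
#' Computes per-haplotype frequencies over the non-excluded varieties of a
#' subset, optionally grouped (e.g. by population after joining the panel).
#'
#' @param assignments Assignment tibble (`gene_id`, `variety_id`, `hap_id`),
#'   e.g. `tidy(gchap_set)` or [read_hap_assignments()].
#' @param subset Optional character vector of variety ids to restrict to.
#' @return Tibble `gene_id`, `hap_id`, `n`, `freq`; frequencies sum to 1
#'   within each gene.
#' @export
hap_frequencies <- function(assignments, subset = NULL) {
  x <- assignments
  if (!is.null(subset)) x <- dplyr::filter(x, .data$variety_id %in% subset)
  if (nrow(x) == 0) stop_gchap("empty variety subset after exclusions")
  out <- dplyr::count(x, .data$gene_id, .data$hap_id, name = "n")
  out <- dplyr::mutate(dplyr::group_by(out, .data$gene_id), freq = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  dplyr::arrange(out, .data$gene_id, -.data$n, .data$hap_id)
}

#' Major gcHaps of a variety subset
#'
#' A haplotype is *major* when its frequency among the non-excluded
#' varieties of the subset is at least `threshold` (default 1%).
#'
#' @inheritParams hap_frequencies
#' @param threshold Frequency threshold in (0, 1]; default 0.01.
#' @return Tibble `gene_id`, `hap_id`, `n`, `freq` restricted to major
#'   haplotypes.
#' @export
major_gchaps <- function(assignments, subset = NULL, threshold = 0.01) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    stop_gchap("threshold must be a number in (0, 1]")
  }
  freqs <- hap_frequencies(assignments, subset)
  dplyr::filter(freqs, .data$freq >= threshold)
}
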