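## Input/output layer: FASTA, GFF3, VCF and the TSV tables.
## Coordinates are 1-based inclusive everywhere in the data model; any
## half-open indexing is confined to this file and to sequence extraction.

#' Read a reference genome from FASTA
#'
#' @param fasta_path Path to a (possibly multi-record) FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace so they match GFF3/VCF chromosome identifiers.
#' @export
read_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop_gchap(paste0("FASTA not found: ", fasta_path))
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Read gene models (CDS exons) from a GFF3 file
#'
#' Extracts CDS features grouped per transcript via their `Parent`
#' attribute. The GFF3 phase column is ignored: the coding sequence is
#' defined purely by exon coordinates.
#'
#' @param gff3_path Path to a GFF3 annotation file containing CDS features.
#' @param genes Optional character vector of gene identifiers that must be
#'   present; an error names any gene with no CDS feature.
#' @param reference Optional reference from [read_reference()]; when given,
#'   chromosomes named in the GFF3 but absent from the FASTA raise an error
#'   and exon coordinates are checked against sequence lengths.
#' @return A tibble with one row per CDS exon: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `exon_start`, `exon_end` (1-based inclusive),
#'   sorted by gene then ascending start.
#' @export
read_gene_models <- function(gff3_path, genes = NULL, reference = NULL) {
  if (!file.exists(gff3_path)) stop_gchap(paste0("GFF3 not found: ", gff3_path))
  gff <- rtracklayer::readGFF(gff3_path)
  gff <- as.data.frame(gff)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0 && !is.null(genes)) {
    stop_gchap(paste0("no CDS features found for gene(s): ",
                      paste(genes, collapse = ", ")))
  }
  parent <- cds$Parent
  if (is.list(parent)) parent <- vapply(parent, function(p) p[1] %||% NA_character_, character(1))
  transcript_id <- as.character(parent)
  ## gene id: prefer an explicit gene_id attribute, else strip a trailing
  ## ".<n>" transcript suffix from the Parent id
  gene_id <- if ("gene_id" %in% names(cds) && !all(is.na(cds$gene_id))) {
    as.character(cds$gene_id)
  } else {
    sub("\\.[0-9]+$", "", transcript_id)
  }
  models <- tibble::tibble(
    gene_id = gene_id,
    transcript_id = transcript_id,
    chrom = as.character(cds$seqid),
    strand = as.character(cds$strand),
    exon_start = as.integer(cds$start),
    exon_end = as.integer(cds$end)
  )
  models <- dplyr::arrange(models, .data$gene_id, .data$exon_start)
  if (!is.null(genes)) {
    missing <- setdiff(genes, unique(models$gene_id))
    if (length(missing) > 0) {
      stop_gchap(paste0("no CDS features found for gene(s): ",
                        paste(missing, collapse = ", ")))
    }
    models <- dplyr::filter(models, .data$gene_id %in% genes)
  }
  if (!is.null(reference)) {
    bad <- setdiff(unique(models$chrom), names(reference))
    if (length(bad) > 0) {
      stop_gchap(paste0("chromosome(s) in GFF3 absent from FASTA: ",
                        paste(bad, collapse = ", ")))
    }
    too_far <- dplyr::filter(
      models,
      .data$exon_end > Biostrings::width(reference)[match(.data$chrom, names(reference))]
    )
    if (nrow(too_far) > 0) {
      stop_gchap(paste0("CDS exon beyond reference length for gene ",
                        too_far$gene_id[1]))
    }
  }
  validate_gene_models(models)
  models
}

#' Validate a gene-model table
#'
#' Checks the invariants of the CDS exon table: per transcript, exons are
#' non-overlapping, sorted ascending, on a single chromosome and strand,
#' with total CDS length > 0.
#'
#' @param models A gene-model tibble as returned by [read_gene_models()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_gene_models <- function(models) {
  needed <- c("gene_id", "transcript_id", "chrom", "strand", "exon_start", "exon_end")
  miss <- setdiff(needed, names(models))
  if (length(miss) > 0) stop_gchap(paste0("gene models missing column(s): ",
                                          paste(miss, collapse = ", ")))
  if (!all(models$strand %in% c("+", "-"))) {
    stop_gchap("gene model strand must be '+' or '-'")
  }
  by_tx <- split(models, models$transcript_id)
  for (tx in by_tx) {
    if (length(unique(tx$chrom)) != 1 || length(unique(tx$strand)) != 1) {
      stop_gchap(paste0("transcript ", tx$transcript_id[1],
                        " spans multiple chromosomes or strands"))
    }
    o <- order(tx$exon_start)
    s <- tx$exon_start[o]; e <- tx$exon_end[o]
    if (any(e < s)) stop_gchap(paste0("exon with end < start in ", tx$transcript_id[1]))
    if (length(s) > 1 && any(s[-1] <= e[-length(e)])) {
      stop_gchap(paste0("overlapping CDS exons in ", tx$transcript_id[1]))
    }
    if (sum(e - s + 1) <= 0) stop_gchap(paste0("empty CDS for ", tx$transcript_id[1]))
  }
  invisible(models)
}

#' Read variants with genotypes from a VCF file
#'
#' Returns a long (tidy) table: one row per variant site per variety, with
#' the variety's allele index (0 = REF, 1.. = ALT, `NA` = missing).
#' Genotypes are treated as those of inbred lines: a heterozygous GT is by
#' default mapped to missing (`het_policy = "missing"`); alternatively the
#' first allele of the GT can be used (`het_policy = "first"`).
#' Multiallelic records are preserved, not split.
#'
#' @param vcf_path Path to a VCF v4.x file with GT fields.
#' @param region Optional `c(chrom, start, end)` (1-based inclusive) to
#'   restrict sites. A chromosome absent from the VCF yields an empty
#'   result with a warning.
#' @param panel Optional variety panel; the VCF sample set must then equal
#'   the panel's variety ids (error lists the symmetric difference).
#' @param het_policy `"missing"` (default) or `"first"`.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated ALT alleles), `variety_id`, `allele`.
#' @export
read_variants <- function(vcf_path, region = NULL, panel = NULL,
                          het_policy = c("missing", "first")) {
  het_policy <- match.arg(het_policy)
  if (!file.exists(vcf_path)) stop_gchap(paste0("VCF not found: ", vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          variety_id = character(), allele = integer()))
  }
  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  if (!is.null(panel)) {
    extra <- setdiff(samples, panel$variety_id)
    missing <- setdiff(panel$variety_id, samples)
    if (length(extra) > 0 || length(missing) > 0) {
      stop_gchap(paste0(
        "VCF sample set does not match panel; only in VCF: {",
        paste(extra, collapse = ", "), "}; only in panel: {",
        paste(missing, collapse = ", "), "}"))
    }
  }
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(region)) {
    chrom <- as.character(region[[1]])
    start <- as.integer(region[[2]]); end <- as.integer(region[[3]])
    if (!chrom %in% sites$chrom) {
      warn(paste0("region chromosome ", chrom, " not present in VCF; empty result"))
    }
    keep <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
  }
  sites <- sites[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (nrow(sites) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          variety_id = character(), allele = integer()))
  }
  allele_mat <- gt_to_allele(gt, het_policy, sites)
  long <- tibble::as_tibble(expand.grid(
    site = seq_len(nrow(sites)), variety_id = samples,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  out <- dplyr::bind_cols(sites[long$site, ],
                          tibble::tibble(variety_id = long$variety_id,
                                         allele = as.vector(allele_mat)))
  dplyr::arrange(out, .data$chrom, .data$pos, .data$variety_id)
}

## GT string matrix -> integer allele matrix applying the inbred-line policy
gt_to_allele <- function(gt, het_policy, sites) {
  parse_one <- function(g, site_idx) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == ".")) return(NA_integer_)
    idx <- suppressWarnings(as.integer(parts))
    if (any(is.na(idx))) {
      stop_gchap(paste0("malformed GT '", g, "' at ", sites$chrom[site_idx],
                        ":", sites$pos[site_idx]))
    }
    n_alt <- length(strsplit(sites$alt[site_idx], ",")[[1]])
    if (any(idx > n_alt)) {
      stop_gchap(paste0("allele index out of range in GT '", g, "' at ",
                        sites$chrom[site_idx], ":", sites$pos[site_idx]))
    }
    if (length(unique(idx)) > 1) {
      if (het_policy == "missing") return(NA_integer_) else return(idx[1])
    }
    idx[1]
  }
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  for (i in seq_len(nrow(gt))) {
    out[i, ] <- vapply(gt[i, ], parse_one, integer(1), site_idx = i)
  }
  out
}

#' Read the variety metadata table
#'
#' @param metadata_path TSV with header and columns `variety_id`,
#'   `population`, `subpopulation`, `improvement` (LAN / MV / other).
#' @param populations Closed set of admissible population labels.
#' @return Tibble (the variety panel). Errors on duplicate `variety_id`
#'   or an unknown population label.
#' @export
read_variety_panel <- function(metadata_path, populations = gchap_populations()) {
  panel <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  needed <- c("variety_id", "population", "improvement")
  miss <- setdiff(needed, names(panel))
  if (length(miss) > 0) stop_gchap(paste0("panel missing column(s): ",
                                          paste(miss, collapse = ", ")))
  if (!"subpopulation" %in% names(panel)) panel$subpopulation <- NA_character_
  dup <- panel$variety_id[duplicated(panel$variety_id)]
  if (length(dup) > 0) stop_gchap(paste0("duplicate variety_id: ",
                                         paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(panel$population), populations)
  if (length(bad) > 0) stop_gchap(paste0("unknown population label(s): ",
                                         paste(bad, collapse = ", ")))
  bad_imp <- setdiff(unique(panel$improvement), c("LAN", "MV", "other"))
  if (length(bad_imp) > 0) stop_gchap(paste0("unknown improvement label(s): ",
                                             paste(bad_imp, collapse = ", ")))
  dplyr::select(panel, "variety_id", "population", "subpopulation", "improvement")
}

#' Read the phenotype table
#'
#' Reads a wide TSV (`variety_id` plus one column per trait code) and
#' returns a long tidy table. "NA" and empty cells become missing values.
#'
#' @param phenotype_path TSV path.
#' @param traits Admissible trait codes (defaults to [gchap_traits()]).
#' @return Tibble with columns `variety_id`, `trait`, `value`.
#' @export
read_phenotypes <- function(phenotype_path, traits = names(gchap_traits())) {
  wide <- readr::read_tsv(phenotype_path, show_col_types = FALSE, na = c("", "NA"))
  if (!"variety_id" %in% names(wide)) stop_gchap("phenotypes must have a variety_id column")
  trait_cols <- setdiff(names(wide), "variety_id")
  unknown <- setdiff(trait_cols, traits)
  if (length(unknown) > 0) {
    stop_gchap(paste0("unknown trait code(s) in phenotype table: ",
                      paste(unknown, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(wide, -"variety_id", names_to = "trait",
                              values_to = "value")
  long$value <- as.numeric(long$value)
  long$variety_id <- as.character(long$variety_id)
  long
}

#' Load and join the variety metadata and phenotype tables
#'
#' Varieties present in the phenotype table but not in the metadata are
#' rejected (dropped with a report); metadata varieties without phenotypes
#' are kept with missing values implied.
#'
#' @param metadata_path,phenotype_path TSV paths.
#' @inheritParams read_variety_panel
#' @return A list with `panel`, `phenotypes` (restricted to panel
#'   varieties) and `rejected` (character vector of dropped variety ids).
#' @export
load_panel_tables <- function(metadata_path, phenotype_path,
                              populations = gchap_populations()) {
  panel <- read_variety_panel(metadata_path, populations)
  pheno <- read_phenotypes(phenotype_path)
  rejected <- setdiff(unique(pheno$variety_id), panel$variety_id)
  if (length(rejected) > 0) {
    warn(paste0(length(rejected),
                " phenotyped varieties absent from metadata were rejected"))
    pheno <- dplyr::filter(pheno, .data$variety_id %in% panel$variety_id)
  }
  list(panel = panel, phenotypes = pheno, rejected = rejected)
}

#' Read a pre-computed haplotype assignment table
#'
#' Alternative entry point bypassing haplotype calling: a TSV with columns
#' `variety_id`, `gene_id`, `hap_id` (the layout of repository-style gcHap
#' downloads).
#'
#' @param path TSV path.
#' @return Tibble with columns `gene_id`, `variety_id`, `hap_id`.
#' @export
read_hap_assignments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  needed <- c("variety_id", "gene_id", "hap_id")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0) stop_gchap(paste0("assignment table missing column(s): ",
                                          paste(miss, collapse = ", ")))
  dplyr::select(x, "gene_id", "variety_id", "hap_id")
}

#' Write an output table as TSV
#'
#' All tabular outputs go through this writer: fixed column order as given,
#' floats printed with 6 significant digits, so that writing and re-reading
#' is stable.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gchap_tsv <- function(x, path) {
  y <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.double),
    function(v) {
      ifelse(is.na(v), NA_character_,
             formatC(signif(v, 6), format = "g", digits = 6))
    }
  ))
  readr::write_tsv(y, path, na = "NA")
  invisible(path)
}
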