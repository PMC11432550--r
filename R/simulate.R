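## Synthetic panel simulator with known ground truth, emulating the
## structure of a large rice diversity panel: ~5 populations with
## landrace/modern substructure, per-locus haplotype frequency spectra
## with one dominant haplotype, frequency drift between LAN and MV
## groups, and additive haplotype effects on traits with Gaussian noise.
## One pseudo-random stream per run, consumed in documented order
## (panel -> haplotypes -> phenotypes) via fixed seed offsets.

#' Simulation configuration
#'
#' Builds the full configuration of a synthetic gcHap study, including
#' explicit per-population, per-class haplotype frequency vectors drawn
#' once from the configuration seed. The defaults mirror a large rice
#' panel qualitatively at desk scale: 5 populations totalling 600
#' varieties with LAN/MV substructure, 6 genes with 3-10 haplotypes each,
#' a dominant haplotype per locus, a mild evenness-raising LAN-to-MV
#' frequency drift, and additive haplotype effects on yield-related
#' traits.
#'
#' @param seed Integer seed; drives every random stage.
#' @param populations Tibble `name`, `n`, `lan_frac`, `mv_frac` (fractions
#'   in `[0, 1]`, summing to at most 1 per population; the remainder is
#'   class `"other"`).
#' @param genes Tibble `gene_id`, `chrom`, `strand`, `n_exons`,
#'   `cds_length` (divisible by 3), `n_haplotypes` (>= 1).
#' @param drift Named numeric vector per gene in `[0, 1)`: the exponent
#'   tilt applied to MV frequency vectors (`q_i` proportional to
#'   `p_i^(1 - drift)`); 0 means no drift.
#' @param effects Tibble `gene_id`, `hap_id`, `trait`, `effect` of planted
#'   additive haplotype effects (`hap_id` in ground-truth labels, `Hap1`
#'   being the founder). An empty tibble gives a null study.
#' @param trait_means,trait_sds Named numeric vectors over the trait
#'   panel: baseline mean and residual (Gaussian) standard deviation per
#'   trait, in trait units.
#' @param pop_offsets Tibble `population`, `trait`, `offset` of additive
#'   population-level trait offsets.
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param pheno_missing_rate Per-phenotype missing probability (default 0).
#' @param indel_haplotype If `TRUE`, the last haplotype of the first
#'   (plus-strand) gene is a 3-bp in-frame deletion haplotype instead of
#'   a SNP haplotype.
#' @param freq_concentration Dirichlet concentration controlling how much
#'   per-population frequency vectors vary around the gene's base
#'   spectrum (larger = less variation).
#' @return An object of class `gchap_sim_config`.
#' @export
gchap_sim_config <- function(seed = 1,
                             populations = default_sim_populations(),
                             genes = default_sim_genes(),
                             drift = NULL,
                             effects = default_sim_effects(),
                             trait_means = default_trait_means(),
                             trait_sds = default_trait_sds(),
                             pop_offsets = default_pop_offsets(),
                             missing_rate = 0,
                             pheno_missing_rate = 0,
                             indel_haplotype = FALSE,
                             freq_concentration = 80) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (any(populations$lan_frac < 0 | populations$lan_frac > 1 |
            populations$mv_frac < 0 | populations$mv_frac > 1)) {
    stop_gchap("lan_frac and mv_frac must lie in [0, 1]")
  }
  if (any(populations$lan_frac + populations$mv_frac > 1 + 1e-9)) {
    stop_gchap("lan_frac + mv_frac must not exceed 1")
  }
  if (any(populations$n < 1) || any(genes$n_haplotypes < 1)) {
    stop_gchap("all population sizes and haplotype counts must be >= 1")
  }
  if (any(genes$cds_length %% 3 != 0)) {
    stop_gchap("cds_length must be divisible by 3")
  }
  drift <- drift %||% stats::setNames(
    rep_len(c(0.45, 0.1, 0.35, 0.4, 0.45, 0.15), nrow(genes)), genes$gene_id)
  if (any(drift < 0 | drift >= 1)) stop_gchap("drift must lie in [0, 1)")

  ## explicit frequency vectors, drawn once from the config seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hap_freqs <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    k <- genes$n_haplotypes[gi]
    base <- 0.8 * 0.45^(0:(k - 1)) / sum(0.45^(0:(k - 1))) + 0.2 / k
    purrr::map_dfr(populations$name, function(pop) {
      p <- if (k == 1) 1 else {
        draw <- stats::rgamma(k, shape = base * freq_concentration)
        draw / sum(draw)
      }
      d <- drift[[genes$gene_id[gi]]]
      q <- p^(1 - d) / sum(p^(1 - d))
      tibble::tibble(
        gene_id = genes$gene_id[gi],
        population = pop,
        class = c("LAN", "MV", "other"),
        freqs = list(p, q, p)
      )
    })
  })
  bad <- vapply(hap_freqs$freqs, function(p) abs(sum(p) - 1) > 1e-9, logical(1))
  if (any(bad)) stop_gchap("internal: frequency vector does not sum to 1")

  structure(
    list(seed = as.integer(seed), populations = populations, genes = genes,
         drift = drift, hap_freqs = hap_freqs, effects = effects,
         trait_means = trait_means, trait_sds = trait_sds,
         pop_offsets = pop_offsets, missing_rate = missing_rate,
         pheno_missing_rate = pheno_missing_rate,
         indel_haplotype = indel_haplotype),
    class = "gchap_sim_config"
  )
}

#' @rdname gchap_sim_config
#' @export
default_sim_populations <- function() {
  tibble::tibble(
    name = c("Xian", "Geng", "Aus", "Bas", "admix"),
    n = c(200L, 150L, 100L, 75L, 75L),
    lan_frac = c(0.6, 0.6, 0.8, 0.8, 0),
    mv_frac = c(0.3, 0.3, 0.1, 0.1, 0)
  )
}

#' @rdname gchap_sim_config
#' @export
default_sim_genes <- function() {
  tibble::tibble(
    gene_id = paste0("gene", 1:6),
    chrom = paste0("chr", 1:6),
    strand = c("+", "-", "+", "-", "+", "+"),
    n_exons = c(2L, 1L, 3L, 2L, 1L, 2L),
    cds_length = c(600L, 300L, 900L, 762L, 450L, 336L),
    n_haplotypes = c(4L, 3L, 6L, 8L, 10L, 5L)
  )
}

#' @rdname gchap_sim_config
#' @export
default_sim_effects <- function() {
  tibble::tibble(
    gene_id = c("gene1", "gene1", "gene3", "gene4", "gene5", "gene6"),
    hap_id = c("Hap2", "Hap2", "Hap2", "Hap3", "Hap2", "Hap2"),
    trait = c("TGW", "GL", "PL", "PN", "GW", "CN"),
    effect = c(2.0, 0.5, 1.5, 2.0, 0.15, 2.0)
  )
}

#' @rdname gchap_sim_config
#' @export
default_trait_means <- function() {
  c(DTH = 100, PH = 110, FLL = 30, FLW = 1.5, PN = 12, PL = 23, CN = 10,
    GL = 8.5, GW = 2.5, GLWR = 3.4, TGW = 25, LRI = 20, SH = 25, LL = 15)
}

#' @rdname gchap_sim_config
#' @export
default_trait_sds <- function() {
  c(DTH = 8, PH = 10, FLL = 4, FLW = 0.2, PN = 3, PL = 2, CN = 3,
    GL = 0.4, GW = 0.2, GLWR = 0.3, TGW = 2.5, LRI = 8, SH = 4, LL = 3)
}

#' @rdname gchap_sim_config
#' @export
default_pop_offsets <- function() {
  tibble::tibble(
    population = c("Geng", "Geng", "Aus", "Bas"),
    trait = c("PH", "DTH", "DTH", "GL"),
    offset = c(5, 6, -4, 0.3)
  )
}

#' Simulate the variety panel
#'
#' Deterministic given the configuration seed. Variety counts per
#' population and improvement class match the configuration exactly
#' (`round(n * fraction)` landraces, then modern varieties, remainder
#' `"other"`); subpopulation labels are drawn within population.
#'
#' @param config A [gchap_sim_config()].
#' @return A variety panel tibble (`variety_id`, `population`,
#'   `subpopulation`, `improvement`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "gchap_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  subpops <- list(
    Xian = c("XI-1A", "XI-1B", "XI-2", "XI-3", "XI-adm"),
    Geng = c("GJ-tmp", "GJ-sbtrp", "GJ-trp", "GJ-adm")
  )
  rows <- purrr::map_dfr(seq_len(nrow(config$populations)), function(i) {
    p <- config$populations[i, ]
    n_lan <- round(p$n * p$lan_frac)
    n_mv <- round(p$n * p$mv_frac)
    improvement <- c(rep("LAN", n_lan), rep("MV", n_mv),
                     rep("other", p$n - n_lan - n_mv))
    sp <- subpops[[p$name]] %||% p$name
    tibble::tibble(population = p$name,
                   subpopulation = sample(sp, p$n, replace = TRUE),
                   improvement = improvement)
  })
  rows$variety_id <- sprintf("V%04d", seq_len(nrow(rows)))
  dplyr::select(rows, "variety_id", "population", "subpopulation", "improvement")
}

#' Simulate gene haplotypes, reference and variants
#'
#' Generates, per gene: a random reference sequence with the CDS embedded
#' in exons, a random mutation tree of haplotypes (each haplotype adds
#' 1-2 private SNPs to its parent, so distinct haplotypes differ at >= 1
#' CDS site), per-variety haplotype draws following the configured
#' per-population/per-class frequency vectors, and the corresponding
#' homozygous variant genotypes. Deterministic given the seed.
#'
#' @param config A [gchap_sim_config()].
#' @param panel Panel from [simulate_panel()].
#' @return List: `reference` ([Biostrings::DNAStringSet]), `gene_models`
#'   tibble, `variants` long tibble (as [read_variants()] emits) and
#'   `truth` (ground truth: `assignments`, `haplotypes` with transcript-
#'   orientation sequences, `expected` per-population expected evenness
#'   and dominant haplotype, `effects`).
#' @export
simulate_gene_haplotypes <- function(config, panel) {
  stopifnot(inherits(config, "gchap_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE), stops)

  refs <- list(); models <- list(); var_rows <- list()
  truth_asg <- list(); truth_hap <- list()
  for (gi in seq_len(nrow(config$genes))) {
    gene <- config$genes[gi, ]
    L <- gene$cds_length
    K <- gene$n_haplotypes

    ## exon layout: near-equal split, 120 bp introns, 500 bp pads
    base_len <- L %/% gene$n_exons
    ex_len <- rep(base_len, gene$n_exons)
    ex_len[gene$n_exons] <- ex_len[gene$n_exons] + L - sum(ex_len)
    starts <- integer(gene$n_exons); ends <- integer(gene$n_exons)
    pos <- 501L
    for (e in seq_len(gene$n_exons)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + 121L
    }
    chrom_len <- ends[gene$n_exons] + 500L

    ## reference CDS: ATG then random sense codons (transcript orientation)
    cds_tx <- paste0("ATG", paste0(sample(sense_codons, L / 3 - 1, replace = TRUE),
                                   collapse = ""))
    cds_plus <- if (gene$strand == "-") revcomp(cds_tx) else cds_tx
    chrom_seq <- paste0(sample(bases, chrom_len, replace = TRUE), collapse = "")
    for (e in seq_len(gene$n_exons)) {
      off <- sum(ex_len[seq_len(e - 1)])
      substr(chrom_seq, starts[e], ends[e]) <-
        substr(cds_plus, off + 1, off + ex_len[e])
    }
    refs[[gene$chrom]] <- chrom_seq
    models[[gene$gene_id]] <- tibble::tibble(
      gene_id = gene$gene_id, transcript_id = paste0(gene$gene_id, ".1"),
      chrom = gene$chrom, strand = gene$strand,
      exon_start = starts, exon_end = ends)

    ## mutation tree over plus-orientation CDS offsets; each haplotype
    ## inherits its parent's substitutions and adds private ones
    cds_plus_ref <- paste0(vapply(seq_len(gene$n_exons), function(e) {
      substr(chrom_seq, starts[e], ends[e])
    }, character(1)), collapse = "")
    used <- integer(0)
    hap_subs <- vector("list", K)  # each: named chr vector offset -> alt plus-base
    hap_subs[[1]] <- stats::setNames(character(0), character(0))
    make_indel <- config$indel_haplotype && gi == 1 && gene$strand == "+" && K >= 2
    hap_indel <- rep(FALSE, K)
    for (k in seq_len(K)[-1]) {
      if (make_indel && k == K) { hap_indel[k] <- TRUE; hap_subs[[k]] <- hap_subs[[1]]; next }
      parent <- if (k == 2) 1L else sample(seq_len(k - 1L), 1)
      while (hap_indel[parent]) parent <- sample(seq_len(k - 1L), 1)
      n_new <- 1L + stats::rbinom(1, 1, 0.3)
      subs <- hap_subs[[parent]]
      for (m in seq_len(n_new)) {
        avail <- setdiff(seq_len(L), used)
        if (length(avail) == 0) {
          stop_gchap(paste0(gene$gene_id,
                            ": more haplotypes requested than distinguishable sites available"))
        }
        o <- if (length(avail) == 1) avail else sample(avail, 1)
        used <- c(used, o)
        cur_base <- substr(cds_plus_ref, o, o)
        alts <- sample(setdiff(bases, cur_base))
        chosen <- NA_character_
        for (a in alts) {  # avoid creating a premature stop in any frame user
          cand <- subs
          cand[as.character(o)] <- a
          seq_try <- apply_plus_subs(cds_plus_ref, cand)
          tx <- if (gene$strand == "-") revcomp(seq_try) else seq_try
          if (!has_internal_stop(tx)) { chosen <- a; break }
        }
        if (is.na(chosen)) chosen <- alts[1]
        subs[as.character(o)] <- chosen
      }
      hap_subs[[k]] <- subs
    }

    ## haplotype transcript sequences (ground truth)
    hap_tx <- vapply(seq_len(K), function(k) {
      if (hap_indel[k]) {
        ## 3-bp in-frame deletion in the middle of exon 1 (plus strand)
        s <- apply_plus_subs(cds_plus_ref, hap_subs[[k]])
        del_at <- (ex_len[1] %/% 2) - ((ex_len[1] %/% 2) %% 3) + 4L
        paste0(substr(s, 1, del_at - 1), substr(s, del_at + 3, nchar(s)))
      } else {
        s <- apply_plus_subs(cds_plus_ref, hap_subs[[k]])
        if (gene$strand == "-") revcomp(s) else s
      }
    }, character(1))
    if (anyDuplicated(hap_tx)) {
      stop_gchap(paste0(gene$gene_id, ": internal: duplicate haplotype sequences"))
    }

    ## per-variety haplotype draws following configured frequencies
    cls <- ifelse(panel$improvement %in% c("LAN", "MV"), panel$improvement, "other")
    hap_of <- integer(nrow(panel))
    for (i in seq_len(nrow(panel))) {
      fv <- config$hap_freqs$freqs[[which(
        config$hap_freqs$gene_id == gene$gene_id &
          config$hap_freqs$population == panel$population[i] &
          config$hap_freqs$class == cls[i])]]
      hap_of[i] <- sample.int(K, 1, prob = fv)
    }

    ## variant sites (SNPs of the mutation tree + the indel, if any)
    cum <- c(0, cumsum(ex_len))
    plus_off_to_pos <- function(o) {
      e <- findInterval(o - 1, cum)  # exon index containing offset o
      starts[e] + (o - cum[e] - 1L)
    }
    snp_offsets <- sort(used)
    site_rows <- purrr::map_dfr(snp_offsets, function(o) {
      carriers <- vapply(seq_len(K), function(k)
        as.character(o) %in% names(hap_subs[[k]]) && !hap_indel[k], logical(1))
      tibble::tibble(chrom = gene$chrom, pos = plus_off_to_pos(o),
                     ref = substr(cds_plus_ref, o, o),
                     alt = hap_subs[[which(carriers)[1]]][[as.character(o)]],
                     hap_has = list(carriers))
    })
    if (any(hap_indel)) {
      del_at <- (ex_len[1] %/% 2) - ((ex_len[1] %/% 2) %% 3) + 4L
      anchor <- del_at - 1L
      site_rows <- dplyr::bind_rows(site_rows, tibble::tibble(
        chrom = gene$chrom, pos = plus_off_to_pos(anchor),
        ref = substr(cds_plus_ref, anchor, anchor + 3),
        alt = substr(cds_plus_ref, anchor, anchor),
        hap_has = list(hap_indel)))
      site_rows <- dplyr::arrange(site_rows, .data$pos)
    }
    if (nrow(site_rows) > 0) {
      carrier_mat <- do.call(rbind, site_rows$hap_has)  # sites x haplotypes
      gvar <- tidyr::expand_grid(site = seq_len(nrow(site_rows)),
                                 vi = seq_len(nrow(panel)))
      gvar <- dplyr::mutate(
        gvar,
        chrom = site_rows$chrom[.data$site],
        pos = site_rows$pos[.data$site],
        ref = site_rows$ref[.data$site],
        alt = site_rows$alt[.data$site],
        variety_id = panel$variety_id[.data$vi],
        allele = as.integer(carrier_mat[cbind(.data$site, hap_of[.data$vi])]))
      if (config$missing_rate > 0) {
        miss <- stats::runif(nrow(gvar)) < config$missing_rate
        gvar$allele[miss] <- NA_integer_
      }
      var_rows[[gene$gene_id]] <- dplyr::select(
        gvar, "chrom", "pos", "ref", "alt", "variety_id", "allele")
    }

    truth_asg[[gene$gene_id]] <- tibble::tibble(
      gene_id = gene$gene_id, variety_id = panel$variety_id,
      hap_id = paste0("Hap", hap_of))
    truth_hap[[gene$gene_id]] <- tibble::tibble(
      gene_id = gene$gene_id, hap_id = paste0("Hap", seq_len(K)),
      hap_seq = hap_tx)
  }

  ## expected per-population diversity from the configured mixtures
  expected <- purrr::map_dfr(seq_len(nrow(config$genes)), function(gi) {
    g <- config$genes$gene_id[gi]
    purrr::map_dfr(seq_len(nrow(config$populations)), function(pi) {
      p <- config$populations[pi, ]
      n_lan <- round(p$n * p$lan_frac); n_mv <- round(p$n * p$mv_frac)
      w <- c(LAN = n_lan, MV = n_mv, other = p$n - n_lan - n_mv) / p$n
      fv <- purrr::map(c("LAN", "MV", "other"), function(cl) {
        config$hap_freqs$freqs[[which(config$hap_freqs$gene_id == g &
                                        config$hap_freqs$population == p$name &
                                        config$hap_freqs$class == cl)]]
      })
      mix <- w[["LAN"]] * fv[[1]] + w[["MV"]] * fv[[2]] + w[["other"]] * fv[[3]]
      tibble::tibble(gene_id = g, population = p$name,
                     expected_freqs = list(mix),
                     expected_E_H = shannon_evenness(mix),
                     expected_dominant = paste0("Hap", which.max(mix)))
    })
  })

  list(
    reference = Biostrings::DNAStringSet(unlist(refs)),
    gene_models = dplyr::bind_rows(models),
    variants = dplyr::bind_rows(var_rows),
    truth = list(assignments = dplyr::bind_rows(truth_asg),
                 haplotypes = dplyr::bind_rows(truth_hap),
                 expected = expected,
                 effects = config$effects)
  )
}

## apply plus-orientation single-base substitutions (offset -> base)
apply_plus_subs <- function(s, subs) {
  if (length(subs) == 0) return(s)
  for (o in as.integer(names(subs))) {
    substr(s, o, o) <- subs[[as.character(o)]]
  }
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

has_internal_stop <- function(tx) {
  codons <- substring(tx, seq(1, nchar(tx) - 3, 3), seq(3, nchar(tx) - 3 + 2, 3))
  any(codons %in% c("TAA", "TAG", "TGA"))
}

#' Simulate phenotypes with planted haplotype effects
#'
#' `y = mu_trait + population offset + sum of haplotype effects +
#' Normal(0, sd_trait)`, deterministic given the seed.
#'
#' @param config A [gchap_sim_config()].
#' @param panel Panel from [simulate_panel()].
#' @param truth Ground truth from [simulate_gene_haplotypes()].
#' @return Long phenotype tibble (`variety_id`, `trait`, `value`).
#' @export
simulate_phenotypes <- function(config, panel, truth) {
  stopifnot(inherits(config, "gchap_sim_config"))
  unknown <- setdiff(unique(config$effects$trait), names(config$trait_means))
  if (length(unknown) > 0) {
    stop_gchap(paste0("unknown trait code(s) in effects: ",
                      paste(unknown, collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  traits <- names(config$trait_means)
  grid <- tidyr::expand_grid(variety_id = panel$variety_id, trait = traits)
  grid <- dplyr::left_join(grid,
                           dplyr::select(panel, "variety_id", "population"),
                           by = "variety_id")
  grid$value <- config$trait_means[grid$trait]
  grid <- dplyr::left_join(grid, config$pop_offsets,
                           by = c("population", "trait"))
  grid$value <- grid$value + tidyr::replace_na(grid$offset, 0)
  if (nrow(config$effects) > 0) {
    eff <- dplyr::inner_join(truth$assignments, config$effects,
                             by = c("gene_id", "hap_id"),
                             relationship = "many-to-many")
    eff <- dplyr::summarise(dplyr::group_by(eff, .data$variety_id, .data$trait),
                            effect = sum(.data$effect), .groups = "drop")
    grid <- dplyr::left_join(grid, eff, by = c("variety_id", "trait"))
    grid$value <- grid$value + tidyr::replace_na(grid$effect, 0)
  }
  ## noise in a fixed order (variety x trait grid order)
  grid$value <- unname(grid$value) +
    rnorm(nrow(grid), 0, config$trait_sds[grid$trait])
  if (config$pheno_missing_rate > 0) {
    miss <- stats::runif(nrow(grid)) < config$pheno_missing_rate
    grid$value[miss] <- NA_real_
  }
  dplyr::select(grid, "variety_id", "trait", "value")
}

#' Simulate a complete gcHap study
#'
#' Runs the three simulation stages in their documented order
#' (panel, haplotypes, phenotypes) and returns everything downstream
#' stages need.
#'
#' @param config A [gchap_sim_config()].
#' @return List: `config`, `panel`, `reference`, `gene_models`,
#'   `variants`, `phenotypes`, `truth`.
#' @export
simulate_gchap_study <- function(config = gchap_sim_config()) {
  panel <- simulate_panel(config)
  gh <- simulate_gene_haplotypes(config, panel)
  phenotypes <- simulate_phenotypes(config, panel, gh$truth)
  list(config = config, panel = panel, reference = gh$reference,
       gene_models = gh$gene_models, variants = gh$variants,
       phenotypes = phenotypes, truth = gh$truth)
}

#' Write a simulated study as a fixture file set
#'
#' Writes FASTA, GFF3, VCF and the two TSV tables in the exact formats
#' the readers accept, plus a manifest with checksums. Re-running with
#' the same seed gives byte-identical files.
#'
#' @param study Output of [simulate_gchap_study()].
#' @param outdir Output directory (created if needed).
#' @return Manifest tibble (`file`, `bytes`, `md5`), invisibly written as
#'   `manifest.tsv` alongside the fixtures.
#' @export
write_fixture_set <- function(study, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0) {
    stop_gchap(paste0("output directory not writable: ", outdir))
  }
  paths <- file.path(outdir, c("reference.fa", "genes.gff3", "variants.vcf",
                               "panel.tsv", "phenotypes.tsv"))
  names(paths) <- c("fasta", "gff3", "vcf", "metadata", "phenotypes")
  Biostrings::writeXStringSet(study$reference, paths[["fasta"]])
  write_sim_gff3(study$gene_models, paths[["gff3"]])
  write_sim_vcf(study$variants, study$panel, study$reference, paths[["vcf"]])
  readr::write_tsv(study$panel, paths[["metadata"]])
  wide <- tidyr::pivot_wider(study$phenotypes, names_from = "trait",
                             values_from = "value")
  wide <- dplyr::mutate(wide, dplyr::across(
    dplyr::where(is.numeric),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.4f", v))))
  readr::write_tsv(wide, paths[["phenotypes"]], na = "NA")
  manifest <- tibble::tibble(
    file = basename(paths),
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths)))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}

## minimal, byte-stable GFF3 emitter for the simulated gene models
write_sim_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in unique(models$gene_id)) {
    m <- models[models$gene_id == g, ]
    tx <- m$transcript_id[1]
    lines <- c(lines,
      paste(m$chrom[1], "gchapdiv_sim", "gene", min(m$exon_start),
            max(m$exon_end), ".", m$strand[1], ".",
            paste0("ID=", g), sep = "\t"),
      paste(m$chrom[1], "gchapdiv_sim", "mRNA", min(m$exon_start),
            max(m$exon_end), ".", m$strand[1], ".",
            paste0("ID=", tx, ";Parent=", g), sep = "\t"))
    for (i in seq_len(nrow(m))) {
      lines <- c(lines,
        paste(m$chrom[i], "gchapdiv_sim", "CDS", m$exon_start[i],
              m$exon_end[i], ".", m$strand[i], "0",
              paste0("ID=cds_", tx, ";Parent=", tx, ";gene_id=", g), sep = "\t"))
    }
  }
  writeLines(lines, path)
}

## minimal, byte-stable VCF v4.2 emitter (homozygous GTs, '.' = missing)
write_sim_vcf <- function(variants, panel, reference, path) {
  samples <- panel$variety_id
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(reference), ",length=",
           Biostrings::width(reference), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (nrow(variants) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  sites <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  gt <- matrix("0/0", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(NULL, samples))
  key <- paste(variants$chrom, variants$pos)
  skey <- paste(sites$chrom, sites$pos)
  ridx <- match(key, skey)
  cidx <- match(variants$variety_id, samples)
  gtv <- ifelse(is.na(variants$allele), "./.",
                paste0(variants$allele, "/", variants$allele))
  gt[cbind(ridx, cidx)] <- gtv
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
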