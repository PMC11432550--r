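## Pipeline orchestration: a single configuration (programmatic list or
## YAML file) drives all stages — call -> diversity -> differentiation ->
## breeding -> association -> network — writing documented TSVs, a
## structured log and a checksum manifest so that identical config + seed
## gives byte-identical output.

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_gchap_pipeline()].
#' Either `inputs` (paths to FASTA/GFF3/VCF/metadata/phenotype files) or
#' `simulate = TRUE` (synthetic study from [gchap_sim_config()]) must be
#' given.
#'
#' @param inputs Named list of paths: `fasta`, `gff3`, `vcf`, `metadata`,
#'   `phenotypes` (phenotypes optional; the association stage is skipped
#'   without them). `NULL` when simulating.
#' @param simulate If `TRUE`, inputs are generated by the simulator.
#' @param seed Integer seed (mandatory: the bootstrap and the simulator
#'   are stochastic).
#' @param genes Optional gene subset.
#' @param breeding_groups List of `list(population=, label=)` pairs to
#'   compare as LAN vs MV within the named populations.
#' @param traits Traits for the association stage.
#' @param major_threshold Major-haplotype frequency threshold (default 0.01).
#' @param i_nei_threshold Differentiation flag (default 0.35).
#' @param alpha Significance level (default 0.05).
#' @param very_significant Strong-association flag (default 1e-7).
#' @param n_boot Bootstrap resamples for the Z test (default 1000).
#' @param min_n Minimum phenotyped carriers per haplotype group (default 10).
#' @param sim_config Optional [gchap_sim_config()] overriding the default
#'   simulated study (its seed is taken from `seed`).
#' @return A validated list of class `gchap_pipeline_config`.
#' @export
gchap_config <- function(inputs = NULL, simulate = is.null(inputs), seed = 1,
                         genes = NULL,
                         breeding_groups = list(list(population = "Xian"),
                                                list(population = "Geng")),
                         traits = c("TGW", "PL", "PN", "PH"),
                         major_threshold = 0.01, i_nei_threshold = 0.35,
                         alpha = 0.05, very_significant = 1e-7,
                         n_boot = 1000, min_n = 10, sim_config = NULL) {
  if (!is_scalar_number(major_threshold) || major_threshold <= 0 ||
        major_threshold > 1) {
    stop_gchap("major_threshold must lie in (0, 1]", class = "gchapdiv_config_error")
  }
  if (!is_scalar_number(i_nei_threshold) || i_nei_threshold < 0 ||
        i_nei_threshold > 1) {
    stop_gchap("i_nei_threshold must lie in [0, 1]", class = "gchapdiv_config_error")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_gchap("alpha must lie in (0, 1)", class = "gchapdiv_config_error")
  }
  if (!is_scalar_number(seed)) {
    stop_gchap("seed is mandatory (stochastic stages run)",
               class = "gchapdiv_config_error")
  }
  if (!simulate) {
    needed <- c("fasta", "gff3", "vcf", "metadata")
    miss <- setdiff(needed, names(inputs))
    if (length(miss) > 0) {
      stop_gchap(paste0("inputs missing: ", paste(miss, collapse = ", ")),
                 class = "gchapdiv_config_error")
    }
  }
  structure(list(inputs = inputs, simulate = simulate, seed = as.integer(seed),
                 genes = genes, breeding_groups = breeding_groups,
                 traits = traits, major_threshold = major_threshold,
                 i_nei_threshold = i_nei_threshold, alpha = alpha,
                 very_significant = very_significant, n_boot = n_boot,
                 min_n = min_n, sim_config = sim_config),
            class = "gchap_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [gchap_config()]; a `thresholds`
#' block may hold `major_hap`, `i_nei`, `alpha`, `very_significant`.
#'
#' @param path YAML file path.
#' @return A `gchap_pipeline_config`.
#' @export
read_gchap_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds %||% list()
  gchap_config(
    inputs = y$inputs, simulate = y$simulate %||% is.null(y$inputs),
    seed = y$seed %||% 1, genes = y$genes,
    breeding_groups = y$breeding_groups %||%
      list(list(population = "Xian"), list(population = "Geng")),
    traits = y$traits %||% c("TGW", "PL", "PN", "PH"),
    major_threshold = th$major_hap %||% 0.01,
    i_nei_threshold = th$i_nei %||% 0.35,
    alpha = th$alpha %||% 0.05,
    very_significant = th$very_significant %||% 1e-7,
    n_boot = y$n_boot %||% 1000, min_n = y$min_n %||% 10)
}

#' Run the full gcHap pipeline
#'
#' Executes call -> diversity -> differentiation -> breeding ->
#' association (incl. favorable/unfavorable contrasts) -> network on
#' simulated or user data, writing every output table as TSV plus a
#' structured log (seeds, thresholds, exclusion counts) and a manifest
#' with checksums. Stage errors abort with a stage-named message; outputs
#' of the failed stage are retained with a `.partial` suffix. The
#' association stage is skipped, with a logged reason, when no
#' phenotypes are available.
#'
#' @param config A `gchap_pipeline_config` (or YAML path).
#' @param outdir Output directory.
#' @return The manifest tibble (`file`, `bytes`, `md5`), also written as
#'   `manifest.tsv`.
#' @export
run_gchap_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_gchap_config(config)
  stopifnot(inherits(config, "gchap_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("gchapdiv pipeline log",
                 paste0("seed: ", config$seed),
                 paste0("major_threshold: ", config$major_threshold),
                 paste0("i_nei_threshold: ", config$i_nei_threshold),
                 paste0("alpha: ", config$alpha),
                 paste0("n_boot: ", config$n_boot))
  files <- character(0)
  stage <- "load"
  emit <- function(x, name) {
    write_gchap_tsv(x, file.path(outdir, name))
    files <<- c(files, name)
  }
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      ## keep partial outputs of the failed stage
      part <- file.path(outdir, paste0(name, ".partial"))
      writeLines(conditionMessage(e), part)
      stop_gchap(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)))
    })
  }

  ## ---- load / simulate ----
  if (config$simulate) {
    simc <- config$sim_config %||% gchap_sim_config(seed = config$seed)
    ## rebuild so the pipeline seed governs the whole stream
    simc <- gchap_sim_config(
      seed = config$seed, populations = simc$populations, genes = simc$genes,
      drift = simc$drift, effects = simc$effects,
      trait_means = simc$trait_means, trait_sds = simc$trait_sds,
      pop_offsets = simc$pop_offsets, missing_rate = simc$missing_rate,
      pheno_missing_rate = simc$pheno_missing_rate,
      indel_haplotype = simc$indel_haplotype)
    study <- run_stage("simulate", simulate_gchap_study(simc))
    reference <- study$reference; gene_models <- study$gene_models
    variants <- study$variants; panel <- study$panel
    phenotypes <- study$phenotypes
    log_lines <- c(log_lines, "inputs: simulated")
  } else {
    reference <- run_stage("load", read_reference(config$inputs$fasta))
    gene_models <- run_stage("load", read_gene_models(
      config$inputs$gff3, genes = config$genes, reference = reference))
    panel <- run_stage("load", read_variety_panel(config$inputs$metadata))
    variants <- run_stage("load", read_variants(config$inputs$vcf, panel = panel))
    phenotypes <- if (!is.null(config$inputs$phenotypes)) {
      run_stage("load", read_phenotypes(config$inputs$phenotypes))
    } else NULL
    log_lines <- c(log_lines, paste0("inputs: ", config$inputs$vcf))
  }
  genes <- config$genes %||% unique(gene_models$gene_id)

  ## ---- call ----
  gchaps <- run_stage("call", call_gchaps(reference, gene_models, variants,
                                          panel, genes = genes))
  emit(gchaps$assignments, "gchap_assignments.tsv")
  emit(gchaps$haplotypes, "hap_sequences.tsv")
  emit(gchaps$excluded, "exclusions.tsv")
  log_lines <- c(log_lines, paste0("exclusions: ", nrow(gchaps$excluded)))

  ## ---- diversity & differentiation ----
  div <- run_stage("diversity", diversity_summary(
    gchaps$assignments, panel, threshold = config$major_threshold))
  emit(div, "diversity.tsv")
  diff <- run_stage("differentiation", pairwise_differentiation(
    gchaps$assignments, panel, threshold = config$i_nei_threshold))
  emit(diff, "differentiation.tsv")

  ## ---- breeding signatures ----
  breeding <- run_stage("breeding", purrr::map_dfr(
    config$breeding_groups, function(bg) {
      lan <- panel_group(panel, bg$population, "LAN")
      mv <- panel_group(panel, bg$population, "MV")
      if (length(lan) == 0 || length(mv) == 0) {
        return(tibble::tibble())
      }
      out <- compare_breeding_groups(
        gchaps$assignments, panel, lan, mv, genes = genes,
        n_boot = config$n_boot, seed = config$seed)
      dplyr::mutate(out, group_a = paste0("LANs-", bg$population),
                    group_b = paste0("MVs-", bg$population), .after = "gene_id")
    }))
  emit(breeding, "breeding.tsv")

  ## ---- association ----
  if (!is.null(phenotypes)) {
    assoc <- run_stage("association", purrr::map_dfr(genes, function(g) {
      purrr::map_dfr(config$traits, function(tr) {
        res <- tryCatch(
          gchap_trait_anova(gchaps$assignments, phenotypes, g, tr,
                            threshold = config$major_threshold,
                            min_n = config$min_n, alpha = config$alpha,
                            very_significant = config$very_significant),
          gchapdiv_error = function(e) NULL)
        if (is.null(res)) return(tibble::tibble())
        gl <- glance(res)
        gl$letters <- paste(res$groups$hap_id, res$groups$letters,
                            sep = ":", collapse = ",")
        gl
      })
    }))
    if (nrow(assoc) > 0) {
      assoc$p_bonferroni <- pmin(1, assoc$p_value * nrow(assoc))
    }
    emit(assoc, "association.tsv")
    contrasts <- run_stage("contrast", {
      fav <- label_favorable_unfavorable(
        gchaps$assignments, threshold = config$major_threshold, genes = genes)
      contrast_traits(fav, gchaps$assignments, phenotypes,
                      traits = config$traits, alpha = config$alpha)
    })
    emit(contrasts, "contrasts.tsv")
    favfreq <- run_stage("favorable_frequencies", {
      dirs <- default_trait_directions()
      targets <- intersect(config$traits, names(dirs))
      fav_tbl <- purrr::map_dfr(genes, function(g) {
        purrr::map_dfr(targets, function(tr) {
          tryCatch(favorable_hap_for_trait(
            gchaps$assignments, phenotypes, g, tr,
            threshold = config$major_threshold, min_n = config$min_n),
            gchapdiv_error = function(e) tibble::tibble())
        })
      })
      if (nrow(fav_tbl) > 0) {
        favorable_allele_frequencies(gchaps$assignments, panel, fav_tbl)
      } else tibble::tibble()
    })
    emit(favfreq, "favorable_frequencies.tsv")
  } else {
    log_lines <- c(log_lines, "association: skipped (no phenotypes)")
  }

  ## ---- networks ----
  run_stage("network", for (g in genes) {
    net <- build_hap_network(gchaps, panel, g)
    written <- export_network(net, file.path(outdir, paste0("network_", g)))
    emit(net$nodes, paste0("network_", g, "_nodes.tsv"))
    files <- unique(c(files, basename(written)))
  })

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  files <- unique(c(files, "run_log.txt"))
  paths <- file.path(outdir, files)
  manifest <- tibble::tibble(file = files, bytes = file.size(paths),
                             md5 = unname(tools::md5sum(paths)))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}
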