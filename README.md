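# gchapdiv

Population-genetic analysis of **gene-CDS-haplotypes (gcHaps)** in crop
variety panels: from a reference genome, gene models, a variant table
and variety metadata, call per-locus haplotypes and analyse their
diversity, the footprint of modern breeding, and their association with
agronomic traits.

A gcHap is the haplotype defined by all variant sites within a gene's
coding sequence: varieties with identical CDS sequences share a gcHap.
This gene-level view of allelic variation is the working unit for
candidate-gene studies in large inbred panels such as the rice diversity
collections (Xian/indica, Geng/japonica, Aus, Bas and admixed groups,
with landrace, LAN, vs modern variety, MV, substructure). The package is
aimed at crop population geneticists and breeders who want that analysis
reproducible end-to-end rather than spread across ad-hoc scripts.

## What it computes

* **gcHap calling** — per-variety CDS reconstruction (strand-aware,
  indel-capable) and frequency-ranked haplotype tables, with
  conservative exclusion of missing/heterozygous genotypes.
* **Diversity** — per locus and population: gcHapN, major gcHapN
  (frequency >= 1%), dominant haplotype frequency `F_P`, and Shannon's
  evenness `E_H = (-sum p_i ln p_i) / ln N` in [0, 1].
* **Differentiation** — Nei's genetic identity between populations,
  `I = sum(x_i y_i) / sqrt(sum x_i^2 sum y_i^2)`, with pairs below 0.35
  flagged as strongly differentiated.
* **Breeding signatures** — LAN vs MV per locus: `delta E_H` with a
  seeded bootstrap Z test, gcHapN change, new gcHaps gained, dominant-
  haplotype frequency drift with a 2x2 chi-square test, and an
  up/down artificial-selection label.
* **Trait association** — one-way ANOVA of each trait across major
  gcHaps with Tukey HSD and compact letter displays;
  favorable-vs-unfavorable haplotype contrasts (Welch tests); per-trait
  favorable-allele frequencies across subpopulations.
* **Haplotype networks** — minimum mutation-step distances and a
  minimum spanning network (equal-weight ties retained), exported as
  GraphML/TSV with per-population node composition.
* **Auxiliaries** — Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
  correction and codon-level synonymous/non-synonymous annotation;
  Livak 2^-ddCt relative expression with four-level significance stars.
* **Synthetic studies** — a simulator with known ground truth (panel,
  loci, frequency spectra, LAN-to-MV drift, planted trait effects) that
  writes standard FASTA/GFF3/VCF/TSV fixtures byte-reproducibly.

All user-facing functions take and return tibbles, so stages compose
with the pipe; fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

A fully synthetic study with known truth (600 varieties, 6 genes):

```r
library(gchapdiv)

study  <- simulate_gchap_study(gchap_sim_config(seed = 42))
gchaps <- call_gchaps(study$reference, study$gene_models,
                      study$variants, study$panel)
glance(gchaps)
#> # A tibble: 6 × 6
#>   gene_id gcHapN n_assigned dominant_hap dominant_freq n_excluded
#> 1 gene1        4        600 Hap1                 0.512          0
#> 2 gene2        3        600 Hap1                 0.537          0
#> 3 gene3        6        600 Hap1                 0.435          0
#> # ...
```

Per-population diversity of one locus — four haplotypes everywhere, but
evenness and dominant-haplotype frequency differ by population:

```r
diversity_summary(tidy(gchaps), study$panel) |>
  dplyr::filter(gene_id == "gene1")
#>   gene_id population n_varieties gcHapN major_gcHapN   E_H dominant_hap   F_P
#> 1 gene1   Xian               200      4            4 0.775 Hap1         0.59
#> 2 gene1   Geng               150      4            4 0.879 Hap1         0.507
#> 3 gene1   Aus                100      4            4 0.912 Hap1         0.42
#> 4 gene1   Bas                 75      4            4 0.801 Hap1         0.587
#> 5 gene1   admix               75      4            4 0.948 Hap1         0.36
#> 6 gene1   All                600      4            4 0.862 Hap1         0.512
```

The breeding comparison (Xian landraces vs modern varieties). The
simulator's default drift flattens MV spectra, and the Z test picks this
up at three of six loci:

```r
lan <- panel_group(study$panel, "Xian", "LAN")
mv  <- panel_group(study$panel, "Xian", "MV")
compare_breeding_groups(tidy(gchaps), study$panel, lan, mv, seed = 42)
#>   gene_id E_H_A E_H_B delta_E_H z_pvalue significance selection_effect
#> 1 gene1   0.726 0.877    0.151  0.0412   *            up
#> 2 gene2   0.812 0.824    0.0119 0.886    ns           up
#> 3 gene3   0.824 0.867    0.0428 0.461    ns           up
#> 4 gene4   0.660 0.864    0.204  0.000797 **           up
#> 5 gene5   0.774 0.919    0.145  0.00458  **           up
#> 6 gene6   0.887 0.873   -0.0136 0.812    ns           down
```

The planted +2 g thousand-grain-weight effect on `gene1`'s second
haplotype is recovered by the association stage — carriers of `Hap2`
average 27.2 g against ~24.8 g for the others, and the compact letters
isolate it:

```r
gchap_trait_anova(tidy(gchaps), study$phenotypes, "gene1", "TGW")
#> <gchap_anova> gene1 x TGW: F = 32.75, p = 1.32e-19 (very significant)
#>   hap_id     n  mean    sd letters
#> 1 Hap1     307  24.8  2.42 b
#> 2 Hap2     139  27.2  2.54 a
#> 3 Hap3     102  25.2  2.26 b
#> 4 Hap4      52  24.6  2.67 b
```

`run_gchap_pipeline(gchap_config(seed = 42), "results/")` executes all
stages (call, diversity, differentiation, breeding, association,
networks) and writes every table plus a checksum manifest; identical
config and seed reproduce the outputs byte-for-byte. A thin CLI wrapper
lives at `inst/scripts/run_pipeline.R`.

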