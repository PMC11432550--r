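---
title: "Gene-CDS-haplotype diversity analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-CDS-haplotype diversity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gchapdiv)
```

## The gcHap model

A *gene-CDS-haplotype* (gcHap) is the haplotype defined by all variant
sites falling within a gene's coding sequence: two varieties share a
gcHap exactly when their CDS nucleotide sequences are identical.
Compared with single-SNP views, gcHaps treat the gene as the unit of
allelic variation, which is the natural resolution for connecting
candidate genes to agronomic traits in inbred crop panels such as large
rice diversity collections (thousands of varieties structured into the
Xian/indica, Geng/japonica, Aus, Bas and admixed groups, each split into
landraces, LAN, and modern varieties, MV).

`call_gchaps()` builds each variety's CDS per gene from the reference,
the CDS exon model and the variety's variant alleles, then collapses
identical sequences. Haplotypes are labelled `Hap1, Hap2, ...` in
decreasing panel-wide frequency, with ties broken by the panel order of
the first carrier. These labels are per-analysis frequency ranks, not
stable global identifiers: the haplotype-sequence table is emitted
alongside so that reruns (or external numbering schemes) can be
reconciled by sequence rather than by label.

Two policies matter here and are deliberately conservative:

* **Heterozygous and missing genotypes.** The panels this method targets
  are inbred lines, so a heterozygous GT is treated as missing by
  default (`het_policy = "missing"`, optionally `"first"`). A variety
  with any missing CDS genotype at a locus is *excluded at that locus*
  (reason `missing_genotype`) rather than imputed; exclusion keeps every
  downstream frequency auditable from the assignment table alone.
* **Indels.** CDS substitutions are applied in ascending genomic
  position with offsets tracked, so in-frame indels shift downstream
  variant offsets correctly. SNP-only haplotypes are the default in the
  simulator; one in-frame indel haplotype can be injected
  (`indel_haplotype = TRUE`) to exercise this path.

## Diversity statistics

Per locus and population the package reports gcHapN (distinct
haplotypes), the number of *major* gcHaps (frequency at least 1%, the
conventional cutoff, configurable), the dominant haplotype and its
frequency `F_P`, and Shannon's evenness

$$E_H = \frac{-\sum_i p_i \ln p_i}{\ln N},$$

where \(p_i\) are the haplotype frequencies among non-excluded varieties
and \(N\) is the number of haplotypes observed *in that population at
that locus* (with \(0\ln 0 := 0\) and \(E_H := 0\) when \(N = 1\)). The
normalisation base is a genuine design choice: normalising by the
population-specific \(N\) (rather than a panel-wide count) makes
\(E_H = 0\) equivalent to monomorphism and keeps \(E_H \le 1\) within
every population, matching how per-population evenness tables are read.
The function is isolated (`shannon_evenness()`) so an alternative base
is a one-line substitution.

Differentiation between two populations is Nei's genetic identity over
the union of haplotypes,

$$I = \frac{\sum_i x_i y_i}{\sqrt{\left(\sum_i x_i^2\right)\left(\sum_i y_i^2\right)}} \in [0, 1],$$

with pairs below 0.35 *flagged* as strongly differentiated. The 0.35
cutoff is a reporting convention, not a hypothesis test, and the flag is
presented as such.

## Breeding signatures (LAN vs MV)

For each locus, `compare_breeding_groups()` contrasts a landrace group A
with a modern-variety group B: \(\Delta E_H = E_H(B) - E_H(A)\), the
change in gcHapN, the number of *new* gcHaps (at least one carrier in B,
none in A — raw presence, not major status, since it is paired with
total gcHapN), and the drift of the dominant haplotype's frequency.

Two tests back these summaries:

* **Evenness Z test.** No closed-form variance is available for the
  evenness of haplotype counts, so the standard error of each group's
  \(E_H\) is estimated by a seeded nonparametric bootstrap over
  varieties within the group (equivalently multinomial resampling of the
  count vector; default 1000 resamples), and
  \(Z = \Delta E_H / \sqrt{SE_A^2 + SE_B^2}\) is referred to the
  standard normal, two-sided. Stars follow the comparison-table
  convention (`**` p < 0.01, `*` p < 0.05, `ns`). Applying the Z test to
  \(E_H\) (rather than to \(F_P\)) is a documented interpretation: the
  evenness difference is the quantity the selection-effect label is
  defined on, while \(F_P\) drift has its own chi-square test below.
* **Frequency drift chi-square.** A Pearson chi-square (df = 1, no
  continuity correction) on the 2x2 carriers/non-carriers table of one
  haplotype in the two groups; degenerate tables (a zero margin) are
  flagged with an undefined p rather than silently patched.

The *artificial selection effect* label is purely the sign of
\(\Delta E_H\): `up` for positive, `down` for negative, `none` at exactly
zero. Groups below 10 varieties yield an undefined Z with a warning.
When the whole comparison is degenerate (both groups monomorphic) the Z
statistic is 0 and p = 1 by convention.

## Haplotype-trait association

`gchap_trait_anova()` fits a one-way fixed-effects ANOVA of one trait
across the major gcHaps of one gene, followed by Tukey's HSD on all
pairs. One-way ANOVA + Tukey is used (a two-factor/Duncan variant was
considered and rejected as the non-Methods description of the same
analysis). Haplotype groups with fewer than `min_n` phenotyped carriers
(default 10) are dropped from the model and recorded in the result.
Compact letters come from the insert-and-absorb algorithm: start with
one letter column containing all groups; for each significant pair,
split every column containing both; absorb subset columns; letter the
columns in order of their best group mean. This construction guarantees
the display property that two haplotypes share a letter *iff* Tukey does
not separate them at \(\alpha\), which the tests verify exhaustively for
up to six groups. If every observation is identical the model is
degenerate and F = 0, p = 1, one shared letter is reported by
convention.

No multiple-testing correction is applied across genes and traits — the
`p < 1e-7` "very significant" flag is reported as-is to match how such
scans are read — but a Bonferroni column is emitted in the pipeline's
association table for transparency.

The favorable/unfavorable contrast labels the most frequent major gcHap
favorable (presumed favored by selection) and the lowest-frequency major
gcHap unfavorable, ties broken by haplotype rank with the favorable
haplotype excluded from the unfavorable candidates (so a frequency tie
can never select the same haplotype twice). Per trait the two carrier
groups are compared with a Welch two-sample test; groups with fewer than
5 non-missing values give `insufficient data` rather than an error.
These contrasts default to whole-panel grouping; a population subset can
be passed explicitly. Per-trait *favorable alleles* (the major haplotype
with the best mean in the declared direction) require an explicit
direction map; only TGW, GL, GW, PL and CN default to higher-is-better,
and any other trait without a declared direction is an error rather than
a hidden assumption.

## Haplotype networks

The network stage connects haplotypes by minimum mutation steps: the
distance between two aligned CDS sequences is the number of differing
positions, with a run of contiguous gap positions counting as one step
(one indel event; per-position counting is available). Sequences of
unequal length are end-gap aligned pairwise first. The network itself is
a *minimum spanning network*: Kruskal growth in ascending distance in
which every edge whose weight equals the weight first connecting its two
components is retained, so equal-cost alternative links survive instead
of an arbitrary tie-break; the result always contains a minimum spanning
tree and equals the MST exactly when all distances are distinct. This
realises "connect closely related haplotypes with a minimum of mutation
steps" in the sense of the classical haplotype-network tools;
median-joining inference of unobserved intermediate haplotypes is
deliberately out of scope. Nodes carry total frequency and
per-population carrier counts (for pie rendering); exports are GraphML
and an edge-list TSV.

## Ka/Ks and codon annotation

Because homologous CDS pairs are compared without the estimator being
externally fixed, the package implements the Nei-Gojobori (1986)
counting method, the most transparent choice, and isolates it so other
estimators can be added: per codon position, the fraction of single-base
changes that are synonymous (changes to stop codons excluded from the
denominator) gives synonymous site counts \(S\) (averaged between the
two sequences); per-codon differences are resolved by averaging over all
minimal substitution pathways, excluding pathways through stop codons
unless all are blocked; and the Jukes-Cantor correction
\(K = -\tfrac34 \ln(1 - \tfrac43 p)\) maps the proportions to rates. The
correction is undefined at \(p \ge 3/4\) and flagged, as is the ratio
when \(K_s = 0\). Ratios below 1 are annotated as purifying selection.
Published Ka/Ks values for specific gene pairs are estimator-dependent,
so they are treated as context, not as a numeric target for this
implementation. `classify_codon_changes()` reuses the same code table to
annotate inter-haplotype differences as synonymous or non-synonymous.

## Relative expression (2^-ddCt)

The Livak method: technical replicates are averaged to one Ct per
sample; \(\Delta C_t = C_t^{target} - C_t^{reference}\) per biological
replicate; \(\Delta\Delta C_t\) subtracts the mean control-timepoint
\(\Delta C_t\) of the same condition (control = 0 h by default — whether
the control is the same-treatment 0 h or an untreated parallel is
configurable, same-treatment being the default); the fold change is
\(2^{-\Delta\Delta C_t}\) per biological replicate. Significance stars
use the four-level grid (`****` < 1e-4 through `*` < 0.05) from a Welch
test of treated vs control \(\Delta C_t\); a single-replicate group is
`nd`. A one-way ANOVA across timepoints is also emitted, since both
styles of call appear in practice. Primer-efficiency (Pfaffl) correction
is out of scope.

## The synthetic study

The simulator exists so that every downstream stage is testable with
known ground truth and no download. Its defaults define the study
conditions and mirror a large rice panel qualitatively at desk scale:

* **Panel:** 5 populations (Xian 200, Geng 150, Aus 100, Bas 75, admix
  75; 600 varieties), with LAN/MV fractions 0.6/0.3 for Xian and Geng
  and 0.8/0.1 for Aus and Bas; admix carries neither label. Counts are
  exact (`round(n * fraction)`), improvement classes are assigned
  deterministically, subpopulation labels (XI-1A ... GJ-trp) are drawn
  within population.
* **Loci:** 6 genes on separate chromosomes, 1-3 CDS exons, CDS lengths
  300-900 bp (divisible by 3), 3-10 haplotypes per locus, strands mixed
  so reverse-complement handling is always exercised.
* **Frequency spectra:** each locus gets a base spectrum
  \(0.8 \cdot d^{i-1}/\sum d^{j-1} + 0.2/K\) with decay \(d = 0.45\) — one
  dominant haplotype (~0.5-0.7) and a floor that keeps minor haplotypes
  above ~2% so "major gcHap" logic has substance. Population-specific
  vectors are Dirichlet draws around the base (concentration 80, drawn
  once at configuration time and stored explicitly in the config).
* **LAN-to-MV drift:** MV vectors tilt the LAN vector by
  \(q_i \propto p_i^{1-d_g}\) with per-gene drift \(d_g \in [0.1, 0.45]\),
  which flattens spectra — modern varieties show mildly higher evenness,
  the qualitative signature the breeding stage is designed to detect.
* **Haplotype sequences:** a random mutation tree — each haplotype adds
  1-2 private SNPs to a random earlier haplotype — guaranteeing pairwise
  distinctness, biallelic sites and a tree-shaped network; alternative
  bases that would create a premature stop are avoided where possible.
* **Phenotypes:** \(y = \mu_t + \text{population offset} +
  \sum_g \beta(hap) + \mathcal N(0, \sigma_t)\) over the 14-trait panel,
  with means and standard deviations at realistic magnitudes (e.g. TGW
  25 ± 2.5 g, GL 8.5 ± 0.4 mm) and planted effects of roughly one
  residual standard deviation (e.g. +2 g TGW) on a handful of
  (gene, haplotype, trait) triples.
* **Randomness:** one seed drives everything; the three stages consume
  documented substreams (seed, seed+1, seed+2 for panel, haplotypes,
  phenotypes) so each stage is independently reproducible and the
  end-to-end run is byte-deterministic, including the emitted
  FASTA/GFF3/VCF/TSV fixture files.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: linkage between loci, recombination
within genes (real "new gcHaps in MVs" partly arise by intragenic
recombination; simulated MV novelty comes only from drifted frequencies),
coalescent-realistic frequency spectra, genotyping error, population
structure within subpopulations, and environment or kinship effects on
traits. Results on real panels depend on upstream variant calling
quality, which is out of scope entirely.

## Problem sizes and numerical conventions

The test suite runs the closure check on the full default study (600
varieties, 6 genes), the statistical calibration at 500 replicates per
test (null type-I error bands [0.03, 0.07] at \(\alpha = 0.05\)), the
oracle comparisons on 200 random graphs (n <= 7) and 100 random codon
pairs (<= 10 codons), and the determinism check on a reduced 3-gene,
260-variety pipeline run — sizes chosen so the whole suite stays fast
while every claim is still measured, not assumed. Agreement tolerances
are 1e-10 against algebraic oracles (ANOVA F, chi-square, NG86 counts)
and 1e-12 for the dual-route recomputation of \(E_H\) and \(I_{Nei}\).

Other conventions, collected in one place: frequencies are always over
non-excluded varieties of the subset under analysis; dominant-haplotype
ties break toward the lower haplotype rank; TSV outputs print floats
with 6 significant digits and are write-read stable; the pipeline
manifest hashes every output file so reruns can be compared by checksum;
and all user-facing tables are tibbles so stages compose with the pipe.

## Known limitations

Haplotype labels are analysis-local; cross-dataset reconciliation must
go through sequences. The bootstrap Z test is approximate for very small
groups (hence the `min_n = 10` guard) and, like any evenness-based test,
says nothing about *which* haplotypes shifted — pair it with the
per-haplotype chi-square table. The NG86 estimator undercorrects at high
divergence relative to maximum-likelihood estimators; for the
within-species haplotype comparisons it is designed for, divergences are
tiny and the choice is immaterial. The MSN reading of the network
construction is an interpretation of an underspecified upstream
description and is documented as such.
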