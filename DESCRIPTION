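Package: gchapdiv
Title: Gene-CDS-Haplotype Diversity, Breeding Signatures and Trait
    Association in Crop Variety Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls gene-CDS-haplotypes (gcHaps) for each gene locus of a
    variety panel from a reference genome, gene models and a variant table,
    and analyses their population genetics: Shannon evenness and Nei's
    genetic identity per population, landrace-versus-modern-variety breeding
    signatures (bootstrap Z tests on evenness, chi-square tests on dominant
    haplotype frequency drift), haplotype-trait association by one-way ANOVA
    with Tukey compact letter displays, favorable/unfavorable haplotype
    contrasts, minimum-spanning haplotype networks, Nei-Gojobori (1986)
    Ka/Ks with Jukes-Cantor correction, and Livak 2^-ddCt relative
    expression. Includes a synthetic panel simulator with known ground truth
    emulating the structure of large rice diversity panels, and a
    file-driven pipeline orchestrating all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
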