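Package: poolseg
Title: Bulk Segregant Analysis of Pooled Yeast Segregants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative causal mutations from pooled-segregant
    (bulk segregant) sequencing of experimentally evolved budding yeast.
    Annotates variants against single-exon gene models (coding, promoter,
    synonymous/missense/nonsense/frameshift) with standard mutation
    nomenclature, classifies mutations by their allele frequency in a
    selected spore pool, separates linked hitchhikers from causal alleles,
    and assesses copy-number events from windowed read depth. A synthetic
    experiment generator simulates mutator evolution, backcross meiosis
    under a Haldane map, spore selection, pooled read sampling, and Sanger
    trace time courses, so the whole pipeline is testable end to end.
    Includes small quantitative helpers (adjusted-Wald binomial intervals,
    delta-delta-Ct fold changes, serial-dilution generation counts, and
    qualitative competition scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    broom,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
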