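Package: paraldiv
Title: Paralogue-Aware Population Genetics of Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of a duplicated gene and its
    paralogous pseudogene: classification of segregating sites by their
    coexistence across the paralogue pair (fixed, shared, specific),
    per-region and sliding-window diversity summaries, site-frequency-
    spectrum and haplotype neutrality tests (Tajima's D, Fu's Fs, Fay and
    Wu's H, normalized H, Ewens-Watterson), coalescent simulation under
    piecewise bottleneck-and-expansion demography with simulation-based
    rejection probabilities, gene-conversion tract masking reruns, MaxChi-
    style breakpoint scans, and distance-based tree diagnostics of
    concerted evolution (neighbor joining, bootstrap, BootScan signal,
    Robinson-Foulds). Ships a synthetic-data generator emulating the
    site-class structure of the human CYP21A2/CYP21A1P pair so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
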