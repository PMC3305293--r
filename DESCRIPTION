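Package: snpexpress
Title: Group-Exclusive SNP Discovery and Expression Divergence for
    Two-Population Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting the transcriptomes of two population
    groups sequenced with legacy long-read (454-style) technology: a
    seeded read simulator with planted variants and expression effects, a
    seed-and-extend read aligner with per-sample pileups, SNP calling with
    an allele-frequency window filter and group-exclusivity
    classification (fixed divergent vs. group-restricted polymorphism,
    with coding-effect annotation), RPKM quantification with
    empirical-Bayes moderated t-tests and Benjamini-Hochberg FDR control,
    fold-change tiers and centroid-linkage expression clustering, and the
    divergence summaries (Fisher exact test on within-group polymorphism,
    SNP-locus/DE-gene overlap) that tie the two analyses together. An
    orchestrated pipeline runs all stages from a single seeded
    configuration and emits FASTA/FASTQ/SAM/VCF/TSV/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
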