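Package: foxtail
Title: Post-Assembly Genome Analytics for Plant Genome Projects
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytical layer for a finished plant genome assembly project:
    genome-size estimation from k-mer multiplicity histograms, contig and
    scaffold summary statistics, transposable-element genic-context and
    strand-bias composition, permutation tests for sequence content at
    assembly-gap flanks, curation of Delly-style structural-variant calls
    with population minor-allele frequencies, MAKER-style gene-model
    filtration (AED thresholds, primary-isoform selection, orthogroup-aware
    final filtering), and hypergeometric enrichment of gene-family
    duplication sets with Benjamini-Hochberg correction. A deterministic
    synthetic-data generator emulates every input format with known ground
    truth so the whole pipeline is testable without any sequencing archive
    accession.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
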