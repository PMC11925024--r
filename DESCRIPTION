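Package: kmerdiv
Title: Alignment-Free Measures of Genetic Diversity from k-mer Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for alignment-free population genetics based on k-mer
    counting. Provides the chance-match theory for choosing a minimum k-mer
    length, ploidy-aware bounds linking sample-exclusive k-mers to nucleotide
    diversity, canonical k-mer counting from FASTA/FASTQ with error
    thresholding, Jaccard, Bray-Curtis and cosine k-mer dissimilarities,
    counting-bloom-filter compression of count vectors, a neutral coalescent
    population and short-read simulator with exact true diversity, and an
    experiment driver that regresses k-mer dissimilarity scores against true
    nucleotide diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
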