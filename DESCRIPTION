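Package: ampliclass
Title: Class-Weight-Aware Taxonomic Classification of 16S rRNA Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for taxonomic classification of 16S rRNA amplicon
    reads from k-mer features. Implements a multinomial naive Bayes
    classifier with ecological class-weight priors, a random-forest
    classifier over k-mer count bags, a small one-dimensional
    convolutional network over CBOW k-mer embeddings or one-hot
    nucleotides, and an exact-sequence-match classifier that measures the
    upper bound of achievable accuracy for a reference database. All
    classifiers share a confidence-threshold assignment procedure that
    truncates lineages rank by rank. Includes per-rank precision, recall
    and F-measure, multiclass Matthews correlation, community-weighted
    cross-validation, paired Wilcoxon comparisons with Hommel correction,
    and a deterministic synthetic-data generator for taxonomies, reference
    sequences, skewed communities and reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
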