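Package: promokit
Title: Promoter Sequence Classification with k-mer Encodings, Shuffled
    Negatives and Convolutional, Recurrent and Random-Forest Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for classifying fixed-length putative promoter
    sequences. Provides promoter-window extraction around transcription
    start sites, composition-preserving shuffled negative sets
    (mononucleotide and dinucleotide modes), overlapping k-mer feature
    extraction with frequency-based tokenization and one-hot encoding,
    three reference classifiers (a 1D convolutional network, an LSTM
    recurrent network and a random forest) with a shared training
    configuration, and binary, cross-species, random-background and
    multiclass evaluation with accuracy, sensitivity, specificity and
    Matthews correlation coefficient. A synthetic promoter generator with
    planted positional motifs makes every stage testable without genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    ranger,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
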