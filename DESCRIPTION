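Package: lctriangle
Title: Low Complexity Triangle Analysis of Protein Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assess protein sequence low complexity by decomposing sequences
    into overlapping fixed-length windows and scoring each window on two
    axes: the minimum number of mutations needed to turn the window into a
    perfect tandem repeat (MMPR, the repeatability axis) and the fraction of
    the most frequent amino acid (the compositional axis). Window scores are
    pooled into a discrete triangular count grid, summarised as occupancy
    percentages of nested high-complexity regions, and rendered as a log10
    abundance heatmap. Includes a FASTA reader and region slicer, seeded
    generators for synthetic benchmark sequences (homorepeats, direpeats,
    degenerate tandem repeats, random and biased composition), and a
    command-line driver mirroring the restrictions of the original web
    server.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
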