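Package: flym6A
Title: miCLIP m6A Site Mapping and Genetic-Control Analyses for Drosophila
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing antibody-based m6A miCLIP data with a
    writer-null genetic control: crosslink-induced-mutation (CIM) calling
    with the m > 1 and 0.01 < m/k < 0.5 filter, Poisson likelihood-ratio
    differential peak calling of IP over input with Mettl3-dependent versus
    -independent classification, local-minimum peak splitting, metagene
    profiles on a fixed 200/1000/300-bin 5'UTR/CDS/3'UTR scale, sequence
    context matrices and IUPAC consensus around CIMs, transcript-segment
    annotation with fixed precedence, bootstrap-background two-sample
    Kolmogorov-Smirnov comparisons of target-gene properties, performance
    indices and estimation statistics (BCa bootstrap effect sizes,
    Mann-Whitney tests, precision planning) for olfactory-conditioning
    behaviour, and interquartile-fence scoring of m6A-probe proteomics.
    Includes a full synthetic-data generator emulating all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
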