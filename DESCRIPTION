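Package: porewise
Title: Simulation and Quality Control of Nanopore Sequencing Runs
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising MinION-style nanopore sequencing runs
    and for simulating them. Provides a flow-cell and run simulator (512
    channels x 4 wells, mux well-group allocation, pore inactivation,
    declining event rate, bias-voltage quality dips, template/complement/2D
    reads with configurable miscall, insertion and deletion rates), readers
    and writers for the run artifact formats (FASTQ with structured
    per-read metadata, =/X SAM, run-log TSV, JSON config), time-binned
    yield profiles normalised per active pore, per-read error
    decomposition into miscall, insertion and deletion percentages,
    target/control read classification, 5-mer representation-bias tables,
    Phred quality calibration statistics, and majority-vote pileup
    consensus accuracy as a function of theoretical fold coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
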