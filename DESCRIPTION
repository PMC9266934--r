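Package: isonodule
Title: Isoform-Level Alternative Splicing, Switch and lncRNA Analysis for
    Time-Course Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream isoform-level analysis of full-length transcriptome
    annotations over a two-condition time-course design: classification of
    alternative-splicing events (intron retention, exon skipping, alternative
    5'/3' splice sites, mutually exclusive exons) from exon chains,
    percent-spliced-in (PSI) based differential splicing with temporal
    clustering, major-isoform calling and isoform-switch detection and
    categorisation, positional classification of long non-coding RNAs with
    partner correlation analysis, and rule-based screening for
    nonsense-mediated-decay features.  Includes a synthetic-data generator
    that plants ground-truth splicing events, isoform switches and lncRNA
    partner correlations for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
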