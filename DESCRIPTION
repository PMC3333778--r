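Package: cnladder
Title: Allele-Specific Copy Number Calling for Tumor SNP-Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Allele-specific copy number analysis of tumor SNP-array data
    without matched normals. Summarizes each genomic segment by its mean
    Log-ratio and an allelic imbalance ratio obtained by two-means
    clustering of mirrored B-allele frequencies, then calls total and
    minor copy number by iteratively building a sample-specific ladder of
    expected (Log-ratio, allelic imbalance) coordinates from low to high
    copy number. Robust to aneuploidy, normal-cell admixture down to
    about 30 percent tumor cells, and subclonal (non-integer) copy
    number, which it flags. Includes changepoint segmentation of marker
    tracks, a short-segment splitter for double-minute-like
    amplifications, a synthetic tumor-signal simulator with ground truth
    (dilution series, subclones, short amplicons), and a
    sensitivity/specificity evaluation protocol against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
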