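Package: cas13screen
Title: Design and Analysis of Pooled CRISPR/Cas13 Survival-Challenge Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled CRISPR/Cas13 phenotypic screens that use
    targeting/mismatch guide pairs as sequence-matched controls. Covers
    28-mer crRNA spacer design with composition, uniqueness and repeat
    filters plus central-mismatch control generation; exact-match guide
    quantification from amplicon reads; library coverage and evenness
    diagnostics; doxycycline-contrast (D - ND) and targeting-vs-mismatch
    (T - MT) inference with one-sided paired t-tests and
    Benjamini-Hochberg adjustment; RNA-seq fold-change target selection;
    and a fully seeded simulator of screen count data, amplicon reads and
    expression tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
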