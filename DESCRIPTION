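Package: immnorm
Title: Iterated Median of M-Values Normalization for RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Normalization of RNA-seq read-count libraries by the iterated
    median of M-values (IMM): the scaling factor between two libraries is the
    median log2 fold change over an iteratively refined invariant set of
    genes, where genes called differentially expressed at a
    Benjamini-Hochberg Q-value threshold are excluded and the factor
    recomputed until it stabilizes. Includes the trimmed mean of M-values
    (TMM) and library-size baselines, exact binomial (Fisher/Poisson) and
    Poisson likelihood-ratio tests for two-condition comparisons with
    effective library totals, a Poisson count simulator with known
    differential-expression structure, and false-discovery-curve
    benchmarking of normalization and test combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, statmod, edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
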