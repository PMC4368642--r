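Package: rhythmscan
Title: Empirical JTK_CYCLE Rhythm Detection with Asymmetry Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects periodic (e.g. circadian) patterns in genome-wide
    expression time series. Implements the empirical JTK_CYCLE procedure: the
    Kendall tau rank correlation between each series and a family of triangle
    or cosine reference waveforms spanning phases and asymmetries, with the
    significance of the max-over-waveforms selection step computed from a
    Monte-Carlo permutation null rather than a Bonferroni or
    Benjamini-Hochberg correction. Also provides the F24 Fourier-projection
    test with a Gamma-fit permutation null, one-way ANOVA across time points
    with optional interpolated pseudo-replicates, simulated benchmark
    generators with ground-truth labels, AUROC/MCC evaluation, and a Z-score
    procedure for merging multi-study expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'waveforms.R'
    'tau.R'
    'significance.R'
    'comparators.R'
    'simulate.R'
    'evaluate.R'
    'preprocess.R'
    'io.R'
    'detect.R'
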