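Package: epiaccel
Title: Epigenetic Age Acceleration Analysis by Reference-Group Residual Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing DNA methylation surrogate biomarkers across
    phenotype groups. Provides quality control of Illumina-style beta-value
    matrices against detection p-values, a generic engine for linear and
    composite epigenetic clocks, reference-based cell-fraction deconvolution,
    Tukey-fence outlier removal, and a two-stage residual-outcome regression in
    which each biomarker is regressed on chronological age and sex within a
    designated reference group and all groups are compared on the resulting
    residuals with pooled-variance t-tests. A synthetic cohort generator with
    known injected age-acceleration effects supports end-to-end validation, and
    a pipeline driver orchestrates the full analysis from a configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
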