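Package: trpscan
Title: Discovery and Annotation of Residue-Localized Delta-Mass Variants
    from Open-Search Proteomics
Version: 0.1.0
Authors@R:
    person("trpscan", "developers", email = "trpscan@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for wildcard (open) database searches
    of shotgun proteomics data. Filters peptide-spectrum matches by
    confidence scores, clusters residue-localized delta masses into variant
    peaks using per-window Gaussian mixture models with BIC model selection
    and goodness-of-fit filtering, annotates peaks against a curated
    modification database including cascade (base plus secondary) reactions
    via Unimod-style elemental composition arithmetic, and runs cohort-level
    statistics: paired tumour versus adjacent-normal differential
    modification levels, Spearman correlation of modification profiles, and
    optimal-cutpoint log-rank survival analysis. Includes a synthetic-data
    generator so the whole pipeline is testable without raw
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
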