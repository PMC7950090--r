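Package: massshiftr
Title: Mass-Shift Profiling for Open-Search Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of open (mass-tolerant) database search results in
    shotgun proteomics. Builds a finely binned, smoothed histogram of precursor
    delta masses across one or more experiments, calls mass-shift peaks by
    prominence and ranks them by signal-to-noise remainder, annotates each peak
    by decomposition into at most two known modification masses, localizes
    shifts within peptides by exhaustive single-site fragment rescoring, and
    compares modified spectra with unmodified counterparts (cosine spectral
    similarity and retention-time deltas). Includes a synthetic-fixture
    generator with ground-truth manifests for end-to-end validation and
    deterministic multi-experiment TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
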