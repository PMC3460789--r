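Package: e3miner
Title: Mining and Expression Characterization of E3 Ubiquitin Ligases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a genome-wide catalogue of putative E3 ubiquitin ligases
    from profile-HMM domain search output (RING/zf-C3HC4, HECT and U-box
    domains with an E-value filter), summarizes cross-species conservation of
    the catalogue through ortholog-group intersection with an exact binomial
    enrichment test, rates tissue specificity of mRNA expression on a
    five-level scale (absent, present, highly present, multi-tissue specific,
    specific) from per-dataset z-scores aggregated by a cross-dataset ballot,
    and classifies developmental expression onset during spermatogenesis into
    mitotic, meiotic and post-meiotic groups. Ships a synthetic-data generator
    that emulates multi-tissue microarray panels with presence/absence calls,
    EST count profiles and staged developmental time courses with known ground
    truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
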