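Package: planktraits
Title: Morpho-Functional Trait Analysis of Phytoplankton Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trait-based analysis of summertime phytoplankton
    community monitoring data. Resolves binary morpho-functional traits
    (nitrogen fixation, mixotrophy, motility, buoyancy, harmfulness, size)
    per taxon from a trait table with genus-level propagation rules, applies
    standard exclusion filters to counting-unit observations, derives
    morphometric statistics (equivalent spherical diameter), summarizes
    hydrographic depth profiles into surface-layer means and a
    density-based stratification index (EOS-80), classifies water bodies by
    nutrient loading source, builds a 27-column matrix of trait biomasses
    and biomass shares, and fits one penalized-spline generalized additive
    mixed model per response with nested random intercepts, continuous-time
    AR(1) residuals, and per-area variance weights, followed by
    Tukey-adjusted pairwise contrasts of estimated marginal area means.
    Includes a hierarchical survey simulator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    nlme,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
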