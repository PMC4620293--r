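Package: nkckr
Title: Simulation and Hierarchical Gating of NK-Cell Chemokine-Receptor
    Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising chemokine-receptor repertoires of
    blood natural killer (NK) cell subsets from event-level flow
    cytometry. Provides a moment-matched lognormal simulator that
    generates multi-tube cytometry cohorts from published per-subset
    summary tables, readers and writers for FCS 2.0/3.0/3.1 list-mode
    and tabular CSV data, isotype-calibrated hierarchical gating
    including a deterministic two-component CD56 mixture boundary and
    the pooled CXCR3/CCR5-channel three-way split into CD56+low,
    CD56+int and CD56+high subsets, per-subset statistics (percent
    positive, MFI, CV), cohort summaries, Mann-Whitney comparisons,
    subject-level correlations, an intermediacy verdict for
    transitional NK-cells, and a chemokine receptor-ligand reference
    map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
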