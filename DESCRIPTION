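Package: flowCapacity
Title: Capacity-Monitor Analysis of Gene-Expression Resource Load from
    Co-Transfection Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the draw of synthetic constructs on shared mammalian
    gene-expression resources from co-transfection flow-cytometry data. A
    constitutively expressed fluorescent capacity monitor is co-delivered with
    each test construct; the drop in its mean fluorescence relative to an
    empty-vector control measures the construct's resource footprint. The
    package reads FCS or CSV event tables, selects transfected cells with a
    fuzzy OR gate fitted on a negative control, summarises gated populations,
    applies Tukey-fence outlier exclusion to replicate means, computes
    remaining-capacity percentages, doxycycline induction fold changes and
    exact two-sided Mann-Whitney comparisons, and attributes resource load to
    promoter, Kozak and polyA choices through single-factor pair deltas,
    quartile bars and Pareto fronts. A shared-resource co-transfection
    simulator with per-event ground truth provides a fully synthetic test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
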