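Package: plfatax
Title: PLFA Chemotaxonomy and Trophic Fatty-Acid Transfer in Pond Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phospholipid fatty acid (PLFA) chemotaxonomy of
    aquatic microbial communities. Parses fatty-acid nomenclature (omega
    notation, iso/anteiso and methyl branching, hydroxy and cyclopropyl
    acids), builds taxon-by-fatty-acid ratio matrices (referenced to 16:0)
    from cultured-isolate profiles, estimates autotroph and heterotroph
    group abundances in seston by CHEMTAX-style constrained matrix
    factorization with bounded ratio adjustment, quantifies bacterial,
    fungal and autotroph marker fatty acids in consumer lipid fractions
    with retention ratios of essential fatty acids, and screens variables
    for principal component analysis (Kaiser-Meyer-Olkin adequacy and
    communalities). Includes a synthetic-data generator emulating pond
    seston, isolate libraries and zooplankton profiles so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
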