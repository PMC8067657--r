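Package: phycobycatch
Title: Heterotroph Bycatch Communities in Picocyanobacterial Enrichment
    Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the heterotrophic bacterial "bycatch" communities
    that co-occur with Prochlorococcus and Synechococcus in long-term seawater
    enrichment cultures. Implements plate-adjacency decontamination and
    relative-abundance floor filtering of amplicon feature tables with
    mock-community floor calibration, host-read exclusion and host-normalized
    abundance, greedy percent-identity OTU clustering, unweighted UniFrac,
    principal coordinates and Ward clustering, permutation statistics
    (PERMANOVA, beta-dispersion, indicator species analysis), Fisher exact and
    rank-based association tests, and culture-versus-ocean prevalence
    analyses, together with synthetic-data generators (plates with cross-well
    leakage, dilution-series mock communities, ocean transect site tables)
    that carry ground truth for filter-performance and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
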