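Package: wxlsurvey
Title: Survey of WxL Surface-Protein Gene Clusters in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects WxL and WxLIP domain architectures in annotated
    bacterial genomes, groups the encoding genes into adjacency clusters
    (at most four intervening annotated genes), types the clusters, and
    computes per-protein physicochemical properties (average molecular
    weight, theoretical isoelectric point) and alignment-column
    conservation statistics. Domain evidence comes from HMMER3 domtblout
    tables filtered at E < 1e-10 or from built-in sequence-motif and
    hydropathy scanners. A seeded synthetic-genome generator with a
    ground-truth manifest makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
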