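Package: profda
Title: Differential Abundance Analysis and Visualization of Predicted
    Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of PICRUSt2-style predicted functional
    profiles (KO, EC, MetaCyc and KEGG-pathway abundance tables): reads the
    unstratified prediction table dialect without reformatting, aggregates KO
    abundances into KEGG pathway abundances from a packaged reference
    snapshot, runs a registry of natively implemented differential-abundance
    methods (Welch's t, Kruskal-Wallis, and simplified analogues of ALDEx2,
    LinDA, limma-voom, metagenomeSeq CSS, Maaslin2 and LEfSe) under a single
    tidy output contract, annotates features, compares methods and
    metagenomes, and computes testable data layers for errorbar, PCA and
    heatmap figures. Includes a synthetic spike-in generator with known
    ground truth and an integrated workflow runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
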