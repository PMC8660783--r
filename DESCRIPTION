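Package: panelor
Title: Gene-Panel Case-Control Analysis of Rare Pathogenic Variant Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for population-based case-control studies
    of rare germline variants identified by multi-gene panel sequencing.
    Harmonises variant calls across sequencing platforms (per-platform depth
    and allele-fraction QC, target-region intersection, cohort-level artefact
    and call-rate filters), classifies variants with rule-based pathogenicity
    criteria (ClinVar assertions plus protein-truncating variant rules),
    builds subject-by-gene carrier matrices with auditable exclusion ledgers,
    and estimates per-gene odds ratios by unconditional logistic regression
    with confounder adjustment, including oestrogen-receptor subtype
    analyses, recurrent-variant splits and sensitivity analyses. A
    synthetic-cohort generator emulates a population-based breast cancer
    case-control design with an elderly healthy super-control arm, with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
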