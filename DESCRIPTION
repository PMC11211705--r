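Package: newsfunnel
Title: Rule-Based Media Content Analysis Pipeline for Health Workforce
    Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces large open-source news corpora to topic-coded,
    quantifiable records for health-workforce surveillance. Provides a
    Boolean rule language for per-topic inclusion/exclusion classification
    scoped to title, body or sentence; extractive three-sentence
    summarization with a pluggable sentence scorer; near-duplicate removal
    by word-trigram overlap; gazetteer-based reduction of multi-country
    tags to a single most-relevant country; monthly time clustering; and a
    synthesis layer producing subevent distribution tables, affected-count
    sums, monthly topic series, country coverage and co-occurrence
    matrices. A ground-truthed synthetic corpus generator emulates the
    statistical structure of media-monitoring extracts so that every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
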