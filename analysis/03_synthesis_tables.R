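#!/usr/bin/env Rscript
# Step 3 — synthesis tables from the coded records: subevent distribution
# per impact area (frequency, n (%)), yearly affected-count sums per
# kind, monthly topic series, and per-topic country coverage. Outputs
# under results/tables/.

suppressMessages(library(newsfunnel))
suppressMessages(library(dplyr))

records <- readr::read_csv("results/pipeline/06_records.csv",
                           col_types = readr::cols(
                             affected_count = readr::col_double(),
                             .default = readr::col_character()),
                           progress = FALSE)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

cb <- read_codebook()
label_of <- stats::setNames(cb$label, cb$code)

## subevent distribution per impact area
area <- records %>% filter(theme == "area_of_impact")
dist <- bind_rows(lapply(sort(unique(area$topic_id)), function(tid) {
  tab <- subevent_distribution(area, topic = tid)
  tibble::tibble(topic = tid, subevent = label_of[tab$code],
                 n = tab$n, pct = tab$pct, N = attr(tab, "N"))
}))
readr::write_csv(dist, "results/tables/subevent_distribution.csv",
                 progress = FALSE)
cat("subevent distribution (frequency of reporting, n (%)):\n")
for (tid in unique(dist$topic)) {
  d <- dist[dist$topic == tid, ]
  cat(sprintf("  %s (N=%d)\n", tid, d$N[[1]]))
  cat(sprintf("    %-38s %5d (%.1f)\n", d$subevent, d$n, d$pct), sep = "")
}

## yearly affected sums
aff <- affected_sums(records)
readr::write_csv(aff$table, "results/tables/affected_by_year.csv",
                 progress = FALSE)
cat(sprintf("\naffected health workers by year (%d articles without counts excluded):\n",
            aff$excluded))
print(tidyr::pivot_wider(aff$table, names_from = "year",
                         values_from = "total"))

## monthly topic series and country coverage
months <- month_seq(c("2020-01-01", "2022-06-30"))
ser <- monthly_series(area, months = months)
readr::write_csv(ser, "results/tables/monthly_topic_series.csv",
                 progress = FALSE)
peak <- ser %>% group_by(topic_id) %>% slice_max(n, n = 1, with_ties = FALSE)
cat("\npeak reporting month per topic:\n")
print(as.data.frame(peak))

cover <- tibble::tibble(
  topic = sort(unique(area$topic_id)),
  countries = vapply(sort(unique(area$topic_id)), function(tid)
    country_coverage(records, topic = tid), integer(1)))
readr::write_csv(cover, "results/tables/country_coverage.csv",
                 progress = FALSE)
cat("\ncountries with at least one article per topic:\n")
print(as.data.frame(cover))
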