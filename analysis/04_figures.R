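#!/usr/bin/env Rscript
# Step 4 — figures: monthly topic time series, 100%-stacked monthly
# shares of contributing factors and responses, and code x topic
# co-occurrence heatmaps. PNGs under results/figures/.

suppressMessages(library(newsfunnel))
suppressMessages(library(dplyr))
suppressMessages(library(ggplot2))

records <- readr::read_csv("results/pipeline/06_records.csv",
                           col_types = readr::cols(
                             affected_count = readr::col_double(),
                             .default = readr::col_character()),
                           progress = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
months <- month_seq(c("2020-01-01", "2022-06-30"))
as_date <- function(m) as.Date(paste0(m, "-01"))

area <- records %>% filter(theme == "area_of_impact")
ser <- monthly_series(area, months = months)
p1 <- ggplot(ser, aes(as_date(month), n, colour = topic_id)) +
  geom_line() +
  labs(x = NULL, y = "articles per month", colour = "topic",
       title = "Monthly news volume per impact area") +
  theme_minimal()
ggsave("results/figures/monthly_topic_series.png", p1,
       width = 9, height = 4.5, dpi = 150)

for (th in c("contributing_factor", "response")) {
  sh <- stacked_share_series(records %>% filter(theme == th),
                             months = months)
  p <- ggplot(sh %>% filter(!empty),
              aes(as_date(month), share, fill = code)) +
    geom_area(position = "stack") +
    labs(x = NULL, y = "share of monthly reports", fill = NULL,
         title = sprintf("Monthly composition of %s codes",
                         gsub("_", " ", th))) +
    theme_minimal()
  ggsave(sprintf("results/figures/%s_shares.png", th), p,
         width = 9, height = 4.5, dpi = 150)
}

for (th in c("contributing_factor", "response")) {
  codes <- sort(unique(records$code[records$theme == th]))
  co <- cooccurrence_matrix(
    records %>% filter(theme %in% c("area_of_impact", th)),
    axis_a = codes)
  long <- as.data.frame(as.table(co$matrix))
  names(long) <- c("code", "topic", "n")
  p <- ggplot(long, aes(topic, code, fill = n)) +
    geom_tile() +
    geom_text(aes(label = n), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = NULL, y = NULL,
         title = sprintf("Overlap of %s codes with impact areas",
                         gsub("_", " ", th))) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
  ggsave(sprintf("results/figures/%s_cooccurrence.png", th), p,
         width = 8, height = 5, dpi = 150)
}

cat("figures written under results/figures/\n")
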