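#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study corpus.
#
# Real media-monitoring extracts are not redistributable, so the study
# corpus is generated: 2,000 base articles over January 2020 - June 2022,
# five deductive topics with planted lexicon signals and Gaussian-bump
# prevalence curves, 30% irrelevant background, ~8% syndicated
# near-copies, and multi-country tag noise. Ground truth (labels,
# subevents, countries, duplicate links, affected counts) is written
# alongside the corpus.

suppressMessages(library(newsfunnel))

seed <- 2026L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec <- generation_spec(n_articles = 2000, seed = seed)
gen <- generate_corpus(spec)

write_corpus(gen$corpus, "results/data/corpus.jsonl")
write_ground_truth(gen$truth, "results/data/ground_truth.jsonl")

st <- corpus_stats(gen$corpus)
cat(sprintf("generated %d articles (%d with syndicated copies), %s words, %s pages\n",
            nrow(gen$corpus), sum(!is.na(gen$truth$duplicate_of)),
            format(st$words, big.mark = ","), format(st$pages, big.mark = ",")))
cat(sprintf("background articles: %d; topical: %d\n",
            sum(gen$truth$background), sum(!gen$truth$background)))
print(table(gen$truth$primary_topic[!gen$truth$background]))
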