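test_that("generation spec validates proportions, topics and window", {
  expect_error(generation_spec(background_fraction = 1.2), "proportions")
  expect_error(generation_spec(n_articles = -1), "n_articles")
  expect_error(generation_spec(date_window = c("2021-01-01", "2020-01-01")),
               "window")
  expect_error(generation_spec(topics = list(), background_fraction = 0.5),
               "non-empty")
  # background-only corpora need no topics
  expect_s3_class(generation_spec(topics = list(), background_fraction = 1),
                  "generation_spec")
  expect_error(topic_spec("t", "x", c(-1, 1), c(a = 1)), ">= 0")
  expect_error(topic_spec("t", "x", c(1, 1), c(a = 0.6, b = 0.5)),
               "sum to 1")
})

test_that("identical spec and seed reproduce byte-identical corpora", {
  spec <- generation_spec(n_articles = 80, seed = 55)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(g1$corpus$body, g2$corpus$body)
  expect_identical(g1$corpus$title, g2$corpus$title)
  expect_identical(g1$corpus$country_tags, g2$corpus$country_tags)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_corpus(generation_spec(n_articles = 80, seed = 56))
  expect_false(identical(g1$corpus$body, g3$corpus$body))
  empty <- generate_corpus(generation_spec(n_articles = 0))
  expect_identical(nrow(empty$corpus), 0L)
  expect_identical(nrow(empty$truth), 0L)
})

test_that("degenerate mixtures plant exactly one topic", {
  window <- c("2020-01-01", "2022-06-30")
  one <- default_topics(window)["vaccination"]
  gen <- generate_corpus(generation_spec(
    n_articles = 100, topics = one, background_fraction = 0,
    duplicate_rate = 0, multi_topic_rate = 0, seed = 61))
  expect_identical(nrow(gen$corpus), 100L)
  expect_true(all(vapply(gen$truth$topics, identical, logical(1),
                         "vaccination")))
  expect_false(any(gen$truth$background))
})

test_that("monthly label counts match multinomial moments", {
  spec <- generation_spec(n_articles = 2000, background_fraction = 0,
                          duplicate_rate = 0, seed = 7)
  gen <- generate_corpus(spec)
  truth <- gen$truth
  n <- nrow(truth)
  months <- month_seq(spec$date_window)
  w <- vapply(spec$topics, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  # expected per-month probability, mixing topic weights and curves
  p <- rep(0, length(months))
  for (k in seq_along(spec$topics)) {
    cv <- spec$topics[[k]]$prevalence_curve
    p <- p + w[[k]] * cv / sum(cv)
  }
  obs <- table(factor(truth$month, levels = months))
  z <- (as.integer(obs) - n * p) / sqrt(n * p * (1 - p))
  expect_true(all(abs(z) <= 4))
  expect_gt(mean(abs(z) <= 3), 0.9)
  # per-topic peak months land where planted
  vac <- table(truth$month[truth$primary_topic == "vaccination"])
  expect_identical(names(which.max(vac)), "2021-03")
})

test_that("duplicate injection creates later-dated acyclic copies", {
  gen0 <- generate_corpus(generation_spec(n_articles = 60,
                                          duplicate_rate = 0, seed = 65))
  out <- inject_duplicates(gen0$corpus, gen0$truth, duplicate_rate = 0,
                           mutation_rate = 0.5, seed = 1)
  expect_identical(out$corpus$body, gen0$corpus$body)
  out2 <- inject_duplicates(gen0$corpus, gen0$truth, duplicate_rate = 0.5,
                            mutation_rate = 0, seed = 2)
  dups <- out2$truth[!is.na(out2$truth$duplicate_of), ]
  expect_gt(nrow(dups), 10L)
  for (r in seq_len(nrow(dups))) {
    src_i <- match(dups$duplicate_of[[r]], out2$corpus$article_id)
    cp_i <- match(dups$article_id[[r]], out2$corpus$article_id)
    expect_lte(out2$corpus$published[[src_i]], out2$corpus$published[[cp_i]])
    # links point to originals only: no copy-of-copy chains
    expect_false(dups$duplicate_of[[r]] %in% dups$article_id)
    # verbatim copies share every trigram
    expect_equal(overlap_fraction(
      trigrams(out2$corpus$body[[cp_i]]),
      trigrams(out2$corpus$body[[src_i]])), 1.0)
  }
  expect_error(inject_duplicates(gen0$corpus, gen0$truth, 1.2, 0), "rates")
})

test_that("classification noise degrades precision monotonically", {
  prec <- vapply(c(0, 0.25, 0.6), function(noise) {
    gen <- generate_corpus(generation_spec(
      n_articles = 400, duplicate_rate = 0, lexicon_noise_rate = noise,
      seed = 71))
    cls <- classify_corpus(gen$corpus, default_rules())
    label_metrics(cls$flags, gen$truth,
                  names(default_lexicons()))$precision
  }, numeric(1))
  expect_equal(prec[[1]], 1.0)
  expect_true(all(diff(prec) <= 0))
  expect_lt(prec[[3]], 1.0)
})

test_that("ground truth round-trips through JSON Lines", {
  gen <- generate_corpus(generation_spec(n_articles = 30, seed = 77))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_ground_truth(gen$truth, path)
  back <- read_ground_truth(path)
  expect_identical(back$article_id, gen$truth$article_id)
  expect_identical(back$topics, gen$truth$topics)
  expect_identical(back$subevent, gen$truth$subevent)
  expect_identical(back$affected_count, gen$truth$affected_count)
  expect_identical(back$duplicate_of, gen$truth$duplicate_of)
})

test_that("generation spec loads from a configuration file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_articles: 25", "background_fraction: 0.5",
               "duplicate_rate: 0.0", "seed: 9"), path)
  spec <- read_generation_spec(path)
  expect_identical(spec$n_articles, 25L)
  expect_identical(spec$seed, 9L)
  gen <- generate_corpus(spec)
  expect_identical(nrow(gen$corpus), 25L)
})
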