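test_that("sentence splitting is abbreviation-aware and offset-exact", {
  expect_identical(nrow(split_sentences("")), 0L)
  expect_identical(nrow(split_sentences("No terminal punctuation here")), 1L)
  sp <- split_sentences("A. B. Smith arrived. Strikes began.")
  expect_identical(sp$text, c("A. B. Smith arrived.", "Strikes began."))
  expect_identical(sp$index, 0:1)
  sp2 <- split_sentences("Dr. Lee spoke at 3 p.m. yesterday. Then Mrs. Cho left! Was it over?")
  expect_identical(nrow(sp2), 3L)
  # extractive guarantee: texts are exact substrings at recorded offsets
  gen <- generate_corpus(generation_spec(n_articles = 15, seed = 9))
  for (body in gen$corpus$body) {
    sp <- split_sentences(body)
    expect_identical(substring(body, sp$start, sp$end), sp$text)
    expect_identical(sp$index, seq_len(nrow(sp)) - 1L)
  }
})

test_that("pseudolabels are exactly the rule trigger sentences", {
  rules <- default_rules()
  gen <- generate_corpus(generation_spec(n_articles = 60, seed = 14))
  cls <- classify_corpus(gen$corpus, rules)
  lex <- default_lexicons()
  checked <- 0L
  for (res in cls$results) {
    flagged <- names(which(res$topic_flags))
    if (length(flagged) == 0L) next
    i <- match(res$article_id, gen$corpus$article_id)
    split <- split_sentences(gen$corpus$body[[i]])
    for (tp in flagged) {
      pl <- extract_pseudolabels(res, split, tp)
      expect_identical(pl$sentences, res$triggers[[tp]]$sentences)
      # every pseudolabel sentence contains a term of that topic's lexicon
      for (idx in pl$sentences) {
        toks <- strsplit(tolower(split$text[[idx + 1L]]), "[^a-z0-9]+")[[1]]
        expect_true(any(lex[[tp]] %in% toks))
      }
      checked <- checked + 1L
    }
    expect_error(extract_pseudolabels(
      res, split, setdiff(names(res$topic_flags), flagged)[1]),
      "not flagged")
  }
  expect_gt(checked, 20L)
})

test_that("lexical scores equal the documented formula", {
  body <- paste("Plain opener without signal.",
                "A vaccine and a jab arrived.",
                "Still nothing here.",
                "More filler text follows.",
                "Nothing again at all.")
  split <- split_sentences(body)
  lex <- list(vaccination = c("vaccine", "jab"), other = c("strike"))
  sc <- score_sentences(split, mode = "topic:vaccination", lexicons = lex)
  expect_equal(sc[2], 2 + 1 / 2)     # 2 distinct terms at index 1
  expect_equal(sc[5], 1 / 5)         # bare sentence at index 4 -> 0.2
  expect_equal(sc[1], 1)             # position bonus only, index 0
  # brute-force recomputation over a synthetic article
  gen <- generate_corpus(generation_spec(n_articles = 5, seed = 21))
  b <- gen$corpus$body[[1]]
  sp <- split_sentences(b)
  got <- score_sentences(sp, mode = "global", lexicons = default_lexicons())
  terms <- unique(unlist(default_lexicons(), use.names = FALSE))
  want <- vapply(seq_len(nrow(sp)), function(i) {
    toks <- strsplit(tolower(sp$text[[i]]), "[^a-z0-9]+")[[1]]
    sum(terms %in% toks) + 1 / (1 + sp$index[[i]])
  }, numeric(1))
  expect_equal(got, want)
  expect_error(score_sentences(sp, scorer = "neural-42"), "unknown scorer")
})

test_that("summaries keep at most k sentences with position tie-break", {
  split <- split_sentences("One here. Two here. Three here. Four here.")
  sm <- summarize_article(split, scores = c(1, 1, 1, 1), k = 3)
  expect_identical(sm$index, 0:2)            # ties -> earlier sentences
  expect_identical(sm$rank, 1:3)
  sm2 <- summarize_article(split, scores = c(0, 5, 1, 2), k = 3)
  expect_identical(sm2$index, c(1L, 3L, 2L)) # rank order, not document order
  expect_true(all(diff(sm2$score) <= 0))
  short <- split_sentences("Only one. And two.")
  expect_identical(nrow(summarize_article(short, c(1, 2), k = 3)), 2L)
  expect_error(summarize_article(short, c(1, 2), k = 0), "k must be")
})

test_that("scorer plug-ins change ranks but never the contracts", {
  register_scorer("chaotic", function(split, mode, lexicons) {
    withr::with_seed(17, stats::runif(nrow(split)))
  })
  gen <- generate_corpus(generation_spec(n_articles = 30, seed = 16))
  cls <- classify_corpus(gen$corpus, default_rules())
  for (scorer in c("lexical", "chaotic")) {
    summ <- summarize_corpus(cls$retained, cls, default_lexicons(),
                             scorer = scorer)
    expect_true(all(lengths(summ$indices) <= 3L))
    expect_true(all(lengths(summ$indices) ==
                      pmin(3L, summ$n_sentences)))
    # extractive: every selected sentence is a verbatim substring of the body
    for (r in seq_len(nrow(summ))) {
      body <- gen$corpus$body[[match(summ$article_id[[r]],
                                     gen$corpus$article_id)]]
      sp <- split_sentences(body)
      for (idx in summ$indices[[r]]) {
        expect_true(grepl(sp$text[[idx + 1L]], body, fixed = TRUE))
      }
      expect_true(all(diff(summ$scores[[r]]) <= 0))
    }
  }
})

test_that("topic summaries contain a pseudolabel sentence on synthetic text", {
  gen <- generate_corpus(generation_spec(n_articles = 60, seed = 19))
  cls <- classify_corpus(gen$corpus, default_rules())
  summ <- summarize_corpus(cls$retained, cls, default_lexicons())
  res_by_id <- cls$results
  names(res_by_id) <- vapply(res_by_id, `[[`, character(1), "article_id")
  topic_rows <- summ[grepl("^topic:", summ$mode), ]
  hit <- vapply(seq_len(nrow(topic_rows)), function(r) {
    tp <- sub("^topic:", "", topic_rows$mode[[r]])
    trig <- res_by_id[[topic_rows$article_id[[r]]]]$triggers[[tp]]$sentences
    length(trig) == 0L || length(intersect(topic_rows$indices[[r]], trig)) > 0L
  }, logical(1))
  expect_true(all(hit))
})
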