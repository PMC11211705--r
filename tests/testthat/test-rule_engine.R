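test_that("pattern parser builds the expected trees and round-trips", {
  tree <- parse_pattern('(("vaccine" OR "vaccination") AND NOT "animal")')
  expect_identical(tree$kind, "and")
  expect_identical(tree$children[[1]]$kind, "or")
  expect_identical(tree$children[[1]]$children[[1]],
                   list(kind = "word", term = "vaccine"))
  expect_identical(tree$children[[2]]$kind, "not")
  expect_identical(tree$children[[2]]$children[[1]]$term, "animal")
  # multi-token strings become phrase atoms
  ph <- parse_pattern('"personal protective equipment"')
  expect_identical(ph, list(kind = "phrase",
                            terms = c("personal", "protective", "equipment")))
  # value atoms
  va <- parse_pattern('NUM >= 100 WITHIN 5 OF "nurses"')
  expect_identical(va[c("kind", "cmp", "value", "window")],
                   list(kind = "value", cmp = ">=", value = 100,
                        window = 5L))
  # deparse/parse round trip on a mixed expression
  src <- '("strike" OR "work stoppage") AND NOT (NUM < 10 WITHIN 4 OF "wards")'
  expect_identical(parse_pattern(deparse_pattern(parse_pattern(src))),
                   parse_pattern(src))
})

test_that("syntax errors report a location", {
  expect_error(parse_pattern('("vaccine" OR "jab"'), "column.*\\)")
  expect_error(parse_pattern('"a" AND'), "column")
  expect_error(parse_pattern('vaccine'), "unquoted")
  expect_error(parse_pattern('"a" "b"'), "column")
  expect_error(criterion("paragraph", "include", '"a"'), "unknown scope")
  expect_error(ruleset("t", list(criterion("body", "exclude", '"a"'))),
               "no include")
})

test_that("rule files parse and serialize to equivalent trees", {
  path <- system.file("extdata", "rules_default.yaml", package = "newsfunnel")
  rules <- parse_ruleset(path)
  expect_length(rules, 5L)
  expect_setequal(vapply(rules, `[[`, character(1), "topic"),
                  names(default_lexicons()))
  reparsed <- parse_ruleset(serialize_ruleset(rules))
  for (k in seq_along(rules)) {
    expect_identical(lapply(reparsed[[k]]$criteria, `[[`, "pattern"),
                     lapply(rules[[k]]$criteria, `[[`, "pattern"))
  }
  # the file form and the built-in defaults agree
  builtin <- default_rules()
  for (k in seq_along(builtin)) {
    m <- match(builtin[[k]]$topic, vapply(rules, `[[`, character(1), "topic"))
    expect_identical(lapply(rules[[m]]$criteria, `[[`, "pattern"),
                     lapply(builtin[[k]]$criteria, `[[`, "pattern"))
  }
})

test_that("criterion evaluation honors scope boundaries", {
  art <- list(article_id = "x", title = "Nurses strike over pay",
              body = paste("Wards reported personal protective. Equipment",
                           "arrived late. About 3,500,000 nurses joined."))
  hit <- evaluate_criterion(art, criterion("title", "include", '"strike"'))
  expect_true(hit$matched)
  expect_true(hit$title)
  # phrase straddling two sentences: body scope sees it, sentence scope not
  straddle <- criterion("sentence", "include",
                        '"personal protective equipment"')
  expect_false(evaluate_criterion(art, straddle)$matched)
  expect_true(evaluate_criterion(
    art, criterion("body", "include", '"personal protective equipment"'))$matched)
  # value atom against the brute-force window scan
  va <- criterion("sentence", "include", 'NUM >= 100 WITHIN 5 OF "nurses"')
  got <- evaluate_criterion(art, va)
  expect_true(got$matched)
  expect_identical(got$spans, 2L)   # third sentence, 0-based
  expect_true(brute_criterion(art, va))
  expect_false(evaluate_criterion(
    art, criterion("sentence", "include",
                   'NUM >= 4000000 WITHIN 5 OF "nurses"'))$matched)
})

test_that("classification combines includes by OR and excludes by veto", {
  rules <- list(ruleset("vax", list(
    criterion("body", "include", '"vaccine"'),
    criterion("body", "include", '"jab"'),
    criterion("body", "exclude", '"veterinary"'))))
  art <- function(body) list(article_id = "a", title = "", body = body)
  expect_true(classify_article(art("a new jab arrived"), rules)$topic_flags[["vax"]])
  expect_false(classify_article(
    art("veterinary vaccine for cattle"), rules)$topic_flags[["vax"]])
  res <- classify_article(art("nothing relevant here"), rules)
  expect_false(any(res$topic_flags))
  expect_length(res$triggers$vax$sentences, 0L)
  # trigger sentences are non-empty (or title-marked) for every true flag
  res2 <- classify_article(art("The jab arrived. Rain fell."), rules)
  expect_true(res2$topic_flags[["vax"]])
  expect_identical(res2$triggers$vax$sentences, 0L)
  # require_all_includes flips the combination rule
  expect_false(classify_article(art("a new jab arrived"), rules,
                                require_all_includes = TRUE)$topic_flags[["vax"]])
  expect_true(classify_article(art("the vaccine jab arrived"), rules,
                               require_all_includes = TRUE)$topic_flags[["vax"]])
})

test_that("exclusion dominance holds under fuzzed rule sets", {
  gen <- generate_corpus(generation_spec(n_articles = 30, seed = 8))
  vocab <- fuzz_vocab()
  withr::with_seed(99, {
    for (rep in 1:10) {
      inc <- criterion(sample(c("title", "body", "sentence"), 1),
                       "include", fuzz_pattern(2L, vocab))
      exc <- criterion(sample(c("title", "body", "sentence"), 1),
                       "exclude", fuzz_pattern(2L, vocab))
      rs_without <- list(ruleset("t", list(inc)))
      rs_with <- list(ruleset("t", list(inc, exc)))
      for (i in seq_len(nrow(gen$corpus))) {
        art <- as.list(gen$corpus[i, c("article_id", "title", "body")])
        f1 <- classify_article(art, rs_without)$topic_flags[["t"]]
        f2 <- classify_article(art, rs_with)$topic_flags[["t"]]
        expect_true(f1 || !f2)   # adding an exclude never turns false true
      }
    }
  })
})

test_that("sentence-scope matches imply body-scope matches", {
  # the containment property is about monotone (negation-free) patterns:
  # `NOT x` can hold in one sentence while x occurs elsewhere in the body
  gen <- generate_corpus(generation_spec(n_articles = 25, seed = 12))
  vocab <- fuzz_vocab()
  drop_not <- function(node) {
    if (node$kind == "not") return(drop_not(node$children[[1L]]))
    if (!is.null(node$children)) node$children <- lapply(node$children, drop_not)
    node
  }
  withr::with_seed(5, {
    for (rep in 1:12) {
      pat <- drop_not(fuzz_pattern(2L, vocab))
      sc <- criterion("sentence", "include", pat)
      bc <- criterion("body", "include", pat)
      for (i in seq_len(nrow(gen$corpus))) {
        art <- as.list(gen$corpus[i, c("article_id", "title", "body")])
        if (evaluate_criterion(art, sc)$matched) {
          expect_true(evaluate_criterion(art, bc)$matched)
        }
      }
    }
  })
})

test_that("classifying the retained sub-corpus is a fixed point", {
  gen <- generate_corpus(generation_spec(n_articles = 120, seed = 4))
  rules <- default_rules()
  first <- classify_corpus(gen$corpus, rules)
  again <- classify_corpus(first$retained, rules)
  expect_identical(again$retained$article_id, first$retained$article_id)
  # all-background corpus retains nothing
  bg <- generate_corpus(generation_spec(n_articles = 40,
                                        background_fraction = 1,
                                        duplicate_rate = 0, seed = 4))
  expect_identical(nrow(classify_corpus(bg$corpus, rules)$retained), 0L)
})

test_that("validation sampling is seeded, uniform and size-capped", {
  gen <- generate_corpus(generation_spec(n_articles = 150, seed = 6))
  cls <- classify_corpus(gen$corpus, default_rules())
  s1 <- sample_flagged(cls, "mental_health", n = 20, seed = 42)
  s2 <- sample_flagged(cls, "mental_health", n = 20, seed = 42)
  expect_identical(s1, s2)
  expect_length(unique(s1), 20L)
  expect_error(sample_flagged(cls, "nope", n = 5), "unknown topic")
  flagged <- cls$flags$article_id[cls$flags$mental_health]
  expect_true(all(s1 %in% flagged))
  expect_warning(all_ids <- sample_flagged(cls, "mental_health",
                                           n = length(flagged) + 10),
                 "returning all")
  expect_setequal(all_ids, flagged)
  # selection frequencies match the n/N binomial expectation
  N <- length(flagged)
  n <- 10L
  reps <- 10000L
  tally <- integer(N)
  names(tally) <- flagged
  withr::with_seed(7, {
    for (r in seq_len(reps)) {
      pickd <- sample(flagged, n)
      tally[pickd] <- tally[pickd] + 1L
    }
  })
  p <- n / N
  se <- sqrt(reps * p * (1 - p))
  expect_true(all(abs(tally - reps * p) <= 4 * se))
  expect_true(mean(abs(tally - reps * p) <= 3 * se) > 0.95)
})

test_that("relevance rate reports the percentage over annotations", {
  ann <- stats::setNames(c(rep("relevant", 45), rep("irrelevant", 5)),
                         sprintf("a%02d", 1:50))
  got <- relevance_rate(ann)
  expect_equal(got$rate, 90.0)
  expect_identical(got$n_annotated, 50L)
  expect_equal(relevance_rate(stats::setNames(
    c(rep("relevant", 35), rep("irrelevant", 15)), 1:50))$rate, 70.0)
  expect_equal(relevance_rate(c(a = "irrelevant"))$rate, 0)
  expect_error(relevance_rate(character(0)), "non-empty")
  expect_error(relevance_rate(c(a = "maybe")), "unknown judgment")
})
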