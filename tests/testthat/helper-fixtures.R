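# Shared fixtures and independent oracles. Expensive synthetic corpora
# are generated once per test run and cached here.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# the default synthetic study profile used by several suites
default_gen <- function() {
  cached("default_gen", generate_corpus(
    generation_spec(n_articles = 2000, seed = 101)))
}

# one full pipeline run on the default study profile, shared by the
# recovery and contract suites
default_run <- function() {
  cached("default_run", run_pipeline(run_config(
    spec = generation_spec(n_articles = 2000, seed = 101), seed = 101)))
}

# a small classified-and-coded run shared across aggregation tests
coding_run <- function() {
  cached("coding_run", {
    gen <- generate_corpus(generation_spec(n_articles = 250,
                                           duplicate_rate = 0, seed = 43))
    cls <- classify_corpus(gen$corpus, default_rules())
    summ <- summarize_corpus(cls$retained, cls, default_lexicons())
    codes <- apply_codebook(summ, read_codebook())
    list(gen = gen, codes = codes)
  })
}

tiny_articles <- function() {
  tibble::tibble(
    article_id = c("a3", "a1", "a2"),
    title = c("Nurses strike over pay", "Vaccine drive begins",
              "Quiet week in sport"),
    body = c("Hundreds of nurses walked out. The union demanded talks.",
             "The vaccine rollout reached rural clinics. Uptake was strong.",
             "The local team rested. Training resumes on Monday."),
    published = as.Date(c("2020-03-05", "2020-02-01", "2020-02-15")),
    source = "outlet-x",
    country_tags = list("GB", c("IN", "US"), character(0)),
    language = "en")
}

tiny_corpus <- function() news_corpus(tiny_articles())

# --- independent brute-force pattern evaluator -------------------------
# same matching contract, written with explicit enumeration rather than
# the engine's vectorized machinery
brute_tokens <- function(text) {
  raw <- unlist(strsplit(tolower(text), "[[:space:]]+"))
  raw <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw)
  raw[nzchar(raw)]
}

brute_eval <- function(node, tokens) {
  if (node$kind == "word") {
    return(any(tokens == node$term))
  }
  if (node$kind == "phrase") {
    np <- length(node$terms)
    if (length(tokens) < np) return(FALSE)
    for (s in 1:(length(tokens) - np + 1L)) {
      if (all(tokens[s:(s + np - 1L)] == node$terms)) return(TRUE)
    }
    return(FALSE)
  }
  if (node$kind == "value") {
    numeric_tok <- grepl("^[0-9][0-9,.]*$", tokens)
    vals <- suppressWarnings(as.numeric(gsub(",", "", tokens)))
    cmp <- switch(node$cmp, ">=" = `>=`, "<=" = `<=`, ">" = `>`,
                  "<" = `<`, "==" = `==`)
    np <- length(node$terms)
    if (length(tokens) < np) return(FALSE)
    for (s in 1:(length(tokens) - np + 1L)) {
      if (!all(tokens[s:(s + np - 1L)] == node$terms)) next
      span <- s:(s + np - 1L)
      for (p in seq_along(tokens)) {
        if (!numeric_tok[[p]] || is.na(vals[[p]])) next
        if (!cmp(vals[[p]], node$value)) next
        for (q in span) {
          if (abs(p - q) <= node$window) return(TRUE)
        }
      }
    }
    return(FALSE)
  }
  if (node$kind == "not") return(!brute_eval(node$children[[1L]], tokens))
  if (node$kind == "and") {
    for (ch in node$children) if (!brute_eval(ch, tokens)) return(FALSE)
    return(TRUE)
  }
  if (node$kind == "or") {
    for (ch in node$children) if (brute_eval(ch, tokens)) return(TRUE)
    return(FALSE)
  }
  stop("unknown node kind")
}

brute_criterion <- function(article, crit) {
  if (crit$scope == "title") {
    return(brute_eval(crit$pattern, brute_tokens(article$title)))
  }
  if (crit$scope == "body") {
    return(brute_eval(crit$pattern, brute_tokens(article$body)))
  }
  sents <- split_sentences(article$body)$text
  for (s in sents) {
    if (brute_eval(crit$pattern, brute_tokens(s))) return(TRUE)
  }
  FALSE
}

# random expression trees over a mixed vocabulary, for fuzzing
fuzz_pattern <- function(depth = 2L, vocab) {
  if (depth == 0L || stats::runif(1) < 0.4) {
    r <- stats::runif(1)
    if (r < 0.55) {
      return(list(kind = "word", term = sample(vocab, 1L)))
    }
    if (r < 0.85) {
      return(list(kind = "phrase", terms = sample(vocab, 2L)))
    }
    return(list(kind = "value",
                cmp = sample(c(">=", ">", "<=", "<"), 1L),
                value = sample(c(5, 100, 5000), 1L),
                window = sample(3:8, 1L),
                terms = sample(vocab, 1L)))
  }
  op <- sample(c("and", "or", "not"), 1L)
  if (op == "not") {
    return(list(kind = "not",
                children = list(fuzz_pattern(depth - 1L, vocab))))
  }
  list(kind = op, children = lapply(seq_len(sample(2:3, 1L)),
                                    function(i) fuzz_pattern(depth - 1L, vocab)))
}

fuzz_vocab <- function() {
  c(unlist(default_lexicons(), use.names = FALSE),
    "nurses", "doctors", "hospital", "clinic", "tourism", "football",
    "conditions", "pressures", "the", "wages", "hazard")
}

# --- independent quadratic dedup oracle --------------------------------
brute_trigrams <- function(body) {
  toks <- brute_tokens(body)
  if (length(toks) < 3L) return(character(0))
  out <- character(0)
  for (s in 1:(length(toks) - 2L)) {
    out <- c(out, paste(toks[s], toks[s + 1L], toks[s + 2L]))
  }
  unique(out)
}

brute_dedup <- function(corpus, threshold = 0.30) {
  sh <- lapply(corpus$body, brute_trigrams)
  kept <- integer(0)
  removed <- character(0)
  kept_of <- character(0)
  for (i in seq_len(nrow(corpus))) {
    hit <- NA_integer_
    for (j in kept) {
      if (length(sh[[i]]) == 0L) break
      ov <- length(intersect(sh[[i]], sh[[j]])) / length(sh[[i]])
      if (ov >= threshold) { hit <- j; break }   # kept is in corpus order
    }
    if (is.na(hit)) {
      kept <- c(kept, i)
    } else {
      removed <- c(removed, corpus$article_id[[i]])
      kept_of <- c(kept_of, corpus$article_id[[hit]])
    }
  }
  list(kept_ids = corpus$article_id[kept], removed_ids = removed,
       kept_of = kept_of)
}

# precision/recall of predicted topic flags against generator truth
label_metrics <- function(flags, truth, topics) {
  tp <- fp <- fn <- 0L
  truth_topics <- truth$topics[match(flags$article_id, truth$article_id)]
  for (i in seq_len(nrow(flags))) {
    pred <- topics[unlist(flags[i, topics])]
    true <- truth_topics[[i]]
    tp <- tp + length(intersect(pred, true))
    fp <- fp + length(setdiff(pred, true))
    fn <- fn + length(setdiff(true, pred))
  }
  list(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0L) 1 else tp / (tp + fn))
}
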