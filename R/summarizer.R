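# Extractive summarization: every retained article is reduced to at most
# three verbatim sentences per mode (global, or focused on one topic).
# Sentence scoring is a pluggable interface; the shipped reference scorer
# is deterministic and lexical (distinct lexicon-term count plus a
# lead-position bonus). Neural scorers can be registered behind the same
# interface without changing the k / tie-break / extractive contracts.

# Abbreviations that do not end a sentence (matched case-insensitively
# against the token preceding the period, sans trailing period).
nf_abbreviations <- c(
  "mr", "mrs", "ms", "dr", "prof", "st", "vs", "etc", "e.g", "i.e", "no",
  "jr", "sr", "gen", "col", "lt", "gov", "sen", "rep", "hon", "fig", "al",
  "jan", "feb", "mar", "apr", "jun", "jul", "aug", "sep", "sept", "oct",
  "nov", "dec", "u.s", "u.k", "a.m", "p.m")

#' Split a body text into sentences
#'
#' Deterministic rule-based splitting on terminal punctuation (`.`, `!`,
#' `?`) followed by whitespace and an upper-case letter, digit or opening
#' quote, guarded by a fixed abbreviation list and a single-initial guard
#' (so `"A. B. Smith arrived."` stays one sentence). Sentence texts are
#' exact substrings of the body: `substr(body, start, end)` reproduces each
#' `text` (the extractive guarantee rests on this).
#'
#' @param body character scalar.
#' @return tibble with `index` (0-based, contiguous), `text`, `start`,
#'   `end` (1-based character offsets). Zero rows for an empty body.
#' @export
split_sentences <- function(body) {
  empty <- tibble::tibble(index = integer(0), text = character(0),
                          start = integer(0), end = integer(0))
  if (is.null(body) || is.na(body) || !nzchar(trimws(body))) {
    return(empty)
  }
  m <- gregexpr("[.!?]+[\"')\\]]*[[:space:]]+", body, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1L] != -1L) {
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      pos <- m[[j]]
      punct_end <- pos + lens[[j]] - 1L
      # token immediately preceding the terminal punctuation
      prefix <- substr(body, max(1L, pos - 40L), pos - 1L)
      prev <- sub(".*[[:space:](]", "", prefix)
      prev_clean <- tolower(sub("\\.$", "", prev))
      nxt <- substr(body, punct_end + 1L, punct_end + 1L)
      is_abbrev <- prev_clean %in% nf_abbreviations ||
        grepl("^[A-Z]$", prev)
      opens_sentence <- grepl("^[A-Z0-9\"'(]", nxt) || nxt == ""
      if (!is_abbrev && opens_sentence) {
        # sentence ends at the last punctuation/quote char, before the gap
        gap <- regexpr("[[:space:]]", substr(body, pos, punct_end))[[1]]
        breaks <- c(breaks, pos + gap - 2L)
      }
    }
  }
  bounds <- unique(c(breaks, nchar(body)))
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  s_out <- e_out <- integer(length(bounds))
  keep <- logical(length(bounds))
  for (j in seq_along(bounds)) {
    s <- starts[[j]]
    e <- bounds[[j]]
    # advance past inter-sentence whitespace without losing offsets
    while (s <= e && grepl("^[[:space:]]$", substr(body, s, s))) s <- s + 1L
    while (e >= s && grepl("^[[:space:]]$", substr(body, e, e))) e <- e - 1L
    if (s > e) next
    s_out[[j]] <- s
    e_out[[j]] <- e
    keep[[j]] <- TRUE
  }
  if (!any(keep)) return(empty)
  s_out <- s_out[keep]
  e_out <- e_out[keep]
  tibble::tibble(index = seq_along(s_out) - 1L,
                 text = substring(body, s_out, e_out),
                 start = s_out, end = e_out)
}

#' Extract pseudolabel sentences for a topic
#'
#' Pseudolabels are the sentences whose rule match caused the article's
#' inclusion under a topic; they are the weak supervision a trainable
#' scorer would consume. Title-scope matches carry no sentence index: they
#' yield an empty sentence set plus a title marker.
#'
#' @param result an `nf_classification` from [classify_article()].
#' @param split the article's [split_sentences()] result.
#' @param topic topic id with a true flag in `result`.
#' @return list with `article_id`, `topic_id`, `sentences` (0-based
#'   indices, subset of the split's indices) and `title_match` (logical).
#' @export
extract_pseudolabels <- function(result, split, topic) {
  if (!topic %in% names(result$topic_flags)) {
    stop("unknown topic: ", topic, call. = FALSE)
  }
  if (!isTRUE(result$topic_flags[[topic]])) {
    stop("article ", result$article_id, " is not flagged for topic `",
         topic, "`", call. = FALSE)
  }
  trig <- result$triggers[[topic]]
  sentences <- intersect(trig$sentences, split$index)
  list(article_id = result$article_id, topic_id = topic,
       sentences = sentences, title_match = isTRUE(trig$title))
}

## ---- pluggable scorer registry ----------------------------------------

nf_scorer_registry <- new.env(parent = emptyenv())

#' Register a sentence scorer
#'
#' A scorer is `function(split, mode, lexicons)` returning one numeric
#' score per sentence (same order as `split`). Higher is better; ranking
#' and the k/tie/extractive contracts are enforced outside the scorer.
#' @param name scorer name.
#' @param fun scorer function.
#' @export
register_scorer <- function(name, fun) {
  assign(name, fun, envir = nf_scorer_registry)
  invisible(name)
}

lexical_scorer <- function(split, mode, lexicons) {
  if (identical(mode, "global")) {
    terms <- unique(unlist(lexicons, use.names = FALSE))
  } else {
    topic <- sub("^topic:", "", mode)
    if (!topic %in% names(lexicons)) {
      stop("no lexicon for topic `", topic, "`", call. = FALSE)
    }
    terms <- unique(lexicons[[topic]])
  }
  term_tokens <- lapply(terms, nf_tokens)
  vapply(seq_len(nrow(split)), function(i) {
    toks <- nf_tokens(split$text[[i]])
    hits <- sum(vapply(term_tokens, function(tt) {
      length(tt) > 0L && nf_has_phrase(toks, tt)
    }, logical(1)))
    hits + 1 / (1 + split$index[[i]])
  }, numeric(1))
}

register_scorer("lexical", lexical_scorer)

#' Score sentences for summarization
#'
#' The reference `"lexical"` scorer gives each sentence the count of
#' distinct lexicon terms it contains plus a position bonus of
#' `1 / (1 + index)` (0-based index), i.e. a bare lead sentence scores 1
#' and a sentence at index 4 with no lexicon term scores 0.2. In
#' `"global"` mode the union of all topic lexicons is used; in
#' `"topic:<id>"` mode only that topic's lexicon.
#'
#' @param split a [split_sentences()] result.
#' @param mode `"global"` or `"topic:<topic_id>"`.
#' @param lexicons named list: topic id -> character vector of terms
#'   (single words or space-separated phrases).
#' @param scorer registered scorer name (default `"lexical"`).
#' @return numeric vector of scores, one per sentence.
#' @export
score_sentences <- function(split, mode = "global", lexicons = list(),
                            scorer = "lexical") {
  if (!exists(scorer, envir = nf_scorer_registry, inherits = FALSE)) {
    stop("configuration error: unknown scorer `", scorer, "`",
         call. = FALSE)
  }
  fun <- get(scorer, envir = nf_scorer_registry)
  scores <- fun(split, mode, lexicons)
  if (length(scores) != nrow(split)) {
    stop("scorer `", scorer, "` returned ", length(scores),
         " scores for ", nrow(split), " sentences", call. = FALSE)
  }
  as.numeric(scores)
}

#' Select the top-k sentences as the article summary
#'
#' Sentences are ranked by score, ties broken by earlier document position
#' (the inverted-pyramid prior of news writing); the first `k` are the
#' summary, in rank order. Articles with fewer than `k` sentences return
#' all of them.
#'
#' @param split a [split_sentences()] result.
#' @param scores numeric scores from [score_sentences()].
#' @param k maximum sentences to keep (default 3).
#' @param article_id,mode optional metadata carried on the result.
#' @return tibble with `rank`, `index`, `score`, `text` (rank order);
#'   attributes `article_id` and `mode`.
#' @export
summarize_article <- function(split, scores, k = 3L, article_id = NULL,
                              mode = "global") {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  stopifnot(length(scores) == nrow(split))
  ord <- order(-scores, split$index)
  take <- utils::head(ord, k)
  out <- tibble::tibble(rank = seq_along(take),
                        index = split$index[take],
                        score = scores[take],
                        text = split$text[take])
  attr(out, "article_id") <- article_id
  attr(out, "mode") <- mode
  out
}

#' Summarize every retained article of a classified corpus
#'
#' Emits one global-mode summary per article plus one topic-focused
#' summary per true topic flag, side by side. The title is carried on
#' every row (it is always prepended for human review; title-scope rule
#' matches have no sentence to point at).
#'
#' @param corpus retained [news_corpus()].
#' @param classification output of [classify_corpus()] for `corpus` (or a
#'   superset; matched by article id).
#' @param lexicons named list of topic lexicons for the scorer.
#' @param scorer registered scorer name.
#' @param k sentences per summary.
#' @return tibble: `article_id`, `mode`, `title`, `indices` (list of
#'   0-based sentence indices in rank order), `scores` (list), `text`
#'   (summary sentences joined by a space), `n_sentences` (of the source
#'   article).
#' @export
summarize_corpus <- function(corpus, classification, lexicons,
                             scorer = "lexical", k = 3L) {
  empty <- tibble::tibble(article_id = character(0), mode = character(0),
                          title = character(0), indices = list(),
                          scores = list(), text = character(0),
                          n_sentences = integer(0))
  if (nrow(corpus) == 0L) return(empty)
  res_by_id <- classification$results
  names(res_by_id) <- vapply(res_by_id, `[[`, character(1), "article_id")
  rows <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    id <- corpus$article_id[[i]]
    split <- split_sentences(corpus$body[[i]])
    res <- res_by_id[[id]]
    modes <- "global"
    if (!is.null(res)) {
      modes <- c(modes, paste0("topic:", names(which(res$topic_flags))))
    }
    rows[[i]] <- dplyr::bind_rows(lapply(modes, function(md) {
      if (nrow(split) == 0L) {
        return(tibble::tibble(article_id = id, mode = md,
                              title = corpus$title[[i]], indices = list(integer(0)),
                              scores = list(numeric(0)), text = "",
                              n_sentences = 0L))
      }
      sc <- score_sentences(split, mode = md, lexicons = lexicons,
                            scorer = scorer)
      sel <- summarize_article(split, sc, k = k, article_id = id, mode = md)
      tibble::tibble(article_id = id, mode = md, title = corpus$title[[i]],
                     indices = list(sel$index), scores = list(sel$score),
                     text = paste(sel$text, collapse = " "),
                     n_sentences = nrow(split))
    }))
  }
  dplyr::bind_rows(rows)
}
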