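# Rule engine: a small Boolean query language for semiautomated topic
# classification. Rules are per-topic ordered criteria; each criterion has a
# scope (title / body / sentence), a polarity (include / exclude) and a
# pattern — an expression tree over word, phrase and numeric-proximity
# ("value") atoms. Topic membership = at least one include criterion
# matches AND no exclude criterion matches (exclusion veto).
#
# Pattern grammar (EBNF):
#   expr    = or ;
#   or      = and , { "OR" , and } ;
#   and     = unary , { "AND" , unary } ;
#   unary   = "NOT" , unary | primary ;
#   primary = "(" , expr , ")" | atom ;
#   atom    = STRING                                  (* word or phrase *)
#           | "NUM" , cmp , NUMBER , "WITHIN" , NUMBER , "OF" , STRING ;
#   cmp     = ">=" | "<=" | ">" | "<" | "=" | "==" ;
# STRING is a double- or single-quoted literal; one normalized token makes
# a word atom, several make a phrase atom. A value atom is true when a
# numeric token satisfying the comparison occurs within the given token
# window of the quoted term. Matching is case-folded, edge-punctuation
# stripped, whole-token; no stemming.

## ---- pattern lexer / parser -------------------------------------------

lex_pattern <- function(src) {
  chars <- strsplit(src, "")[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, col) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, col = col)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    if (ch == "\"" || ch == "'") {
      close <- ch
      j <- i + 1L
      while (j <= n && chars[[j]] != close) j <- j + 1L
      if (j > n) {
        stop(sprintf("syntax error at column %d: unterminated string", i),
             call. = FALSE)
      }
      push("STRING", paste(chars[seq.int(i + 1L, length.out = j - i - 1L)],
                           collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch %in% c("<", ">", "=")) {
      op <- ch
      if (i < n && chars[[i + 1L]] == "=") {
        op <- paste0(ch, "=")
        i <- i + 1L
      }
      push("CMP", if (op == "=") "==" else op, i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(src, i, nchar(src)),
                    regexpr("^[^[:space:]()\"']+", substr(src, i, nchar(src))))
    word <- m[[1]]
    up <- toupper(word)
    col <- i
    i <- i + nchar(word)
    if (up %in% c("AND", "OR", "NOT", "NUM", "WITHIN", "OF")) {
      push(up, up, col)
    } else if (grepl("^[0-9][0-9,]*\\.?[0-9]*$", word)) {
      push("NUMBER", as.numeric(gsub(",", "", word)), col)
    } else {
      stop(sprintf(
        "syntax error at column %d: unquoted token `%s` (quote terms)",
        col, word), call. = FALSE)
    }
  }
  push("EOF", "", n + 1L)
  toks
}

#' Parse a rule pattern expression
#'
#' Parses one Boolean pattern in the rule grammar (see the package source
#' header of `rule_engine.R` for the EBNF) into an expression tree of
#' `and`/`or`/`not` nodes over `word`, `phrase` and `value` atoms.
#'
#' @param src pattern string, e.g.
#'   `'("vaccine" OR "vaccination") AND NOT "veterinary"'` or
#'   `'NUM >= 100 WITHIN 5 OF "nurses"'`.
#' @return an expression-tree list (`kind` plus node fields).
#' @export
parse_pattern <- function(src) {
  toks <- lex_pattern(src)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }
  expect <- function(type, what) {
    t <- peek()
    if (t$type != type) {
      stop(sprintf("syntax error at column %d: expected %s", t$col, what),
           call. = FALSE)
    }
    advance()
  }
  parse_or <- function() {
    children <- list(parse_and())
    while (peek()$type == "OR") {
      advance()
      children[[length(children) + 1L]] <- parse_and()
    }
    if (length(children) == 1L) children[[1L]] else
      list(kind = "or", children = children)
  }
  parse_and <- function() {
    children <- list(parse_unary())
    while (peek()$type == "AND") {
      advance()
      children[[length(children) + 1L]] <- parse_unary()
    }
    if (length(children) == 1L) children[[1L]] else
      list(kind = "and", children = children)
  }
  parse_unary <- function() {
    if (peek()$type == "NOT") {
      advance()
      return(list(kind = "not", children = list(parse_unary())))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "LPAREN") {
      advance()
      node <- parse_or()
      expect("RPAREN", "')'")
      return(node)
    }
    if (t$type == "STRING") {
      advance()
      terms <- nf_tokens(t$value)
      if (length(terms) == 0L) {
        stop(sprintf("syntax error at column %d: empty string atom", t$col),
             call. = FALSE)
      }
      if (length(terms) == 1L) {
        return(list(kind = "word", term = terms))
      }
      return(list(kind = "phrase", terms = terms))
    }
    if (t$type == "NUM") {
      advance()
      cmp <- expect("CMP", "a comparator after NUM")
      num <- expect("NUMBER", "a number")
      expect("WITHIN", "WITHIN")
      win <- expect("NUMBER", "a window size")
      expect("OF", "OF")
      term <- expect("STRING", "a quoted term")
      terms <- nf_tokens(term$value)
      if (length(terms) == 0L) {
        stop(sprintf("syntax error at column %d: empty value-atom term",
                     term$col), call. = FALSE)
      }
      return(list(kind = "value", cmp = cmp$value, value = num$value,
                  window = as.integer(win$value), terms = terms))
    }
    stop(sprintf("syntax error at column %d: unexpected `%s`", t$col,
                 if (t$type == "EOF") "end of pattern" else t$value),
         call. = FALSE)
  }
  node <- parse_or()
  t <- peek()
  if (t$type != "EOF") {
    stop(sprintf("syntax error at column %d: unexpected `%s`", t$col, t$value),
         call. = FALSE)
  }
  node
}

#' Serialize an expression tree back to pattern text
#'
#' `parse_pattern(deparse_pattern(x))` reproduces an equivalent tree
#' (round-trip contract).
#' @param node expression tree from [parse_pattern()].
#' @return pattern string.
#' @export
deparse_pattern <- function(node) {
  wrap <- function(child) {
    if (child$kind %in% c("and", "or")) {
      paste0("(", deparse_pattern(child), ")")
    } else {
      deparse_pattern(child)
    }
  }
  switch(node$kind,
    word = sprintf('"%s"', node$term),
    phrase = sprintf('"%s"', paste(node$terms, collapse = " ")),
    value = sprintf('NUM %s %s WITHIN %d OF "%s"', node$cmp,
                    format(node$value, scientific = FALSE),
                    node$window, paste(node$terms, collapse = " ")),
    not = paste0("NOT ", wrap(node$children[[1L]])),
    and = paste(vapply(node$children, wrap, character(1)), collapse = " AND "),
    or = paste(vapply(node$children, wrap, character(1)), collapse = " OR "),
    stop("unknown node kind: ", node$kind))
}

eval_pattern <- function(node, tokens, values = NULL) {
  switch(node$kind,
    word = node$term %in% tokens,
    phrase = nf_has_phrase(tokens, node$terms),
    value = eval_value_atom(node, tokens, values),
    not = !eval_pattern(node$children[[1L]], tokens, values),
    and = all(vapply(node$children, eval_pattern, logical(1),
                     tokens = tokens, values = values)),
    or = any(vapply(node$children, eval_pattern, logical(1),
                    tokens = tokens, values = values)),
    stop("unknown node kind: ", node$kind))
}

eval_value_atom <- function(node, tokens, values = NULL) {
  if (length(tokens) == 0L) return(FALSE)
  if (is.null(values)) values <- nf_token_values(tokens)
  cmp_fun <- switch(node$cmp, ">=" = `>=`, "<=" = `<=`, ">" = `>`,
                    "<" = `<`, "==" = `==`)
  np <- which(!is.na(values) & cmp_fun(values, node$value))
  if (length(np) == 0L) return(FALSE)
  starts <- nf_phrase_positions(tokens, node$terms)
  if (length(starts) == 0L) return(FALSE)
  tp <- unique(unlist(lapply(starts, function(s)
    seq.int(s, s + length(node$terms) - 1L))))
  any(vapply(np, function(p) any(abs(tp - p) <= node$window), logical(1)))
}

pattern_atoms <- function(node, negated = FALSE) {
  if (node$kind %in% c("word", "phrase", "value")) {
    return(list(list(node = node, negated = negated)))
  }
  if (node$kind == "not") {
    return(pattern_atoms(node$children[[1L]], !negated))
  }
  unlist(lapply(node$children, pattern_atoms, negated = negated),
         recursive = FALSE)
}

## ---- criteria and rule sets -------------------------------------------

#' Construct a classification criterion
#'
#' @param scope one of `"title"`, `"body"`, `"sentence"`.
#' @param polarity `"include"` or `"exclude"`.
#' @param pattern pattern string (parsed with [parse_pattern()]) or an
#'   already-parsed expression tree.
#' @return an `nf_criterion`.
#' @export
criterion <- function(scope, polarity, pattern) {
  if (!scope %in% c("title", "body", "sentence")) {
    stop("unknown scope: ", scope, call. = FALSE)
  }
  if (!polarity %in% c("include", "exclude")) {
    stop("unknown polarity: ", polarity, call. = FALSE)
  }
  tree <- if (is.character(pattern)) parse_pattern(pattern) else pattern
  structure(list(scope = scope, polarity = polarity, pattern = tree,
                 pattern_src = deparse_pattern(tree)),
            class = "nf_criterion")
}

#' Construct a per-topic rule set
#'
#' @param topic topic id string.
#' @param criteria list of [criterion()] objects, evaluated in order; at
#'   least one must be an include criterion.
#' @return an `nf_ruleset`.
#' @export
ruleset <- function(topic, criteria) {
  pol <- vapply(criteria, function(x) x$polarity, character(1))
  if (!any(pol == "include")) {
    stop("ruleset for topic `", topic, "` has no include criterion",
         call. = FALSE)
  }
  structure(list(topic = topic, criteria = criteria), class = "nf_ruleset")
}

#' Read rule sets from a YAML or JSON configuration file
#'
#' File layout: a top-level `topics` list, each entry with `topic` and
#' `criteria` (each criterion: `scope`, `polarity`, `pattern`).
#' @param path rule file path, or an already-loaded list in the same shape.
#' @return list of [ruleset()] objects.
#' @export
parse_ruleset <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("no such rule file: ", path, call. = FALSE)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  } else {
    path
  }
  if (is.null(cfg$topics)) {
    stop("rule file must have a top-level `topics` list", call. = FALSE)
  }
  lapply(cfg$topics, function(tp) {
    if (is.null(tp$topic)) stop("rule set missing `topic` id", call. = FALSE)
    crits <- lapply(tp$criteria, function(cr) {
      criterion(scope = cr$scope %||% "body",
                polarity = cr$polarity %||% "include",
                pattern = cr$pattern)
    })
    ruleset(tp$topic, crits)
  })
}

#' Serialize rule sets to the configuration-list shape
#'
#' The result can be written with `yaml::write_yaml()` and read back by
#' [parse_ruleset()]; patterns round-trip to equivalent trees.
#' @param rulesets list of [ruleset()] objects.
#' @return plain list.
#' @export
serialize_ruleset <- function(rulesets) {
  list(topics = lapply(rulesets, function(rs) {
    list(topic = rs$topic,
         criteria = lapply(rs$criteria, function(cr) {
           list(scope = cr$scope, polarity = cr$polarity,
                pattern = cr$pattern_src)
         }))
  }))
}

## ---- evaluation over articles -----------------------------------------

# tokenized view of one article, computed once and reused across criteria
article_view <- function(title, body, split = NULL, need_values = TRUE) {
  if (is.null(split)) split <- split_sentences(body)
  sent_tokens <- lapply(split$text, nf_tokens)
  v <- list(
    title_tokens = nf_tokens(title),
    body_tokens = nf_tokens(body),
    split = split,
    sent_tokens = sent_tokens)
  if (need_values) {
    v$title_values <- nf_token_values(v$title_tokens)
    v$body_values <- nf_token_values(v$body_tokens)
    v$sent_values <- lapply(sent_tokens, nf_token_values)
  }
  v
}

criterion_match <- function(view, crit) {
  node <- crit$pattern
  if (crit$scope == "title") {
    m <- eval_pattern(node, view$title_tokens, view$title_values)
    return(list(matched = m, spans = integer(0), title = m))
  }
  if (crit$scope == "sentence") {
    hits <- which(vapply(seq_along(view$sent_tokens), function(i) {
      eval_pattern(node, view$sent_tokens[[i]],
                   if (!is.null(view$sent_values)) view$sent_values[[i]])
    }, logical(1)))
    return(list(matched = length(hits) > 0L,
                spans = view$split$index[hits], title = FALSE))
  }
  # body scope: decide on the full body token stream; attribute the match
  # to sentences that individually satisfy the expression, falling back to
  # sentences containing any non-negated atom (covers cross-sentence
  # phrase/value matches).
  m <- eval_pattern(node, view$body_tokens, view$body_values)
  spans <- integer(0)
  if (m) {
    hits <- which(vapply(seq_along(view$sent_tokens), function(i) {
      eval_pattern(node, view$sent_tokens[[i]],
                   if (!is.null(view$sent_values)) view$sent_values[[i]])
    }, logical(1)))
    if (length(hits) == 0L) {
      atoms <- pattern_atoms(node)
      pos_atoms <- lapply(Filter(function(a) !a$negated, atoms), `[[`, "node")
      hits <- which(vapply(view$sent_tokens, function(toks) {
        any(vapply(pos_atoms, function(a) {
          switch(a$kind,
                 word = a$term %in% toks,
                 phrase = nf_has_phrase(toks, a$terms),
                 value = eval_value_atom(a, toks))
        }, logical(1)))
      }, logical(1)))
    }
    spans <- view$split$index[hits]
  }
  list(matched = m, spans = spans, title = FALSE)
}

#' Evaluate one criterion against one article
#'
#' @param article list (or one-row data frame) with `title` and `body`.
#' @param crit a [criterion()].
#' @param split optional precomputed [split_sentences()] of the body.
#' @return list with `matched` (logical), `spans` (0-based indices of the
#'   matched sentences; empty for title scope) and `title` (logical, `TRUE`
#'   when the match is in the title).
#' @export
evaluate_criterion <- function(article, crit, split = NULL) {
  view <- article_view(article$title, article$body, split = split)
  criterion_match(view, crit)
}

#' Classify one article against a list of rule sets
#'
#' A topic flag is true iff at least one of its include criteria matches
#' (OR combination by default) and no exclude criterion matches (exclusion
#' veto). Trigger sentences — the pseudolabel source for summarizer
#' training — accumulate from include matches only.
#'
#' @param article list or one-row data frame with `article_id`, `title`,
#'   `body`.
#' @param rulesets list of [ruleset()] objects.
#' @param split optional precomputed sentence split.
#' @param require_all_includes when `TRUE`, all include criteria must match
#'   (AND combination).
#' @return an `nf_classification`: list with `article_id`, `topic_flags`
#'   (named logical) and `triggers` (per topic: `sentences`, 0-based
#'   indices, and `title`, logical title-match marker).
#' @export
classify_article <- function(article, rulesets, split = NULL,
                             require_all_includes = FALSE) {
  need_values <- any(vapply(rulesets, function(rs) {
    any(vapply(rs$criteria, function(cr) {
      any(vapply(pattern_atoms(cr$pattern),
                 function(a) a$node$kind == "value", logical(1)))
    }, logical(1)))
  }, logical(1)))
  view <- article_view(article$title, article$body, split = split,
                       need_values = need_values)
  classify_view(article$article_id, view, rulesets,
                require_all_includes = require_all_includes)
}

classify_view <- function(article_id, view, rulesets,
                          require_all_includes = FALSE) {
  flags <- logical(length(rulesets))
  names(flags) <- vapply(rulesets, `[[`, character(1), "topic")
  triggers <- stats::setNames(vector("list", length(rulesets)), names(flags))
  for (k in seq_along(rulesets)) {
    rs <- rulesets[[k]]
    inc_matched <- logical(0)
    sent <- integer(0)
    title_hit <- FALSE
    vetoed <- FALSE
    for (cr in rs$criteria) {
      res <- criterion_match(view, cr)
      if (cr$polarity == "exclude") {
        if (res$matched) vetoed <- TRUE
      } else {
        inc_matched <- c(inc_matched, res$matched)
        if (res$matched) {
          sent <- union(sent, res$spans)
          title_hit <- title_hit || res$title
        }
      }
    }
    ok <- if (require_all_includes) length(inc_matched) > 0L && all(inc_matched)
          else any(inc_matched)
    flags[[k]] <- ok && !vetoed
    triggers[[k]] <- if (flags[[k]]) {
      list(sentences = sort(sent), title = title_hit)
    } else {
      list(sentences = integer(0), title = FALSE)
    }
  }
  structure(list(article_id = article_id, topic_flags = flags,
                 triggers = triggers), class = "nf_classification")
}

#' Classify a corpus and retain the flagged sub-corpus
#'
#' @param corpus a [news_corpus()].
#' @param rulesets list of [ruleset()] objects.
#' @param require_all_includes see [classify_article()].
#' @param verbose log per-topic retention counts with `message()`.
#' @return list with `results` (one `nf_classification` per article, corpus
#'   order), `flags` (tibble article_id x topic logical), `retained`
#'   (sub-corpus of articles with at least one true flag, original order)
#'   and `topic_counts` (named integer).
#' @export
classify_corpus <- function(corpus, rulesets, require_all_includes = FALSE,
                            verbose = FALSE) {
  topics <- vapply(rulesets, `[[`, character(1), "topic")
  need_values <- any(vapply(rulesets, function(rs) {
    any(vapply(rs$criteria, function(cr) {
      any(vapply(pattern_atoms(cr$pattern),
                 function(a) a$node$kind == "value", logical(1)))
    }, logical(1)))
  }, logical(1)))
  results <- vector("list", nrow(corpus))
  flag_mat <- matrix(FALSE, nrow = nrow(corpus), ncol = length(topics),
                     dimnames = list(NULL, topics))
  for (i in seq_len(nrow(corpus))) {
    view <- article_view(corpus$title[[i]], corpus$body[[i]],
                         need_values = need_values)
    res <- classify_view(corpus$article_id[[i]], view, rulesets,
                         require_all_includes = require_all_includes)
    results[[i]] <- res
    flag_mat[i, ] <- res$topic_flags
  }
  keep <- rowSums(flag_mat) > 0L
  counts <- colSums(flag_mat)
  if (verbose) {
    message("retained ", sum(keep), "/", nrow(corpus), " articles (",
            paste(sprintf("%s=%d", topics, counts), collapse = ", "), ")")
  }
  retained <- as_news_corpus(corpus[keep, , drop = FALSE],
                             date_window = attr(corpus, "date_window"))
  list(results = results,
       flags = tibble::as_tibble(cbind(
         tibble::tibble(article_id = corpus$article_id),
         as.data.frame(flag_mat))),
       retained = retained,
       topic_counts = stats::setNames(as.integer(counts), topics))
}

#' Sample flagged articles for human relevance validation
#'
#' Uniform sample without replacement from the articles flagged positive
#' for a topic; the standard validation protocol draws 50 per topic. When
#' fewer than `n` articles are flagged, all of them are returned with a
#' warning.
#'
#' @param results list of `nf_classification` (or output of
#'   [classify_corpus()]).
#' @param topic topic id.
#' @param n sample size (default 50).
#' @param seed integer seed; the same seed reproduces the same sample.
#' @return character vector of article ids.
#' @export
sample_flagged <- function(results, topic, n = 50, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.list(results) && !is.null(results$results)) results <- results$results
  topics <- names(results[[1L]]$topic_flags)
  if (!topic %in% topics) {
    stop("unknown topic: ", topic, call. = FALSE)
  }
  flagged <- vapply(results, function(r) isTRUE(r$topic_flags[[topic]]),
                    logical(1))
  ids <- vapply(results, `[[`, character(1), "article_id")[flagged]
  if (length(ids) <= n) {
    if (length(ids) < n) {
      warning(sprintf("only %d articles flagged for `%s`; returning all",
                      length(ids), topic), call. = FALSE)
    }
    return(ids)
  }
  withr::with_seed(seed, sample(ids, n))
}

#' Relevance rate of a validation sample
#'
#' @param annotations named character vector (names = article ids, values
#'   `"relevant"` or `"irrelevant"`), or a data frame with columns
#'   `article_id` and `judgment`.
#' @return list with `rate` (percentage), `n_annotated`, `n_relevant`.
#' @export
relevance_rate <- function(annotations) {
  if (is.data.frame(annotations)) {
    judgments <- annotations$judgment
  } else {
    judgments <- unname(annotations)
  }
  if (length(judgments) == 0L) {
    stop("annotations must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(judgments), c("relevant", "irrelevant"))
  if (length(bad) > 0L) {
    stop("unknown judgment value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(judgments)
  nr <- sum(judgments == "relevant")
  list(rate = 100 * nr / n, n_annotated = n, n_relevant = nr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
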