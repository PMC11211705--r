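#' News corpus container
#'
#' A `news_corpus` is a tibble of media records — one row per article — with
#' a stable iteration order (publication date, then article id) and an
#' inclusive date window attribute. The stable order makes downstream
#' "keep-earliest" deduplication and seeded validation sampling reproducible.
#'
#' Required columns: `article_id` (unique string), `title`, `body`
#' (character, may be empty but not missing), `published` (`Date`),
#' `source`, `country_tags` (list of ISO-3166 alpha-2 character vectors,
#' no duplicates within an article), `language` (IETF tag).
#'
#' @param articles data frame with the columns above; `published` may be
#'   given as "YYYY-MM-DD" strings; `country_tags` may be a pipe-separated
#'   character column (the CSV dialect).
#' @param date_window length-2 `Date` (or date string) vector, inclusive.
#'   Defaults to the range of `published`.
#' @return a `news_corpus` (tibble subclass).
#' @export
news_corpus <- function(articles, date_window = NULL) {
  required <- c("article_id", "title", "body", "published", "source",
                "country_tags", "language")
  articles <- tibble::as_tibble(articles)
  missing_cols <- setdiff(required, names(articles))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  articles$article_id <- as.character(articles$article_id)
  articles$title <- ifelse(is.na(articles$title), "", as.character(articles$title))
  articles$body <- ifelse(is.na(articles$body), "", as.character(articles$body))
  articles$published <- parse_published(articles$published)
  articles$country_tags <- normalize_tags(articles$country_tags)
  if (anyDuplicated(articles$article_id) > 0L) {
    dup <- articles$article_id[duplicated(articles$article_id)][1L]
    stop("duplicate article_id in corpus: ", dup, call. = FALSE)
  }
  ord <- order(articles$published, articles$article_id)
  articles <- articles[ord, , drop = FALSE]
  if (is.null(date_window)) {
    date_window <- if (nrow(articles) > 0L) range(articles$published) else
      as.Date(c("2020-01-01", "2022-06-30"))
  }
  date_window <- as.Date(date_window)
  if (length(date_window) != 2L || anyNA(date_window) ||
      date_window[1L] > date_window[2L]) {
    stop("date_window must be two ordered dates", call. = FALSE)
  }
  if (nrow(articles) > 0L &&
      (min(articles$published) < date_window[1L] ||
       max(articles$published) > date_window[2L])) {
    stop("article dates fall outside the corpus date_window", call. = FALSE)
  }
  structure(articles,
            date_window = date_window,
            class = c("news_corpus", class(tibble::tibble())))
}

parse_published <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)))
  chr <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}", chr)
  out[ok] <- as.Date(substr(chr[ok], 1L, 10L))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("unparseable `published` date at record ", bad, ": ", chr[bad],
         call. = FALSE)
  }
  out
}

normalize_tags <- function(tags) {
  if (!is.list(tags)) {
    tags <- strsplit(ifelse(is.na(tags), "", as.character(tags)), "|", fixed = TRUE)
  }
  lapply(tags, function(x) {
    x <- toupper(x[!is.na(x) & nzchar(x)])
    unique(x)
  })
}

#' @export
print.news_corpus <- function(x, ...) {
  dw <- attr(x, "date_window")
  cat(sprintf("<news_corpus> %d articles, %s to %s\n",
              nrow(x), format(dw[1L]), format(dw[2L])))
  NextMethod()
}

#' Restore the news_corpus class after tibble/dplyr manipulation
#'
#' Row subsetting keeps the original order, so re-sorting is cheap and safe.
#' @param x data frame of articles.
#' @param date_window optional window; defaults to the attribute on `x` if
#'   present.
#' @export
as_news_corpus <- function(x, date_window = NULL) {
  if (is.null(date_window)) date_window <- attr(x, "date_window")
  news_corpus(x, date_window = date_window)
}

#' Read a corpus from JSON Lines or CSV
#'
#' JSON Lines: one article object per line, UTF-8. CSV: header row with the
#' same field names; `country_tags` pipe-separated. Malformed records are a
#' schema error naming the field and line by default; with
#' `on_error = "drop"` they are dropped and counted in a message so that
#' nothing disappears without trace.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @param on_error `"stop"` (default) or `"drop"`.
#' @param date_window optional explicit window passed to [news_corpus()].
#' @return a [news_corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        on_error = c("stop", "drop"), date_window = NULL) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  required <- c("article_id", "title", "body", "published", "source",
                "country_tags", "language")
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines_keep <- which(nzchar(trimws(lines)))
    records <- vector("list", length(lines_keep))
    bad <- character(0)
    for (i in seq_along(lines_keep)) {
      ln <- lines_keep[[i]]
      rec <- tryCatch(jsonlite::fromJSON(lines[[ln]]), error = function(e) NULL)
      problem <- NULL
      if (is.null(rec)) {
        problem <- sprintf("line %d: invalid JSON", ln)
      } else {
        miss <- setdiff(required, names(rec))
        if (length(miss) > 0L) {
          problem <- sprintf("line %d: missing required field `%s`", ln, miss[1L])
        } else if (!grepl("^\\d{4}-\\d{2}-\\d{2}", as.character(rec$published))) {
          problem <- sprintf("line %d: unparseable date `%s`", ln, rec$published)
        }
      }
      if (!is.null(problem)) {
        if (on_error == "stop") stop("schema error: ", problem, call. = FALSE)
        bad <- c(bad, problem)
        next
      }
      rec$country_tags <- list(as.character(unlist(rec$country_tags)))
      records[[i]] <- tibble::as_tibble(rec[required])
    }
    records <- records[!vapply(records, is.null, logical(1))]
    if (length(bad) > 0L) {
      message(length(bad), " malformed record(s) dropped: ",
              paste(utils::head(bad, 5L), collapse = "; "))
    }
    df <- if (length(records) > 0L) dplyr::bind_rows(records) else
      empty_article_table()
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L) {
      stop("schema error: CSV header missing field `", miss[1L], "`",
           call. = FALSE)
    }
    badln <- which(!grepl("^\\d{4}-\\d{2}-\\d{2}", df$published))
    if (length(badln) > 0L) {
      if (on_error == "stop") {
        stop(sprintf("schema error: line %d: unparseable date `%s`",
                     badln[1L] + 1L, df$published[badln[1L]]), call. = FALSE)
      }
      message(length(badln), " malformed record(s) dropped")
      df <- df[-badln, , drop = FALSE]
    }
  }
  news_corpus(df, date_window = date_window)
}

empty_article_table <- function() {
  tibble::tibble(article_id = character(0), title = character(0),
                 body = character(0), published = as.Date(character(0)),
                 source = character(0), country_tags = list(),
                 language = character(0))
}

#' Write a corpus to JSON Lines or CSV
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x))` is the
#' identity on well-formed corpora.
#' @param corpus a [news_corpus()].
#' @param path output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  df <- tibble::as_tibble(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(list(
        article_id = df$article_id[[i]], title = df$title[[i]],
        body = df$body[[i]], published = format(df$published[[i]]),
        source = df$source[[i]],
        country_tags = I(df$country_tags[[i]]),
        language = df$language[[i]]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    out <- df
    out$published <- format(out$published)
    out$country_tags <- vapply(out$country_tags, paste, character(1),
                               collapse = "|")
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Whitespace word count
#'
#' Count of whitespace-delimited tokens after trimming; the deterministic,
#' language-neutral basis of all corpus-size accounting.
#' @param text character vector.
#' @return non-negative integer vector.
#' @export
word_count <- function(text) {
  text <- ifelse(is.na(text), "", text)
  trimmed <- trimws(text)
  n <- lengths(strsplit(trimmed, "[[:space:]]+"))
  n[!nzchar(trimmed)] <- 0L
  as.integer(n)
}

#' Standardized pages
#'
#' One standardized page is 300 words; pages are floored. The 300-word
#' convention is derived: it is the unique integer page size consistent with
#' every printed (word, page) pair in the reduction funnel this package
#' models (for example 3,007,693 words being 10,025 pages).
#' @param total_words non-negative numeric vector.
#' @param words_per_page page size, default 300.
#' @return integer page count(s).
#' @export
standardized_pages <- function(total_words, words_per_page = 300L) {
  if (any(is.na(total_words)) || any(total_words < 0)) {
    stop("total_words must be non-negative", call. = FALSE)
  }
  as.integer(floor(total_words / words_per_page))
}

#' Corpus size accounting
#'
#' @param corpus a [news_corpus()].
#' @param include_title count title words as well as body words (default);
#'   set `FALSE` for body-only accounting.
#' @return list with `articles`, `words`, `pages`.
#' @export
corpus_stats <- function(corpus, include_title = TRUE) {
  words <- sum(word_count(corpus$body))
  if (include_title) words <- words + sum(word_count(corpus$title))
  list(articles = nrow(corpus), words = as.integer(words),
       pages = standardized_pages(words))
}
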