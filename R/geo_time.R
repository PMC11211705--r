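# Country tag reduction and time clustering. Media-monitoring extracts
# carry zero or more country tags per article; analysis needs exactly one.
# The resolver cross-checks gazetteer mentions of each tagged country in
# the title and body and keeps the most relevant tag (title mentions
# dominate, then body mentions, then original tag order). Resolution only
# ever selects among the article's existing tags; articles whose tags are
# never mentioned stay "unresolved" and are excluded from per-country
# counts. Time clustering is by calendar month.

#' Load a gazetteer of country surface forms
#'
#' CSV with columns `surface_form` (country name, alias or demonym) and
#' `iso2` (ISO-3166 alpha-2 code). Surface forms must be unique after
#' case-folding. The package ships a reference gazetteer at
#' `system.file("extdata", "gazetteer.csv", package = "newsfunnel")`.
#'
#' @param path CSV path, or a data frame with the two columns.
#' @return an `nf_gazetteer`.
#' @export
read_gazetteer <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gazetteer.csv", package = "newsfunnel")
  }
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(c("surface_form", "iso2") %in% names(df))) {
    stop("gazetteer needs columns surface_form, iso2", call. = FALSE)
  }
  bad <- df$iso2[!grepl("^[A-Za-z]{2}$", df$iso2)]
  if (length(bad) > 0L) {
    stop("invalid ISO-3166 alpha-2 code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tok <- lapply(df$surface_form, nf_tokens)
  form_norm <- vapply(tok, paste, character(1), collapse = " ")
  if (anyDuplicated(form_norm) > 0L) {
    stop("duplicate gazetteer surface form after case-folding: ",
         form_norm[duplicated(form_norm)][1L], call. = FALSE)
  }
  structure(list(forms = tibble::tibble(form = form_norm,
                                        len = lengths(tok),
                                        iso2 = toupper(df$iso2))),
            class = "nf_gazetteer")
}

# longest-match scan of one token vector; returns named counts by iso2
scan_tokens <- function(tokens, gaz) {
  n <- length(tokens)
  counts <- integer(0)
  if (n == 0L) return(counts)
  consumed <- logical(n)
  for (len in sort(unique(gaz$forms$len), decreasing = TRUE)) {
    if (n < len) next
    forms <- gaz$forms[gaz$forms$len == len, ]
    starts <- seq_len(n - len + 1L)
    grams <- tokens[starts]
    if (len > 1L) {
      for (off in seq_len(len - 1L)) {
        grams <- paste(grams, tokens[starts + off])
      }
    }
    hit <- match(grams, forms$form)
    for (s in starts[!is.na(hit)]) {
      span <- s:(s + len - 1L)
      if (any(consumed[span])) next
      consumed[span] <- TRUE
      code <- forms$iso2[[hit[[s]]]]
      counts[code] <- (if (code %in% names(counts)) counts[[code]] else 0L) + 1L
    }
  }
  counts
}

#' Count gazetteer mentions per country, split by field
#'
#' Case-folded longest-match scan: an occurrence of "South Africa" counts
#' ZA once and never additionally matches shorter overlapping forms.
#'
#' @param article list or one-row data frame with `title` and `body`.
#' @param gazetteer an `nf_gazetteer`.
#' @return tibble `iso2`, `field` (`"title"`/`"body"`), `count`.
#' @export
detect_mentions <- function(article, gazetteer) {
  tc <- scan_tokens(nf_tokens(article$title), gazetteer)
  bc <- scan_tokens(nf_tokens(article$body), gazetteer)
  dplyr::bind_rows(
    tibble::tibble(iso2 = names(tc) %||% character(0), field = "title",
                   count = as.integer(tc)),
    tibble::tibble(iso2 = names(bc) %||% character(0), field = "body",
                   count = as.integer(bc)))
}

#' Reduce an article's country tags to the single most relevant one
#'
#' Single-tag articles keep their tag without scanning. Multi-tag articles
#' rank candidate tags by title mentions, then body mentions, then
#' original tag order; if no tagged country is mentioned at all the
#' article is `"unresolved"` (original tags preserved in the evidence).
#' Untagged articles are `"unresolved"`.
#'
#' @param article list or one-row data frame with `article_id`, `title`,
#'   `body` and `country_tags` (character vector).
#' @param gazetteer an `nf_gazetteer`.
#' @return list with `article_id`, `resolved` (ISO code or
#'   `"unresolved"`), `tags` (original) and `evidence` (mention tibble for
#'   the tagged countries).
#' @export
resolve_country <- function(article, gazetteer) {
  tags <- article$country_tags
  if (is.list(tags)) tags <- tags[[1L]]
  tags <- as.character(tags)
  empty_ev <- tibble::tibble(iso2 = character(0), field = character(0),
                             count = integer(0))
  if (length(tags) == 0L) {
    return(list(article_id = article$article_id, resolved = "unresolved",
                tags = tags, evidence = empty_ev))
  }
  if (length(tags) == 1L) {
    return(list(article_id = article$article_id, resolved = tags,
                tags = tags, evidence = empty_ev))
  }
  men <- detect_mentions(article, gazetteer)
  men <- men[men$iso2 %in% tags, , drop = FALSE]
  title_n <- body_n <- stats::setNames(integer(length(tags)), tags)
  if (nrow(men) > 0L) {
    for (j in seq_len(nrow(men))) {
      if (men$field[[j]] == "title") {
        title_n[[men$iso2[[j]]]] <- title_n[[men$iso2[[j]]]] + men$count[[j]]
      } else {
        body_n[[men$iso2[[j]]]] <- body_n[[men$iso2[[j]]]] + men$count[[j]]
      }
    }
  }
  if (all(title_n == 0L) && all(body_n == 0L)) {
    return(list(article_id = article$article_id, resolved = "unresolved",
                tags = tags, evidence = men))
  }
  ord <- order(-title_n, -body_n, seq_along(tags))
  list(article_id = article$article_id, resolved = tags[[ord[[1L]]]],
       tags = tags, evidence = men)
}

#' Resolve countries for a whole corpus
#'
#' @param corpus a [news_corpus()].
#' @param gazetteer an `nf_gazetteer` (default: the shipped reference
#'   file).
#' @return tibble `article_id`, `resolved`, `n_tags`.
#' @export
resolve_countries <- function(corpus, gazetteer = read_gazetteer()) {
  if (nrow(corpus) == 0L) {
    return(tibble::tibble(article_id = character(0),
                          resolved = character(0), n_tags = integer(0)))
  }
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    r <- resolve_country(list(article_id = corpus$article_id[[i]],
                              title = corpus$title[[i]],
                              body = corpus$body[[i]],
                              country_tags = corpus$country_tags[[i]]),
                         gazetteer)
    tibble::tibble(article_id = r$article_id, resolved = r$resolved,
                   n_tags = length(r$tags))
  })
  dplyr::bind_rows(rows)
}

#' Calendar month bucket of a publication date
#'
#' @param published `Date` vector (or parseable strings).
#' @param date_window optional inclusive window; out-of-window dates get a
#'   warning but are still bucketed.
#' @return character vector `"YYYY-MM"`.
#' @export
month_bucket <- function(published, date_window = NULL) {
  published <- as.Date(published)
  if (!is.null(date_window)) {
    date_window <- as.Date(date_window)
    out <- published < date_window[1L] | published > date_window[2L]
    if (any(out, na.rm = TRUE)) {
      warning(sum(out), " date(s) outside the corpus window", call. = FALSE)
    }
  }
  format(published, "%Y-%m")
}

#' All month buckets covered by a date window
#'
#' @param date_window length-2 inclusive `Date` window.
#' @return character vector `"YYYY-MM"`, one per calendar month.
#' @export
month_seq <- function(date_window) {
  date_window <- as.Date(date_window)
  start <- as.Date(format(date_window[1L], "%Y-%m-01"))
  end <- as.Date(format(date_window[2L], "%Y-%m-01"))
  format(seq(start, end, by = "month"), "%Y-%m")
}
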