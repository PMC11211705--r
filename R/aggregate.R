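# Synthesis layer: apply a subevent codebook to summaries and compute the
# quantitative outputs of a media content analysis — subevent distribution
# tables, affected-count sums by year, monthly topic series, country
# coverage, code x topic co-occurrence matrices and 100%-stacked monthly
# shares. The dictionary auto-coder is an explicit stand-in for human
# deductive-inductive coding; manual code files take precedence when
# supplied.

# round half up (commercial rounding); base round() is round-half-even,
# which does not reproduce standard 1-decimal percentage tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Load a subevent / factor / response codebook
#'
#' YAML (or equivalent list) with a top-level `codes` list; each code has
#' `code`, `label`, `theme` (`area_of_impact`, `contributing_factor` or
#' `response`), `topics` (topic ids it applies to; empty = all),
#' `keywords` (words or phrases matched case-folded on token boundaries)
#' and optionally `residual: true` — a residual code is assigned to a
#' topic record exactly when no sibling keyword code of the same theme and
#' topic matched (e.g. "unspecified" vaccination status is the absence of
#' any dose keyword).
#'
#' @param path YAML path or list in the same shape.
#' @return an `nf_codebook` (tibble of codes).
#' @export
read_codebook <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codebook.yaml", package = "newsfunnel")
  }
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$codes)) {
    stop("codebook must have a top-level `codes` list", call. = FALSE)
  }
  rows <- lapply(cfg$codes, function(cd) {
    if (is.null(cd$code)) stop("codebook entry missing `code` id", call. = FALSE)
    residual <- isTRUE(cd$residual)
    kw <- as.character(unlist(cd$keywords))
    if (length(kw) == 0L && !residual && !isTRUE(cd$manual_only)) {
      stop("code `", cd$code, "` has no keywords and is not residual/manual",
           call. = FALSE)
    }
    tibble::tibble(code = cd$code,
                   label = cd$label %||% cd$code,
                   theme = cd$theme %||% "area_of_impact",
                   topics = list(as.character(unlist(cd$topics))),
                   keywords = list(kw),
                   residual = residual)
  })
  cb <- dplyr::bind_rows(rows)
  if (anyDuplicated(cb$code) > 0L) {
    stop("duplicate code id: ", cb$code[duplicated(cb$code)][1L],
         call. = FALSE)
  }
  if (!all(cb$theme %in% c("area_of_impact", "contributing_factor",
                           "response"))) {
    stop("unknown codebook theme", call. = FALSE)
  }
  structure(cb, class = c("nf_codebook", class(cb)))
}

#' Assign codebook codes to summarized records
#'
#' Operates on the topic-mode rows of [summarize_corpus()] output: a code
#' is assigned to (article, topic) iff the code applies to the topic and
#' at least one of its keywords occurs in the summary text (title
#' prepended, case-folded, whole-token / phrase match). Residual codes are
#' assigned when no sibling keyword code of the same theme matched for
#' that record. A manual code table (`article_id`, `code`) overrides all
#' auto-codes of the listed articles.
#'
#' @param summaries [summarize_corpus()] output (topic-mode rows are
#'   used).
#' @param codebook an `nf_codebook`.
#' @param manual_codes optional data frame or CSV path with columns
#'   `article_id`, `code`; unknown codes are a validation error.
#' @return tibble `article_id`, `topic_id`, `theme`, `code`. Articles
#'   whose summary matches nothing get no rows.
#' @export
apply_codebook <- function(summaries, codebook, manual_codes = NULL) {
  topic_rows <- summaries[grepl("^topic:", summaries$mode), , drop = FALSE]
  kw_tokens <- lapply(codebook$keywords, function(kws) lapply(kws, nf_tokens))
  out <- vector("list", nrow(topic_rows))
  for (i in seq_len(nrow(topic_rows))) {
    topic <- sub("^topic:", "", topic_rows$mode[[i]])
    toks <- nf_tokens(paste(topic_rows$title[[i]], topic_rows$text[[i]]))
    applies <- vapply(codebook$topics, function(tp) {
      length(tp) == 0L || topic %in% tp
    }, logical(1))
    hit <- logical(nrow(codebook))
    for (k in which(applies & !codebook$residual)) {
      hit[[k]] <- any(vapply(kw_tokens[[k]], function(tt) {
        length(tt) > 0L && nf_has_phrase(toks, tt)
      }, logical(1)))
    }
    for (k in which(applies & codebook$residual)) {
      sib <- applies & !codebook$residual & codebook$theme == codebook$theme[[k]]
      hit[[k]] <- !any(hit[sib])
    }
    if (any(hit)) {
      out[[i]] <- tibble::tibble(article_id = topic_rows$article_id[[i]],
                                 topic_id = topic,
                                 theme = codebook$theme[hit],
                                 code = codebook$code[hit])
    }
  }
  codes <- dplyr::bind_rows(out)
  if (nrow(codes) == 0L) {
    codes <- tibble::tibble(article_id = character(0), topic_id = character(0),
                            theme = character(0), code = character(0))
  }
  if (!is.null(manual_codes)) {
    if (is.character(manual_codes)) {
      manual_codes <- readr::read_csv(manual_codes, col_types = "cc",
                                      progress = FALSE)
    }
    unknown <- setdiff(manual_codes$code, codebook$code)
    if (length(unknown) > 0L) {
      stop("manual code file uses unknown code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    manual <- dplyr::left_join(
      tibble::as_tibble(manual_codes[c("article_id", "code")]),
      tibble::tibble(code = codebook$code, theme = codebook$theme),
      by = "code")
    manual$topic_id <- NA_character_
    if ("topic_id" %in% names(manual_codes)) {
      manual$topic_id <- manual_codes$topic_id
    }
    codes <- dplyr::bind_rows(
      codes[!codes$article_id %in% manual$article_id, , drop = FALSE],
      manual[c("article_id", "topic_id", "theme", "code")])
  }
  dplyr::arrange(codes, .data$article_id, .data$theme, .data$code)
}

#' Assemble coded records from the pipeline stages
#'
#' Joins code assignments with resolved countries, month buckets and
#' optional affected-count annotations into the unit of all synthesis
#' tables.
#'
#' @param codes output of [apply_codebook()].
#' @param corpus the deduplicated [news_corpus()] (for dates).
#' @param geo output of [resolve_countries()] (optional; country becomes
#'   `"unresolved"` when absent).
#' @param annotations optional data frame `article_id`, `affected_count`,
#'   `affected_kind` (kind one of vaccinated / striking / infected /
#'   dead). Negative counts are a validation error; a count without a kind
#'   is too.
#' @return tibble `article_id`, `topic_id`, `theme`, `code`, `country`,
#'   `month`, `affected_count`, `affected_kind`.
#' @export
assemble_records <- function(codes, corpus, geo = NULL, annotations = NULL) {
  dates <- tibble::tibble(article_id = corpus$article_id,
                          month = month_bucket(corpus$published))
  rec <- dplyr::left_join(codes, dates, by = "article_id")
  if (!is.null(geo)) {
    rec <- dplyr::left_join(rec, geo[c("article_id", "resolved")],
                            by = "article_id")
    rec$country <- ifelse(is.na(rec$resolved), "unresolved", rec$resolved)
    rec$resolved <- NULL
  } else {
    rec$country <- "unresolved"
  }
  rec$affected_count <- NA_real_
  rec$affected_kind <- NA_character_
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    if (any(!is.na(annotations$affected_count) & annotations$affected_count < 0)) {
      stop("negative affected_count in annotations", call. = FALSE)
    }
    if (any(!is.na(annotations$affected_count) &
            is.na(annotations$affected_kind))) {
      stop("affected_count present without affected_kind", call. = FALSE)
    }
    ann <- annotations[!is.na(annotations$affected_count),
                       c("article_id", "affected_count", "affected_kind")]
    rec$affected_count <- NULL
    rec$affected_kind <- NULL
    rec <- dplyr::left_join(rec, ann, by = "article_id")
  }
  rec[c("article_id", "topic_id", "theme", "code", "country", "month",
        "affected_count", "affected_kind")]
}

#' Distribution table from per-code counts
#'
#' Percentages are `100 * n / N` rounded half-up to `digits` decimals
#' (1 by default; 2 reproduces running-text variants like 28.57). The
#' half-up rule is what standard frequency tables use; round-half-even
#' would disagree on exact .05 boundaries.
#'
#' @param counts named integer vector (code -> n).
#' @param digits decimal places for the percentage.
#' @return tibble `code`, `n`, `pct`, with attribute `N` (theme total).
#' @export
distribution_table <- function(counts, digits = 1) {
  N <- sum(counts)
  if (length(counts) == 0L || N == 0L) {
    out <- tibble::tibble(code = names(counts) %||% character(0),
                          n = as.integer(counts), pct = rep(0, length(counts)))
    attr(out, "N") <- 0L
    return(out)
  }
  out <- tibble::tibble(code = names(counts), n = as.integer(counts),
                        pct = round_half_up(100 * as.integer(counts) / N,
                                            digits))
  attr(out, "N") <- as.integer(N)
  out
}

#' Subevent distribution over coded records
#'
#' Row units are code assignments (an article contributing to several
#' subevents counts once per subevent), so the theme total N is the number
#' of assignments in scope, not of distinct articles.
#'
#' @param records [assemble_records()] output.
#' @param theme optional theme filter.
#' @param topic optional topic filter.
#' @param digits see [distribution_table()].
#' @return a [distribution_table()]; empty (attribute `N` = 0) when
#'   nothing is in scope.
#' @export
subevent_distribution <- function(records, theme = NULL, topic = NULL,
                                  digits = 1) {
  scope <- records
  if (!is.null(theme)) scope <- scope[scope$theme == theme, , drop = FALSE]
  if (!is.null(topic)) scope <- scope[scope$topic_id %in% topic, , drop = FALSE]
  counts <- table(scope$code)
  distribution_table(stats::setNames(as.integer(counts), names(counts)),
                     digits = digits)
}

#' Yearly sums of affected health workers by kind
#'
#' Sums `affected_count` per `affected_kind` per calendar year over
#' distinct articles. Records lacking a count are excluded and tallied
#' separately (counts that "could not be ascertained").
#'
#' @param records [assemble_records()] output.
#' @return list with `table` (tibble `affected_kind`, `year`, `total`) and
#'   `excluded` (distinct articles without a count).
#' @export
affected_sums <- function(records) {
  per_article <- dplyr::distinct(records, .data$article_id, .keep_all = TRUE)
  has <- !is.na(per_article$affected_count)
  if (any(per_article$affected_count[has] < 0)) {
    stop("negative affected_count", call. = FALSE)
  }
  tab <- per_article[has, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(list(table = tibble::tibble(affected_kind = character(0),
                                       year = character(0),
                                       total = numeric(0)),
                excluded = sum(!has)))
  }
  tab$year <- substr(tab$month, 1L, 4L)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$affected_kind, .data$year),
    total = sum(.data$affected_count), .groups = "drop")
  list(table = out, excluded = sum(!has))
}

#' Monthly article counts per topic
#'
#' Counts distinct articles per topic per month; months with zero
#' articles are reported explicitly over `months` (typically
#' [month_seq()] of the corpus window).
#'
#' @param records [assemble_records()] output (or any tibble with
#'   `article_id`, `topic_id`, `month`).
#' @param topic optional topic filter (default: all topics present).
#' @param months character vector of `"YYYY-MM"` buckets to report.
#' @return tibble `month`, `topic_id`, `n` — complete over
#'   `months x topics`.
#' @export
monthly_series <- function(records, topic = NULL, months = NULL) {
  scope <- records
  if (!is.null(topic)) scope <- scope[scope$topic_id %in% topic, , drop = FALSE]
  topics <- if (!is.null(topic)) topic else
    sort(unique(stats::na.omit(scope$topic_id)))
  if (is.null(months)) months <- sort(unique(scope$month))
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(scope, .data$article_id, .data$topic_id,
                                    .data$month),
                    .data$month, .data$topic_id),
    n = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(month = months, topic_id = topics)
  out <- dplyr::left_join(grid, counts, by = c("month", "topic_id"))
  out$n <- ifelse(is.na(out$n), 0L, out$n)
  out$n <- as.integer(out$n)
  out
}

#' Number of countries with at least one article
#'
#' @param records [assemble_records()] output.
#' @param topic,code optional filters.
#' @return integer count of distinct resolved countries (`"unresolved"`
#'   excluded).
#' @export
country_coverage <- function(records, topic = NULL, code = NULL) {
  scope <- records
  if (!is.null(topic)) scope <- scope[scope$topic_id %in% topic, , drop = FALSE]
  if (!is.null(code)) scope <- scope[scope$code %in% code, , drop = FALSE]
  length(setdiff(unique(stats::na.omit(scope$country)), "unresolved"))
}

#' Code x topic co-occurrence matrix
#'
#' Cell (a, b) counts distinct articles carrying code `a` (under any
#' topic) and topic `b`. Marginals count distinct articles per code and
#' per topic, so every cell is bounded by both its marginals.
#'
#' @param records [assemble_records()] output.
#' @param axis_a codes (rows); default: all codes present.
#' @param axis_b topics (columns); default: all topics present.
#' @return list with `matrix` (integer), `row_marginals`,
#'   `col_marginals`.
#' @export
cooccurrence_matrix <- function(records, axis_a = NULL, axis_b = NULL) {
  if (is.null(axis_a)) axis_a <- sort(unique(stats::na.omit(records$code)))
  if (is.null(axis_b)) axis_b <- sort(unique(stats::na.omit(records$topic_id)))
  code_sets <- split(records$article_id, records$code)
  topic_sets <- split(records$article_id, records$topic_id)
  m <- matrix(0L, nrow = length(axis_a), ncol = length(axis_b),
              dimnames = list(axis_a, axis_b))
  for (a in axis_a) {
    ids_a <- unique(code_sets[[a]])
    if (is.null(ids_a)) next
    for (b in axis_b) {
      ids_b <- unique(topic_sets[[b]])
      if (is.null(ids_b)) next
      m[a, b] <- length(intersect(ids_a, ids_b))
    }
  }
  list(matrix = m,
       row_marginals = vapply(axis_a, function(a)
         length(unique(code_sets[[a]])), integer(1)),
       col_marginals = vapply(axis_b, function(b)
         length(unique(topic_sets[[b]])), integer(1)))
}

#' Monthly 100%-stacked shares per code
#'
#' Normalizes monthly code counts to shares summing to 1; months with a
#' zero total emit a flagged zero vector rather than NaN.
#'
#' @param records [assemble_records()] output.
#' @param codes codes to include (default: all present).
#' @param months month buckets to report (default: those present).
#' @return tibble `month`, `code`, `n`, `share`, `empty` (logical,
#'   zero-total month).
#' @export
stacked_share_series <- function(records, codes = NULL, months = NULL) {
  scope <- records[!is.na(records$code), , drop = FALSE]
  if (!is.null(codes)) scope <- scope[scope$code %in% codes, , drop = FALSE]
  if (is.null(codes)) codes <- sort(unique(scope$code))
  if (is.null(months)) months <- sort(unique(scope$month))
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(scope, .data$article_id, .data$code,
                                    .data$month),
                    .data$month, .data$code),
    n = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(month = months, code = codes)
  out <- dplyr::left_join(grid, counts, by = c("month", "code"))
  out$n <- as.integer(ifelse(is.na(out$n), 0L, out$n))
  totals <- stats::ave(out$n, out$month, FUN = sum)
  out$share <- ifelse(totals > 0L, out$n / totals, 0)
  out$empty <- totals == 0L
  out
}
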