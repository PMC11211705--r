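# End-to-end orchestration: generate/ingest -> classify -> summarize ->
# dedup -> geotag -> code -> synthesize, with a run manifest recording the
# article/word/page funnel, parameters and seeds. Single-process,
# sequential, with optional per-stage on-disk outputs so intermediate
# products can be inspected; corpus sizes at desk scale do not warrant
# more.

#' Default classification rule sets
#'
#' One rule set per default topic: a sentence-scope include criterion
#' OR-ing the topic lexicon (so the trigger sentences are exactly the
#' salted sentences), plus body-scope exclude criteria for the classic
#' confounders of the vaccination and infection topics (veterinary /
#' livestock / poultry stories).
#' @return list of [ruleset()] objects.
#' @export
default_rules <- function() {
  or_pattern <- function(terms) {
    paste(sprintf('"%s"', terms), collapse = " OR ")
  }
  lex <- default_lexicons()
  rules <- lapply(names(lex), function(tid) {
    crits <- list(criterion("sentence", "include", or_pattern(lex[[tid]])))
    if (tid == "vaccination") {
      crits <- c(crits, list(criterion("body", "exclude",
                                       '"veterinary" OR "livestock"')))
    }
    if (tid == "infections_deaths") {
      crits <- c(crits, list(criterion("body", "exclude", '"poultry"')))
    }
    ruleset(tid, crits)
  })
  names(rules) <- names(lex)
  rules
}

#' Assemble a pipeline run configuration
#'
#' Either `corpus` (an existing [news_corpus()] or a corpus file path) or
#' `spec` (a [generation_spec()] for synthetic input) must be supplied.
#'
#' @param corpus input corpus or path (`NULL` to generate).
#' @param spec [generation_spec()] used when `corpus` is `NULL`; its
#'   ground truth also supplies affected-count annotations unless
#'   `annotations` is given.
#' @param rules rule file path or list of [ruleset()]s.
#' @param lexicons topic lexicons for the summarizer scorer.
#' @param codebook codebook path or `nf_codebook`.
#' @param gazetteer gazetteer path or `nf_gazetteer`.
#' @param annotations optional affected-count annotations (`article_id`,
#'   `affected_count`, `affected_kind`).
#' @param manual_codes optional manual code table overriding auto-codes.
#' @param k summary length.
#' @param scorer registered scorer name.
#' @param dedup_threshold trigram-overlap duplicate threshold.
#' @param include_title_words count titles in the word funnel.
#' @param seed seed echoed into the manifest (and used for generation
#'   when `spec` carries none).
#' @param out_dir optional directory for per-stage outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(corpus = NULL, spec = NULL, rules = default_rules(),
                       lexicons = default_lexicons(),
                       codebook = read_codebook(),
                       gazetteer = read_gazetteer(),
                       annotations = NULL, manual_codes = NULL, k = 3L,
                       scorer = "lexical", dedup_threshold = 0.30,
                       include_title_words = TRUE, seed = 1L,
                       out_dir = NULL) {
  if (is.null(corpus) && is.null(spec)) {
    stop("run_config needs either a corpus or a generation spec",
         call. = FALSE)
  }
  structure(list(corpus = corpus, spec = spec, rules = rules,
                 lexicons = lexicons, codebook = codebook,
                 gazetteer = gazetteer, annotations = annotations,
                 manual_codes = manual_codes, k = k, scorer = scorer,
                 dedup_threshold = dedup_threshold,
                 include_title_words = include_title_words,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage_stats <- function(corpus, include_title) {
  s <- corpus_stats(corpus, include_title = include_title)
  tibble::tibble(articles = s$articles, words = s$words, pages = s$pages)
}

#' Run the full pipeline
#'
#' Stages execute in fixed order, each consuming the previous stage's
#' output; identical configuration and seeds reproduce identical outputs.
#' When `out_dir` is set, every stage's product is written before the
#' next begins (corpus stages as JSON Lines, tables as CSV, the manifest
#' as JSON).
#'
#' @param config a [run_config()].
#' @param verbose log stage transitions.
#' @return list with `manifest` (stage funnel + parameter/seed echo),
#'   `corpus`, `classification`, `summaries`, `dedup_report`, `geo`,
#'   `codes`, `records`, `tables` (synthesis outputs) and `truth` (when
#'   generated).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_corpus <- function(corpus, name) {
    if (!is.null(out_dir)) {
      write_corpus(corpus, file.path(out_dir, paste0(name, ".jsonl")))
    }
  }
  emit_table <- function(df, name) {
    if (!is.null(out_dir)) {
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }

  ## ingest / generate
  truth <- NULL
  if (!is.null(config$corpus)) {
    corpus <- if (is.character(config$corpus)) read_corpus(config$corpus)
              else config$corpus
  } else {
    gen <- generate_corpus(config$spec)
    corpus <- gen$corpus
    truth <- gen$truth
    if (is.null(config$annotations)) config$annotations <- truth
  }
  say("ingest: %d articles", nrow(corpus))
  emit_corpus(corpus, "01_raw")

  rulesets <- if (is.character(config$rules)) parse_ruleset(config$rules)
              else config$rules
  codebook <- if (is.character(config$codebook)) read_codebook(config$codebook)
              else config$codebook
  gazetteer <- if (is.character(config$gazetteer))
    read_gazetteer(config$gazetteer) else config$gazetteer

  ## classify
  cls <- classify_corpus(corpus, rulesets)
  say("classify: retained %d", nrow(cls$retained))
  emit_corpus(cls$retained, "02_classified")

  ## summarize
  summaries <- summarize_corpus(cls$retained, cls, config$lexicons,
                                scorer = config$scorer, k = config$k)
  if (!is.null(out_dir)) {
    flat <- summaries
    flat$indices <- vapply(flat$indices, paste, character(1), collapse = "|")
    flat$scores <- vapply(flat$scores, function(x)
      paste(format(x, digits = 8), collapse = "|"), character(1))
    emit_table(flat, "03_summaries")
  }
  say("summarize: %d summaries", nrow(summaries))

  ## dedup
  dd <- deduplicate(cls$retained, threshold = config$dedup_threshold)
  deduped <- dd$corpus
  say("dedup: removed %d, kept %d", nrow(dd$report), nrow(deduped))
  emit_corpus(deduped, "04_deduped")
  emit_table(dd$report, "04_dedup_report")
  summaries_kept <- summaries[summaries$article_id %in% deduped$article_id, ,
                              drop = FALSE]

  ## geotag + time cluster
  geo <- resolve_countries(deduped, gazetteer)
  emit_table(geo, "05_geo")

  ## code
  codes <- apply_codebook(summaries_kept, codebook,
                          manual_codes = config$manual_codes)
  records <- assemble_records(codes, deduped, geo = geo,
                              annotations = config$annotations)
  emit_table(records, "06_records")
  say("code: %d coded records for %d articles", nrow(records),
      length(unique(records$article_id)))

  ## synthesize
  months <- month_seq(attr(corpus, "date_window"))
  area <- records[records$theme == "area_of_impact", , drop = FALSE]
  topics_present <- sort(unique(stats::na.omit(records$topic_id)))
  dist_tabs <- lapply(stats::setNames(topics_present, topics_present),
                      function(tid) {
    subevent_distribution(area, theme = "area_of_impact", topic = tid)
  })
  tables <- list(
    subevent_distribution = dist_tabs,
    monthly_series = monthly_series(area, months = months),
    affected_sums = affected_sums(records),
    country_coverage = vapply(
      stats::setNames(topics_present, topics_present),
      function(tid) country_coverage(records, topic = tid), integer(1)),
    factor_cooccurrence = cooccurrence_matrix(
      records[records$theme %in% c("area_of_impact", "contributing_factor"), ],
      axis_a = sort(unique(records$code[records$theme == "contributing_factor"]))),
    response_cooccurrence = cooccurrence_matrix(
      records[records$theme %in% c("area_of_impact", "response"), ],
      axis_a = sort(unique(records$code[records$theme == "response"]))),
    factor_shares = stacked_share_series(
      records[records$theme == "contributing_factor", ], months = months),
    response_shares = stacked_share_series(
      records[records$theme == "response", ], months = months))
  emit_table(tables$monthly_series, "07_monthly_series")
  emit_table(tables$affected_sums$table, "07_affected_sums")
  emit_table(tables$factor_shares, "07_factor_shares")
  emit_table(tables$response_shares, "07_response_shares")
  if (length(dist_tabs) > 0L && !is.null(out_dir)) {
    dist_flat <- dplyr::bind_rows(lapply(names(dist_tabs), function(tid) {
      tab <- dist_tabs[[tid]]
      if (nrow(tab) == 0L) return(NULL)
      tibble::tibble(topic_id = tid, code = tab$code, n = tab$n,
                     pct = tab$pct, N = attr(tab, "N"))
    }))
    if (!is.null(dist_flat) && nrow(dist_flat) > 0L) {
      emit_table(dist_flat, "07_subevent_distribution")
    }
  }

  include_title <- config$include_title_words
  summary_words <- sum(word_count(summaries_kept$text[
    summaries_kept$mode == "global"]))
  if (include_title) {
    summary_words <- summary_words + sum(word_count(
      summaries_kept$title[summaries_kept$mode == "global"]))
  }
  funnel <- dplyr::bind_rows(
    dplyr::mutate(stage_stats(corpus, include_title), stage = "raw"),
    dplyr::mutate(stage_stats(cls$retained, include_title),
                  stage = "classified"),
    dplyr::mutate(stage_stats(deduped, include_title), stage = "deduped"),
    tibble::tibble(articles = nrow(deduped),
                   words = as.integer(summary_words),
                   pages = standardized_pages(summary_words),
                   stage = "summarized"))[, c("stage", "articles", "words",
                                              "pages")]
  manifest <- list(
    funnel = funnel,
    topic_counts = cls$topic_counts,
    dedup_removed = nrow(dd$report),
    unresolved_countries = sum(geo$resolved == "unresolved"),
    params = list(k = config$k, scorer = config$scorer,
                  dedup_threshold = config$dedup_threshold,
                  include_title_words = include_title,
                  require_all_includes = FALSE),
    seed = config$seed,
    spec_seed = if (!is.null(config$spec)) config$spec$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(manifest = manifest, corpus = corpus, classification = cls,
       summaries = summaries_kept, dedup_report = dd$report, geo = geo,
       codes = codes, records = records, tables = tables, truth = truth)
}

#' Human-readable reduction report from a run manifest
#'
#' @param manifest the `manifest` element of a [run_pipeline()] result.
#' @return tibble `stage`, `articles`, `words`, `pages`,
#'   `word_reduction_pct` (relative to the first stage), printed as a
#'   side effect.
#' @export
report_funnel <- function(manifest) {
  f <- manifest$funnel
  base <- f$words[[1L]]
  f$word_reduction_pct <- if (base > 0) {
    round_half_up(100 * (1 - f$words / base), 1)
  } else {
    rep(0, nrow(f))
  }
  for (i in seq_len(nrow(f))) {
    cat(sprintf("%-11s %7d articles %9d words %6d pages  (-%.1f%% words)\n",
                f$stage[[i]], f$articles[[i]], f$words[[i]], f$pages[[i]],
                f$word_reduction_pct[[i]]))
  }
  invisible(f)
}
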