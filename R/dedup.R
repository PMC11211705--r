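# Near-duplicate removal for syndicated copies. An article is a duplicate
# when at least 30% of its distinct word trigrams (3 consecutive
# normalized tokens) already occur in an earlier kept article. A single
# pass in stable (published, article_id) order keeps the earliest copy,
# preserving first-report timestamps for the time series. An exact
# inverted index (trigram -> kept articles) accelerates candidate lookup;
# its output is anchored to the quadratic brute-force pass in the tests.

#' Distinct word trigrams of a body text
#'
#' Tokens are case-folded with edge punctuation stripped; trigrams are the
#' sliding window of 3 consecutive tokens, kept as a distinct set
#' (within-article repetition does not inflate overlap). Fewer than 3
#' tokens yield an empty set.
#'
#' @param body character scalar.
#' @return character vector of distinct trigrams (tokens joined by a
#'   space).
#' @export
trigrams <- function(body) {
  toks <- nf_tokens(body)
  n <- length(toks)
  if (n < 3L) return(character(0))
  unique(paste(toks[1:(n - 2L)], toks[2:(n - 1L)], toks[3:n]))
}

#' Fraction of a candidate's trigrams already seen in a reference
#'
#' `|candidate intersect reference| / |candidate|` — the overlap is a
#' property of the candidate ("the article containing 30% repeated
#' trigrams"), so the denominator is the candidate's distinct trigram
#' count. `metric = "jaccard"` divides by the union size instead.
#'
#' @param candidate,reference character vectors from [trigrams()].
#' @param metric `"candidate"` (default) or `"jaccard"`.
#' @return fraction in `[0, 1]`; 0 when the candidate set is empty.
#' @export
overlap_fraction <- function(candidate, reference,
                             metric = c("candidate", "jaccard")) {
  metric <- match.arg(metric)
  if (length(candidate) == 0L) return(0)
  inter <- sum(candidate %in% reference)
  denom <- if (metric == "candidate") length(candidate) else
    length(candidate) + length(reference) - inter
  inter / denom
}

#' Remove near-duplicate articles from a corpus
#'
#' Single pass in the corpus's stable (published, article_id) order: each
#' article is removed iff its trigram overlap with some earlier kept
#' article reaches `threshold`, attributed to the earliest such kept
#' article; kept articles are never re-examined.
#'
#' @param corpus a [news_corpus()].
#' @param threshold overlap fraction in `(0, 1]`, default 0.30.
#' @param metric see [overlap_fraction()].
#' @return list with `corpus` (deduplicated [news_corpus()]) and `report`
#'   (tibble `removed_id`, `kept_id`, `overlap`; plus attribute
#'   `kept_size`).
#' @export
deduplicate <- function(corpus, threshold = 0.30,
                        metric = c("candidate", "jaccard")) {
  metric <- match.arg(metric)
  if (is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(corpus)
  shingles <- lapply(corpus$body, trigrams)
  sizes <- lengths(shingles)
  index <- new.env(parent = emptyenv())   # trigram -> integer kept row ids
  kept <- logical(n)
  removed <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- shingles[[i]]
    attributed <- NA_integer_
    ov <- NA_real_
    if (length(cand) > 0L) {
      hits <- unlist(lapply(cand, function(g) index[[g]]), use.names = FALSE)
      if (length(hits) > 0L) {
        counts <- table(hits)
        prior <- as.integer(names(counts))
        inter <- as.integer(counts)
        denom <- if (metric == "candidate") length(cand) else
          length(cand) + sizes[prior] - inter
        frac <- inter / denom
        over <- which(frac >= threshold)
        if (length(over) > 0L) {
          # earliest kept article in corpus order
          pick <- over[which.min(prior[over])]
          attributed <- prior[pick]
          ov <- frac[pick]
        }
      }
    }
    if (!is.na(attributed)) {
      removed[[i]] <- tibble::tibble(
        removed_id = corpus$article_id[[i]],
        kept_id = corpus$article_id[[attributed]],
        overlap = ov)
    } else {
      kept[[i]] <- TRUE
      for (g in cand) {
        index[[g]] <- c(index[[g]], i)
      }
    }
  }
  report <- dplyr::bind_rows(removed)
  if (nrow(report) == 0L) {
    report <- tibble::tibble(removed_id = character(0),
                             kept_id = character(0), overlap = numeric(0))
  }
  attr(report, "kept_size") <- sum(kept)
  list(corpus = as_news_corpus(corpus[kept, , drop = FALSE],
                               date_window = attr(corpus, "date_window")),
       report = report)
}
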