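# Internal text normalization shared by the rule engine, the deduplicator,
# the summarizer scorer and the gazetteer scanner. One tokenizer everywhere
# keeps the "whole token, case-folded, punctuation-stripped" matching
# contract consistent across modules.

# Split on whitespace, fold case, strip leading/trailing punctuation.
# Internal punctuation (hyphens, apostrophes, digit group commas) is kept so
# that "sit-in" and "3,500,000" stay single tokens.
nf_tokens <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    return(character(0))
  }
  raw <- strsplit(tolower(text), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw)
  toks[nzchar(toks)]
}

# Numeric value carried by each token, NA for non-numeric tokens.
# Accepts digit-grouping commas ("3,500,000") and decimal points.
nf_token_values <- function(tokens) {
  if (length(tokens) == 0L) {
    return(numeric(0))
  }
  plain <- gsub(",", "", tokens, fixed = TRUE)
  vals <- suppressWarnings(as.numeric(plain))
  vals[!grepl("^[0-9][0-9,.]*$", tokens)] <- NA_real_
  vals
}

# Start positions (possibly none) of a contiguous token subsequence.
nf_phrase_positions <- function(tokens, phrase) {
  np <- length(phrase)
  nt <- length(tokens)
  if (np == 0L || nt < np) {
    return(integer(0))
  }
  starts <- which(tokens == phrase[[1L]])
  starts <- starts[starts <= nt - np + 1L]
  if (np == 1L || length(starts) == 0L) {
    return(starts)
  }
  keep <- vapply(starts, function(s) {
    all(tokens[s:(s + np - 1L)] == phrase)
  }, logical(1))
  starts[keep]
}

nf_has_phrase <- function(tokens, phrase) {
  length(nf_phrase_positions(tokens, phrase)) > 0L
}
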