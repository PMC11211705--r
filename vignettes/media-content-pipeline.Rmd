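---
title: "Methods: a rule-based media content analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based media content analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newsfunnel)
```

## The problem

Open-source media monitoring systems collect millions of news articles;
analysts who want to track, say, the impacts of a pandemic on the health
workforce can read only a few thousand. `newsfunnel` implements the
reduction funnel that makes such a corpus analyzable by humans:

1. **Rule-based topic classification** — per-topic Boolean
   inclusion/exclusion criteria over words, phrases and numeric-proximity
   predicates, scoped to title, body or individual sentences.
2. **Extractive summarization** — each retained article is reduced to at
   most 3 verbatim sentences per mode (global and topic-focused).
3. **Near-duplicate removal** — an article whose distinct word trigrams
   are at least 30% contained in an earlier kept article is dropped as a
   syndicated copy.
4. **Country and time resolution** — multiple country tags are reduced
   to the single most relevant one by cross-checking gazetteer mentions;
   articles are clustered by calendar month.
5. **Coding and synthesis** — a keyword codebook assigns subevent,
   contributing-factor and response codes, from which the quantitative
   outputs (distribution tables, monthly series, affected-count sums,
   co-occurrence matrices, 100%-stacked shares) are computed.

Because real media-monitoring extracts are not redistributable, the
package includes a first-class synthetic corpus generator with full
ground truth, so that every stage is testable offline and every recovery
claim is measurable.

## Classification rules

A criterion is `(scope, polarity, pattern)`. Patterns are Boolean
expression trees (`AND`/`OR`/`NOT`) over three atom kinds:

* *word* — case-folded whole-token equality (`"strike"`);
* *phrase* — a contiguous token sequence
  (`"personal protective equipment"`);
* *value* — a numeric-proximity predicate:
  `NUM >= 100 WITHIN 5 OF "nurses"` is true when a numeric token
  satisfying the comparison occurs within 5 tokens of the term. Numeric
  tokens may carry digit-grouping commas (`3,500,000`).

Tokens are case-folded with edge punctuation stripped; internal hyphens
and apostrophes are kept; there is no stemming (a stemmer would make
matches platform- and locale-sensitive). Sentence scope means *some one
sentence* satisfies the whole expression — a phrase straddling a
sentence boundary matches at body scope but not at sentence scope.

Design choices that the rule language itself does not force:

* **Include combination is OR** (any include criterion suffices); a
  `require_all_includes` flag switches to joint satisfaction.
* **Exclusion is a veto**: any matching exclude criterion defeats the
  topic regardless of includes. This is the conservative,
  precision-oriented reading, matching a workflow whose validation step
  targets high precision on sampled positives.
* The scope-containment property (a sentence-scope match implies a
  body-scope match of the same expression) holds for *negation-free*
  patterns; `NOT` breaks it by construction, since a single sentence can
  lack a term that occurs elsewhere in the body.

Trigger sentences — the sentences that caused inclusion — are recorded
as *pseudolabels*. They are the weak supervision a trainable sentence
scorer consumes, and the package's contract is that the summarizer can
reach them (see below). Title-scope matches have no sentence to point
at; they yield an empty pseudolabel set plus a title marker, and the
title is always carried alongside summaries for human review.

Rule validation follows the standard protocol: draw 50 flagged articles
per topic uniformly without replacement (seeded, hence reproducible) and
compute the relevance rate of human judgments over the sample.

## Summarization

Sentence splitting is rule-based: terminal punctuation followed by
whitespace and an upper-case letter, digit or opening quote, guarded by
a fixed abbreviation list plus a single-initial guard ("A. B. Smith").
Splitting is deterministic, and each sentence is an exact substring of
the body at recorded offsets — the extractive guarantee is checked
against these offsets, not against re-assembled text.

Scoring is a plug-in interface. The reference scorer is lexical and
deterministic: a sentence's score is the count of distinct topic-lexicon
terms it contains plus a position bonus of `1/(1 + index)` (0-based), so
lead sentences win ties — the inverted-pyramid prior of news writing. A
neural extractive model trained on the pseudolabels would register
behind the same interface; the package deliberately does not implement
one, because the pipeline's observable contract (at most 3 verbatim
sentences, global and topic modes, deterministic given the scorer) is
independent of how sentences are scored, and the contract — not the
scorer — is what the downstream synthesis relies on. A property test
swaps in a random scorer and verifies that only ranks change, never the
k/tie/extractive contracts. Both global and topic-focused summaries are
emitted side by side for every article.

## Deduplication

The unit is the distinct word trigram of the body (multiset repetition
inside one article does not inflate overlap). The overlap of a candidate
against a reference is `|candidate ∩ reference| / |candidate|` — the
fraction of the *candidate's* trigrams that are repeats — with a Jaccard
variant behind a flag. A single pass in the corpus's stable (published,
article_id) order removes an article when its overlap with some earlier
kept article reaches the threshold (default 0.30), attributing it to the
earliest such article; kept articles are never re-examined. Keeping the
earliest copy preserves first-report timestamps for the time series. An
exact inverted index (trigram → kept articles) makes the pass near-linear
for corpora with bounded syndication; the test suite anchors it to an
independently written quadratic pass.

## Country and time resolution

The gazetteer (CSV of surface form → ISO-3166 alpha-2) includes names,
aliases and demonyms; scanning is case-folded longest-match with
consumption, so "South Sudan" never also counts "Sudan". Resolution only
selects among the article's *existing* tags: a single tag is kept as-is;
multiple tags are ranked by title mentions, then body mentions, then
original tag order. Title dominance mirrors newsroom salience — the
country in the headline is the story's country — and makes the rule
deterministic. Articles whose tags are never mentioned stay
`"unresolved"`: they are excluded from per-country counts but retained in
global counts, which avoids arbitrary assignment. Time clustering is the
calendar month of publication.

## Coding and synthesis

The dictionary auto-coder assigns a code when any of its keywords occurs
(token-boundary, case-folded) in the summary text, title included. It is
an explicit stand-in for human deductive-inductive coding — it makes the
synthesis layer testable, and manual code files override it wherever
human judgment exists. Residual codes (e.g. "unspecified" vaccination
status) are assigned exactly when no sibling keyword code matched.

Numerical conventions:

* Percentages are rounded **half-up** to 1 decimal (2 via a flag);
  banker's rounding would disagree on exact `.05` boundaries with how
  frequency tables are conventionally printed. Percentage columns are
  conserved to within ±0.3 at 1-decimal rounding.
* Distribution-table rows are *code assignments*, not distinct articles:
  an article with two subevents counts once under each, and the theme
  total N is the assignment count.
* Affected counts enter via annotation fields (the generator plants
  them; real use requires manual entry). Free-text extraction of counts
  is out of scope because no reliable deterministic rule exists for it.
  Records lacking counts are excluded from sums and tallied separately.
* A standardized page is **300 words, floored** — the unique integer
  page size consistent with the published (word, page) funnel figures
  this convention was derived from. Word counting is whitespace
  tokenization over title + body by default (body-only via a flag; the
  choice is echoed in the run manifest, since published word totals
  rarely state whether titles are included).

## The synthetic corpus generator

The generator emulates the statistical structure the pipeline assumes,
not real news style:

* **Text** is built from subject–verb–object templates with slot-filled
  vocabulary pools (12–20 words per pool, at least two slots in every
  trigram window). This keeps generation deterministic and auditable,
  and it bounds the trigram overlap of *unrelated* articles to a few
  percent — far below the 0.30 duplicate threshold — while verbatim
  copies overlap fully.
* **Topics**: five deductive impact areas with disjoint 6-term lexicons.
  Monthly prevalence is a per-topic Gaussian bump over the 30-month
  window: infections/deaths and mental health peak in month 4,
  education in month 3, industrial action in month 6, and vaccination —
  modeled as the sharp rollout spike — in month 15 (March 2021 for the
  default window) with a 1-month standard deviation, which makes its
  peak month decisively recoverable at the default corpus size.
  Topic weights (0.24/0.30/0.12/0.22/0.12) and subevent mixes follow
  the relative frequencies of a published subevent distribution.
* **Planting**: the first three sentences of a topical article carry two
  lexicon terms each plus the subevent / factor / response keyword, so
  the reference scorer provably ranks them into the 3-sentence summary
  and the coding layer can recover the planted codes from summaries
  alone. Bodies are 15–21 sentences of ~20 words, so summarization
  reduces the corpus by slightly over 80% — the same order as published
  reduction funnels.
* **Duplicates**: selected articles gain one later-dated copy whose
  sentences are paraphrased independently with probability
  `mutation_rate` via a fixed synonym table (plus sentence reordering).
  The synonym vocabulary is disjoint from every source pool, so a fully
  paraphrased sentence shares essentially no trigram with its source: a
  copy's overlap is approximately the fraction of unmutated sentences.
* **Countries**: the true country is mentioned in the title and body;
  noise tags are added with probability `multi_tag_rate`, which makes
  the title-dominance resolution rule exactly recoverable.
* **Randomness**: one pseudo-random stream per concern (labels, text,
  tags, duplicates), all derived from the master seed — changing one
  knob does not perturb the others, and a fixed spec and seed reproduce
  a byte-identical corpus.

What the generator does **not** emulate: real lexical ambiguity
(polysemous topic terms, negated mentions), realistic outlet mixes,
cross-language duplicates, or any particular per-topic base rate of the
raw extract (the background fraction is chosen for test power). Passing
recovery tests therefore demonstrate that the pipeline implements its
contracts correctly, not that the rules would achieve the same precision
on real news text — on real data the validation sampling step exists
precisely because precision must be measured, not assumed.

## Problem sizes and runtime

The default study profile is 2,000 base articles (~2,160 with injected
copies); the end-to-end reproducibility check runs at 5,000. Oracle
equivalence suites use ~200 articles × 20 fuzzed rule sets (rule
engine) and ~500 articles (deduplication vs the quadratic pass); these
sizes give exhaustive coverage of the matching semantics while keeping
a full test run in the minutes range on one CPU.

## Known limitations

* Whole-token matching means morphological variants must be spelled out
  in lexicons and rule patterns (no stemming by default).
* The auto-coder cannot represent codes without keyword signatures
  (manual-only codes are supported but require a human code file).
* The 30% trigram rule is directional (candidate-denominated); two
  articles can each be non-duplicates of the other under Jaccard while
  one is removed under containment — the flag chooses the metric, the
  default follows the containment reading.
* Incremental/streaming ingestion is out of scope; re-runs are full
  re-runs over a date window.
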