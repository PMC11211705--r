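# Ground-truthed synthetic news corpora. Real media-monitoring extracts
# are not redistributable, so every downstream stage is exercised on
# generated corpora that emulate the statistical structure the pipeline
# assumes: topic articles with planted lexicon signals and time-varying
# prevalence, irrelevant background articles, syndicated near-duplicates,
# multi-country tagging noise, and subevent / affected-count annotations.
#
# Text is built from subject-verb-object templates with slot-filled
# vocabulary pools rather than language-model text: generation is
# deterministic, dependency-free and auditable. Slot pools are large
# enough (12-20 words, two slots in every trigram window) that unrelated
# articles share only a few percent of their trigrams — far below the 30%
# duplicate threshold — while verbatim copies share all of them.
# Paraphrase is synonym substitution from a fixed table (plus sentence
# reordering); the synonym vocabulary is disjoint from every source pool,
# so a fully paraphrased sentence shares essentially no trigram with its
# source and the trigram overlap of a copy is approximately the fraction
# of unmutated sentences.

## ---- fixed vocabulary -------------------------------------------------

# filler pools (sources) and their paraphrase partners; partner values are
# outside every source pool so paraphrased text cannot recreate source
# trigrams
nf_pools <- list(
  adj = c("weary", "dedicated", "seasoned", "overstretched", "veteran",
          "junior", "senior", "auxiliary", "visiting", "retired",
          "resident", "contracted", "frontline", "temporary", "permanent",
          "licensed", "certified", "trainee"),
  adj_syn = c("tired", "devoted", "experienced", "overburdened",
              "longserving", "novice", "elder", "supplementary", "touring",
              "emeritus", "inhouse", "hired", "firstline", "interim",
              "standing", "accredited", "validated", "apprenticed"),
  group = c("nurses", "doctors", "midwives", "clinicians", "paramedics",
            "pharmacists", "caregivers", "physicians", "surgeons",
            "dentists", "radiographers", "therapists", "technicians",
            "orderlies", "matrons", "interns", "registrars", "consultants"),
  group_syn = c("practitioners", "medics", "birthhelpers", "diagnosticians",
                "responders", "chemists", "custodians", "healers",
                "operators", "toothsmiths", "scanners", "counselors",
                "mechanics", "porters", "wardens", "residents2",
                "registrants", "advisers"),
  prep = c("near", "beside", "outside", "behind", "opposite", "within",
           "around", "beyond", "across", "underneath", "past", "inside"),
  prep_syn = c("proximate", "abutting", "exterior", "trailing", "facing",
               "interior", "encircling", "surpassing", "spanning",
               "beneath", "bygone", "indoors"),
  adj2 = c("rural", "urban", "regional", "coastal", "northern", "southern",
           "eastern", "western", "central", "suburban", "provincial",
           "metropolitan", "remote", "crowded", "modern", "aging", "busy",
           "quiet"),
  adj2_syn = c("pastoral", "citywide", "zonal", "seaside", "boreal",
               "austral", "oriental", "occidental", "middle", "periurban",
               "territorial", "megacity", "distant", "packed",
               "contemporary", "older", "hectic", "calm"),
  place = c("hospital", "clinic", "ward", "infirmary", "dispensary",
            "surgery", "pharmacy", "laboratory", "maternity", "facility",
            "institute", "polyclinic", "hospice", "sanatorium", "annexe",
            "outpost", "station", "compound"),
  place_syn = c("hub", "unit", "bay", "shelter", "depot", "theatre",
                "drugstore", "bench", "birthwing", "complex", "foundation",
                "villa", "refuge", "retreat", "wing", "camp", "post",
                "yard"),
  verb = c("described", "discussed", "mentioned", "addressed",
           "highlighted", "examined", "noted", "observed", "reviewed",
           "recounted", "detailed", "outlined", "assessed", "weighed",
           "chronicled", "debated", "questioned", "flagged"),
  verb_syn = c("depicted", "deliberated", "cited", "tackled", "underscored",
               "inspected", "remarked", "witnessed", "appraised",
               "narrated", "itemized", "sketched", "evaluated",
               "considered", "logged", "contested", "probed", "signalled"),
  obj = c("conditions", "arrangements", "circumstances", "developments",
          "pressures", "routines", "schedules", "logistics", "procedures",
          "supplies", "rosters", "caseloads", "budgets", "contracts",
          "transfers", "rotations", "briefings", "bulletins"),
  obj_syn = c("situations", "setups", "contexts", "trends", "strains",
              "habits", "timetables", "operations", "protocols",
              "stockpiles", "listings", "dockets", "finances", "accords",
              "moves", "cycles", "updates", "notices"),
  conj = c("regarding", "concerning", "about", "surrounding", "amid",
           "despite", "following", "after", "given", "citing", "per",
           "over"),
  conj_syn = c("respecting", "touching", "apropos", "enwrapping",
               "amongst", "notwithstanding", "succeeding", "preceding",
               "granted", "quoting", "via", "atop"),
  noun2 = c("managers", "officials", "administrators", "supervisors",
            "directors", "planners", "recruiters", "trainers", "assessors",
            "inspectors", "auditors", "advisors", "coordinators",
            "stewards", "spokespersons", "delegates", "messengers",
            "attendants"),
  noun2_syn = c("bosses", "officers", "clerks", "overseers", "heads",
                "schemers", "headhunters", "coaches", "graders",
                "checkers", "bookkeepers", "mentors", "organizers",
                "keepers", "announcers", "envoys", "couriers", "helpers"),
  tailverb = c("continued", "persisted", "escalated", "intensified",
               "lingered", "resurfaced", "subsided", "recurred", "widened",
               "deepened", "slowed", "shifted"),
  tailverb_syn = c("endured", "remained", "mounted", "heightened",
                   "loitered", "reappeared", "receded", "returned",
                   "broadened", "thickened", "decelerated", "drifted"),
  tailadv = c("locally", "nationwide", "steadily", "sharply", "gradually",
              "visibly", "notably", "widely", "quietly", "abruptly",
              "unevenly", "briefly"),
  tailadv_syn = c("regionally", "countrywide", "constantly", "steeply",
                  "slowly", "plainly", "markedly", "broadly", "softly",
                  "suddenly", "patchily", "momentarily"),
  bgnoun = c("tourism", "football", "elections", "rainfall", "traffic",
             "museums", "concerts", "festivals", "harvests", "cricket",
             "cinema", "fashion", "startups", "railways", "markets",
             "exports", "recycling", "astronomy"),
  bgnoun_syn = c("travel", "soccer", "ballots", "showers", "congestion",
                 "galleries", "recitals", "carnivals", "yields", "batting",
                 "films", "couture", "ventures", "trains", "bazaars",
                 "shipments", "composting", "stargazing"))

# fixed paraphrase table: every filler and structural word maps to a
# partner outside all source pools; topic lexicons, codebook keywords,
# numbers and country names are never substituted
nf_synonyms <- local({
  src <- c("the", "in", "involving",
           nf_pools$adj, nf_pools$group, nf_pools$prep, nf_pools$adj2,
           nf_pools$place, nf_pools$verb, nf_pools$obj, nf_pools$conj,
           nf_pools$noun2, nf_pools$tailverb, nf_pools$tailadv,
           nf_pools$bgnoun)
  dst <- c("yonder", "amidst", "encompassing",
           nf_pools$adj_syn, nf_pools$group_syn, nf_pools$prep_syn,
           nf_pools$adj2_syn, nf_pools$place_syn, nf_pools$verb_syn,
           nf_pools$obj_syn, nf_pools$conj_syn, nf_pools$noun2_syn,
           nf_pools$tailverb_syn, nf_pools$tailadv_syn,
           nf_pools$bgnoun_syn)
  stats::setNames(dst, src)
})

#' Default country pool for the generator
#'
#' Twenty countries whose names appear in the shipped gazetteer; the
#' generator plants the country name in the title and body of every
#' article.
#' @return tibble `iso2`, `name`.
#' @export
default_countries <- function() {
  tibble::tribble(
    ~iso2, ~name,
    "IN", "India",        "US", "United States", "GB", "United Kingdom",
    "ZA", "South Africa", "NG", "Nigeria",       "KE", "Kenya",
    "BR", "Brazil",       "FR", "France",        "DE", "Germany",
    "IT", "Italy",        "ES", "Spain",         "AU", "Australia",
    "CA", "Canada",       "JP", "Japan",         "PH", "Philippines",
    "MX", "Mexico",       "EG", "Egypt",         "PL", "Poland",
    "SE", "Sweden",       "TH", "Thailand")
}

# classification lexicons, one per deductive topic; disjoint from the
# codebook keyword vocabulary and from all filler pools
nf_lexicons <- list(
  infections_deaths = c("infection", "infections", "mortality",
                        "quarantine", "icu", "contagion"),
  mental_health = c("psychological", "wellbeing", "morale", "distress",
                    "coping", "resilience"),
  industrial_action = c("strike", "walkout", "protest", "picket", "union",
                        "demonstration"),
  vaccination = c("vaccine", "vaccination", "vaccinated", "immunization",
                  "jab", "inoculation"),
  education = c("curriculum", "internship", "residency", "faculty",
                "semester", "campus"))

#' Default topic lexicons
#'
#' Named list of classification keyword lexicons for the five deductive
#' impact areas (infections and deaths, mental health, industrial action,
#' vaccination, health professionals' education).
#' @return named list of character vectors.
#' @export
default_lexicons <- function() nf_lexicons

## ---- specs -------------------------------------------------------------

#' Topic specification for the generator
#'
#' @param topic_id topic identifier.
#' @param lexicon classification keywords planted into article sentences.
#' @param prevalence_curve non-negative per-month expected share (one
#'   value per month of the generation window; normalized internally).
#' @param subevent_mix named probabilities over subevent codes (must sum
#'   to 1 within 1e-9). Codes whose keyword is `NA` (residual codes like
#'   unspecified vaccination status) plant no keyword.
#' @param weight relative expected share of topical articles.
#' @param affected optional list `prob`, `meanlog`, `sdlog`, `kind`
#'   (`kind` may be a function of the subevent code) describing the
#'   per-article "number affected" model; `NULL` plants no counts.
#' @return a `topic_spec` list.
#' @export
topic_spec <- function(topic_id, lexicon, prevalence_curve, subevent_mix,
                       weight = 1, affected = NULL) {
  if (any(prevalence_curve < 0)) {
    stop("prevalence_curve values must be >= 0", call. = FALSE)
  }
  if (abs(sum(subevent_mix) - 1) > 1e-9) {
    stop("subevent_mix must sum to 1 (topic ", topic_id, ")", call. = FALSE)
  }
  structure(list(topic_id = topic_id, lexicon = lexicon,
                 prevalence_curve = prevalence_curve,
                 subevent_mix = subevent_mix, weight = weight,
                 affected = affected),
            class = "topic_spec")
}

gauss_curve <- function(n, peak, sd) {
  exp(-0.5 * ((seq_len(n) - peak) / sd)^2)
}

#' Default topic specifications
#'
#' Five topics over a 30-month window with Gaussian-bump prevalence
#' curves: infections/deaths and mental health peak in month 4 (April
#' 2020 for the default window), education in month 3, industrial action
#' in month 6, and vaccination — the sharp rollout spike — in month 15
#' (March 2021). Subevent mixes mirror the relative frequencies of a
#' published subevent distribution; affected-count models are lognormal
#' and only the three topics for which counts are reportable carry one.
#'
#' @param date_window generation window (defines the number of months).
#' @return named list of [topic_spec()] objects.
#' @export
default_topics <- function(date_window = c("2020-01-01", "2022-06-30")) {
  nm <- length(month_seq(date_window))
  norm <- function(x) x / sum(x)
  list(
    infections_deaths = topic_spec(
      "infections_deaths", nf_lexicons$infections_deaths,
      gauss_curve(nm, 4, 2),
      norm(c(sub_infections = .539, sub_deaths = .237, sub_both = .225)),
      weight = .24,
      affected = list(prob = .4, meanlog = 5, sdlog = 1.5,
                      kind = function(sub) if (identical(sub, "sub_deaths"))
                        "dead" else "infected")),
    mental_health = topic_spec(
      "mental_health", nf_lexicons$mental_health,
      gauss_curve(nm, 4, 3),
      norm(c(mh_anxiety = .143, mh_burnout = .180, mh_depression = .056,
             mh_exhaustion = .286, mh_sleep = .031, mh_stress = .205,
             mh_suicide = .021, mh_trauma = .079)),
      weight = .30),
    industrial_action = topic_spec(
      "industrial_action", nf_lexicons$industrial_action,
      gauss_curve(nm, 6, 2),
      norm(c(ia_demonstration = .510, ia_walkout = .064, ia_strike = .426)),
      weight = .12,
      affected = list(prob = .3, meanlog = 6, sdlog = 1.5,
                      kind = function(sub) "striking")),
    vaccination = topic_spec(
      "vaccination", nf_lexicons$vaccination,
      gauss_curve(nm, 15, 1),
      norm(c(vac_first = .314, vac_second = .160, vac_booster = .026,
             vac_unspecified = .500)),
      weight = .22,
      affected = list(prob = .3, meanlog = 8, sdlog = 1.5,
                      kind = function(sub) "vaccinated")),
    education = topic_spec(
      "education", nf_lexicons$education,
      gauss_curve(nm, 3, 1.5),
      norm(c(edu_exams = .168, edu_clinical = .307, edu_classes = .219,
             edu_celebrations = .036, edu_visa = .139, edu_other = .131)),
      weight = .12))
}

# keyword planted in the body for each subevent code (NA = residual code,
# nothing planted); must agree with the shipped codebook
nf_subevent_keywords <- c(
  sub_infections = "tested positive", sub_deaths = "passed away",
  sub_both = "casualty toll",
  mh_anxiety = "anxiety", mh_burnout = "burnout",
  mh_depression = "depression", mh_exhaustion = "exhaustion",
  mh_sleep = "insomnia", mh_stress = "stress", mh_suicide = "suicide",
  mh_trauma = "trauma",
  ia_demonstration = "rally", ia_walkout = "work stoppage",
  ia_strike = "downed tools",
  vac_first = "first dose", vac_second = "second dose",
  vac_booster = "booster", vac_unspecified = NA,
  edu_exams = "postponed", edu_clinical = "clinical placements",
  edu_classes = "classroom teaching",
  edu_celebrations = "commencement ceremony", edu_visa = "visa",
  edu_other = "accreditation")

nf_factor_keywords <- c(
  cf_remuneration = "wages", cf_ppe = "protective equipment",
  cf_workload = "workload", cf_staffing = "staffing",
  cf_risk = "hazard", cf_vaccine_safety = "side effects")

nf_response_keywords <- c(
  rs_pay = "salary increment", rs_therapy = "psychosocial support",
  rs_mandate = "mandate", rs_supply = "procurement",
  rs_discipline = "sanctions", rs_technology = "telemedicine")

#' Generation specification
#'
#' @param n_articles number of base articles (before duplicate
#'   injection).
#' @param date_window inclusive generation window.
#' @param topics named list of [topic_spec()]s; must be non-empty unless
#'   `background_fraction` is 1.
#' @param background_fraction proportion of irrelevant background
#'   articles.
#' @param duplicate_rate proportion of articles receiving a syndicated
#'   near-copy.
#' @param mutation_rate per-sentence paraphrase probability in a copy.
#' @param multi_tag_rate probability an article carries extra (noise)
#'   country tags beyond its true country.
#' @param multi_topic_rate probability a topical article carries a second
#'   planted topic.
#' @param lexicon_noise_rate probability a background article is salted
#'   with one random lexicon term (classification noise knob; 0 by
#'   default — the noise-free profile).
#' @param countries country pool tibble (`iso2`, `name`).
#' @param seed master seed; one derived stream per concern (labels, text,
#'   tags, duplicates).
#' @return a `generation_spec`.
#' @export
generation_spec <- function(n_articles = 2000L,
                            date_window = c("2020-01-01", "2022-06-30"),
                            topics = default_topics(date_window),
                            background_fraction = 0.3,
                            duplicate_rate = 0.08,
                            mutation_rate = 0.1,
                            multi_tag_rate = 0.25,
                            multi_topic_rate = 0.1,
                            lexicon_noise_rate = 0,
                            countries = default_countries(),
                            seed = 1L) {
  date_window <- as.Date(date_window)
  if (length(date_window) != 2L || anyNA(date_window) ||
      date_window[1L] > date_window[2L]) {
    stop("empty or invalid date window", call. = FALSE)
  }
  props <- c(background_fraction = background_fraction,
             duplicate_rate = duplicate_rate, mutation_rate = mutation_rate,
             multi_tag_rate = multi_tag_rate,
             multi_topic_rate = multi_topic_rate,
             lexicon_noise_rate = lexicon_noise_rate)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad) > 0L) {
    stop("proportions must be in [0,1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (n_articles < 0) stop("n_articles must be >= 0", call. = FALSE)
  if (background_fraction < 1 && length(topics) == 0L) {
    stop("topics must be non-empty when background_fraction < 1",
         call. = FALSE)
  }
  nm <- length(month_seq(date_window))
  for (tp in topics) {
    if (length(tp$prevalence_curve) != nm) {
      stop("prevalence_curve of topic ", tp$topic_id, " has ",
           length(tp$prevalence_curve), " values for ", nm, " months",
           call. = FALSE)
    }
  }
  structure(list(n_articles = as.integer(n_articles),
                 date_window = date_window, topics = topics,
                 background_fraction = background_fraction,
                 duplicate_rate = duplicate_rate,
                 mutation_rate = mutation_rate,
                 multi_tag_rate = multi_tag_rate,
                 multi_topic_rate = multi_topic_rate,
                 lexicon_noise_rate = lexicon_noise_rate,
                 countries = countries, seed = as.integer(seed)),
            class = "generation_spec")
}

#' Read a generation spec from a YAML or JSON configuration file
#'
#' Scalar fields map directly onto [generation_spec()] arguments; topics
#' default to [default_topics()] for the configured window.
#' @param path configuration file.
#' @return a `generation_spec`.
#' @export
read_generation_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  window <- as.Date(unlist(cfg$date_window %||%
                             c("2020-01-01", "2022-06-30")))
  generation_spec(
    n_articles = cfg$n_articles %||% 2000L,
    date_window = window,
    background_fraction = cfg$background_fraction %||% 0.3,
    duplicate_rate = cfg$duplicate_rate %||% 0.08,
    mutation_rate = cfg$mutation_rate %||% 0.1,
    multi_tag_rate = cfg$multi_tag_rate %||% 0.25,
    multi_topic_rate = cfg$multi_topic_rate %||% 0.1,
    lexicon_noise_rate = cfg$lexicon_noise_rate %||% 0,
    seed = cfg$seed %||% 1L)
}

## ---- text construction -------------------------------------------------

pick <- function(pool, n = 1L) pool[sample.int(length(pool), n, replace = n > length(pool))]

# one template sentence; each salt (possibly multi-word) sits between two
# random slots so no trigram window is low-entropy
build_sentence <- function(salts = character(0), trailer = character(0)) {
  toks <- c("the", pick(nf_pools$adj), pick(nf_pools$group),
            pick(nf_pools$prep), "the", pick(nf_pools$adj2),
            pick(nf_pools$place), pick(nf_pools$verb), pick(nf_pools$obj))
  # pad to three slot chunks so sentences average ~20 words
  if (length(salts) < 3L) {
    salts <- c(salts, pick(nf_pools$bgnoun, 3L - length(salts)))
  }
  for (s in salts) {
    toks <- c(toks, pick(nf_pools$conj), strsplit(s, " ")[[1]],
              pick(nf_pools$noun2))
  }
  toks <- c(toks, trailer, pick(nf_pools$tailverb), pick(nf_pools$tailadv))
  sent <- paste(toks, collapse = " ")
  paste0(toupper(substr(sent, 1L, 1L)), substr(sent, 2L, nchar(sent)), ".")
}

build_title <- function(country_name, signal = NULL) {
  toks <- c(country_name, pick(nf_pools$group), pick(nf_pools$verb),
            pick(nf_pools$obj),
            if (!is.null(signal)) c(pick(nf_pools$conj), signal)
            else pick(nf_pools$tailadv))
  paste(toks, collapse = " ")
}

build_body <- function(topic, lexicon, subevent_kw, factor_kw, response_kw,
                       secondary_lexicon, country_name, affected_count,
                       noise_term, n_sentences) {
  sents <- character(0)
  if (is.null(lexicon)) {
    # background article: neutral sentences only, optional lexicon noise
    sents <- vapply(seq_len(n_sentences), function(i) build_sentence(),
                    character(1))
    if (!is.null(noise_term)) {
      slot <- sample.int(n_sentences, 1L)
      sents[[slot]] <- build_sentence(salts = noise_term)
    }
    return(paste(sents, collapse = " "))
  }
  lex <- sample(lexicon)  # all six terms, shuffled
  trailer1 <- c("in", strsplit(country_name, " ")[[1]])
  if (!is.na(affected_count)) {
    trailer1 <- c("involving", format(affected_count, big.mark = ",",
                                      scientific = FALSE),
                  pick(nf_pools$group), trailer1)
  }
  s0 <- build_sentence(salts = c(lex[1:2],
                                 if (!is.na(subevent_kw)) subevent_kw))
  s1 <- build_sentence(salts = c(lex[3:4], factor_kw), trailer = trailer1)
  s2 <- build_sentence(salts = c(lex[5:6], response_kw))
  sents <- c(s0, s1, s2)
  if (!is.null(secondary_lexicon)) {
    sents <- c(sents, build_sentence(salts = sample(secondary_lexicon, 2L)))
  }
  n_rest <- max(0L, n_sentences - length(sents))
  rest <- vapply(seq_len(n_rest), function(i) {
    if (stats::runif(1) < 0.5) build_sentence(salts = pick(lexicon))
    else build_sentence()
  }, character(1))
  paste(c(sents, rest), collapse = " ")
}

# token-wise synonym substitution; signal terms, numbers and country
# names have no table entry and survive verbatim
paraphrase_sentence <- function(text) {
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  out <- vapply(words, function(w) {
    core <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", w)
    syn <- nf_synonyms[tolower(core)]
    if (is.na(syn)) return(w)
    pre <- sub("^([[:punct:]]*).*$", "\\1", w)
    post <- sub("^.*?([[:punct:]]*)$", "\\1", sub(core, "", w, fixed = TRUE))
    paste0(pre, syn, post)
  }, character(1), USE.NAMES = FALSE)
  sent <- paste(out, collapse = " ")
  paste0(toupper(substr(sent, 1L, 1L)), tolower(substr(sent, 2L, 2L)),
         substr(sent, 3L, nchar(sent)))
}

## ---- generation --------------------------------------------------------

empty_truth <- function() {
  tibble::tibble(article_id = character(0), background = logical(0),
                 topics = list(), primary_topic = character(0),
                 subevent = character(0), factor_code = character(0),
                 response_code = character(0), country = character(0),
                 month = character(0), affected_count = numeric(0),
                 affected_kind = character(0), duplicate_of = character(0))
}

#' Generate a ground-truthed synthetic corpus
#'
#' Labels (topics, months, subevents, countries, affected counts), text,
#' tag noise and duplicate injection each consume their own random stream
#' derived from the master seed, so changing one knob does not perturb
#' the others. A fixed spec and seed reproduce a byte-identical corpus.
#'
#' @param spec a [generation_spec()].
#' @return list with `corpus` (a [news_corpus()]) and `truth` (tibble:
#'   `article_id`, `background`, `topics` (list), `primary_topic`,
#'   `subevent`, `factor_code`, `response_code`, `country`, `month`,
#'   `affected_count`, `affected_kind`, `duplicate_of`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generation_spec"))
  n <- spec$n_articles
  months <- month_seq(spec$date_window)
  if (n == 0L) {
    return(list(corpus = news_corpus(empty_article_table(),
                                     date_window = spec$date_window),
                truth = empty_truth()))
  }
  seeds <- withr::with_seed(spec$seed, sample.int(2147483647L, 4L))
  topics <- spec$topics
  topic_ids <- vapply(topics, `[[`, character(1), "topic_id")

  ## stream 1: labels -----------------------------------------------------
  lab <- withr::with_seed(seeds[[1L]], {
    background <- stats::runif(n) < spec$background_fraction
    primary <- rep(NA_character_, n)
    secondary <- rep(NA_character_, n)
    month_idx <- integer(n)
    subevent <- rep(NA_character_, n)
    factor_code <- rep(NA_character_, n)
    response_code <- rep(NA_character_, n)
    affected_count <- rep(NA_real_, n)
    affected_kind <- rep(NA_character_, n)
    noise_term <- rep(NA_character_, n)
    lab_idx <- which(!background)
    if (length(lab_idx) > 0L) {
      w <- vapply(topics, `[[`, numeric(1), "weight")
      primary[lab_idx] <- sample(topic_ids, length(lab_idx), replace = TRUE,
                                 prob = w / sum(w))
      for (tid in topic_ids) {
        rows <- lab_idx[primary[lab_idx] == tid]
        if (length(rows) == 0L) next
        tp <- topics[[match(tid, topic_ids)]]
        p <- tp$prevalence_curve / sum(tp$prevalence_curve)
        month_idx[rows] <- sample.int(length(months), length(rows),
                                      replace = TRUE, prob = p)
        subevent[rows] <- sample(names(tp$subevent_mix), length(rows),
                                 replace = TRUE, prob = tp$subevent_mix)
        if (!is.null(tp$affected)) {
          has <- stats::runif(length(rows)) < tp$affected$prob
          cnt <- pmax(1, round(stats::rlnorm(sum(has), tp$affected$meanlog,
                                             tp$affected$sdlog)))
          affected_count[rows[has]] <- cnt
          affected_kind[rows[has]] <- vapply(subevent[rows[has]],
                                             tp$affected$kind, character(1))
        }
      }
      if (length(topic_ids) > 1L) {
        sec <- lab_idx[stats::runif(length(lab_idx)) < spec$multi_topic_rate]
        secondary[sec] <- vapply(sec, function(i) {
          sample(setdiff(topic_ids, primary[[i]]), 1L)
        }, character(1))
      }
      factor_rows <- lab_idx[stats::runif(length(lab_idx)) < 0.6]
      factor_code[factor_rows] <- sample(names(nf_factor_keywords),
                                         length(factor_rows), replace = TRUE)
      resp_rows <- lab_idx[stats::runif(length(lab_idx)) < 0.6]
      response_code[resp_rows] <- sample(names(nf_response_keywords),
                                         length(resp_rows), replace = TRUE)
    }
    bg_idx <- which(background)
    month_idx[bg_idx] <- sample.int(length(months), length(bg_idx),
                                    replace = TRUE)
    if (spec$lexicon_noise_rate > 0 && length(bg_idx) > 0L) {
      noisy <- bg_idx[stats::runif(length(bg_idx)) < spec$lexicon_noise_rate]
      all_terms <- unlist(lapply(topics, `[[`, "lexicon"), use.names = FALSE)
      noise_term[noisy] <- sample(all_terms, length(noisy), replace = TRUE)
    }
    country_row <- sample.int(nrow(spec$countries), n, replace = TRUE)
    # uniform day within the month, clamped to the window
    first <- as.Date(paste0(months[month_idx], "-01"))
    ndays <- as.integer(format(as.Date(first + 31 -
      as.integer(format(first + 31, "%d"))), "%d"))
    day <- 1L + floor(stats::runif(n) * ndays)
    published <- pmin(pmax(as.Date(sprintf("%s-%02d", months[month_idx],
                                           day)),
                           spec$date_window[1L]), spec$date_window[2L])
    list(background = background, primary = primary, secondary = secondary,
         subevent = subevent, factor_code = factor_code,
         response_code = response_code, affected_count = affected_count,
         affected_kind = affected_kind, noise_term = noise_term,
         country_row = country_row, published = published)
  })

  ## stream 2: text -------------------------------------------------------
  cn <- spec$countries$name[lab$country_row]
  txt <- withr::with_seed(seeds[[2L]], {
    titles <- character(n)
    bodies <- character(n)
    for (i in seq_len(n)) {
      if (lab$background[[i]]) {
        titles[[i]] <- build_title(cn[[i]])
        bodies[[i]] <- build_body(
          topic = NULL, lexicon = NULL, subevent_kw = NA, factor_kw = NULL,
          response_kw = NULL, secondary_lexicon = NULL,
          country_name = cn[[i]], affected_count = NA,
          noise_term = if (is.na(lab$noise_term[[i]])) NULL else
            lab$noise_term[[i]],
          n_sentences = sample(15:21, 1L))
      } else {
        tp <- topics[[match(lab$primary[[i]], topic_ids)]]
        titles[[i]] <- build_title(cn[[i]], signal = pick(tp$lexicon))
        bodies[[i]] <- build_body(
          topic = tp$topic_id, lexicon = tp$lexicon,
          subevent_kw = nf_subevent_keywords[[lab$subevent[[i]]]],
          factor_kw = if (is.na(lab$factor_code[[i]])) NULL else
            nf_factor_keywords[[lab$factor_code[[i]]]],
          response_kw = if (is.na(lab$response_code[[i]])) NULL else
            nf_response_keywords[[lab$response_code[[i]]]],
          secondary_lexicon = if (is.na(lab$secondary[[i]])) NULL else
            topics[[match(lab$secondary[[i]], topic_ids)]]$lexicon,
          country_name = cn[[i]],
          affected_count = lab$affected_count[[i]],
          noise_term = NULL,
          n_sentences = sample(15:21, 1L))
      }
    }
    list(titles = titles, bodies = bodies)
  })

  ## stream 3: country tags and sources ------------------------------------
  tags <- withr::with_seed(seeds[[3L]], {
    iso <- spec$countries$iso2
    lapply(seq_len(n), function(i) {
      tg <- iso[[lab$country_row[[i]]]]
      if (stats::runif(1) < spec$multi_tag_rate && length(iso) > 1L) {
        extra <- sample(setdiff(iso, tg), sample(1:2, 1L))
        tg <- sample(c(tg, extra))
      }
      tg
    })
  })
  sources <- withr::with_seed(seeds[[3L]] + 1L,
                              sprintf("outlet-%02d", sample.int(40L, n,
                                                                replace = TRUE)))

  ids <- sprintf("a%06d", seq_len(n))
  corpus <- news_corpus(tibble::tibble(
    article_id = ids, title = txt$titles, body = txt$bodies,
    published = lab$published, source = sources, country_tags = tags,
    language = "en"), date_window = spec$date_window)
  truth <- tibble::tibble(
    article_id = ids, background = lab$background,
    topics = lapply(seq_len(n), function(i) {
      if (lab$background[[i]]) character(0) else
        c(lab$primary[[i]],
          if (!is.na(lab$secondary[[i]])) lab$secondary[[i]])
    }),
    primary_topic = lab$primary, subevent = lab$subevent,
    factor_code = lab$factor_code, response_code = lab$response_code,
    country = spec$countries$iso2[lab$country_row],
    month = month_bucket(lab$published),
    affected_count = lab$affected_count,
    affected_kind = lab$affected_kind,
    duplicate_of = NA_character_)

  ## stream 4: syndicated near-duplicates ---------------------------------
  if (spec$duplicate_rate > 0) {
    dup <- inject_duplicates(corpus, truth, spec$duplicate_rate,
                             spec$mutation_rate, seed = seeds[[4L]])
    corpus <- dup$corpus
    truth <- dup$truth
  }
  list(corpus = corpus, truth = truth)
}

#' Inject syndicated near-duplicate copies into a corpus
#'
#' Each selected source article gains one later-dated copy: sentences are
#' paraphrased independently with probability `mutation_rate` via the
#' fixed synonym table, and (when any mutation is possible) the copy's
#' sentence order is shuffled. At `mutation_rate = 0` copies are
#' verbatim. The ground truth records the duplicate-of link (always to
#' the earlier, original article).
#'
#' @param corpus a [news_corpus()].
#' @param truth ground-truth tibble parallel to `corpus` (may be the
#'   [empty_truth] shape for externally built corpora).
#' @param duplicate_rate per-article probability of receiving a copy.
#' @param mutation_rate per-sentence paraphrase probability.
#' @param seed integer seed for the duplicate stream.
#' @return list with `corpus` and `truth` including the copies.
#' @export
inject_duplicates <- function(corpus, truth, duplicate_rate, mutation_rate,
                              seed = 1L) {
  if (duplicate_rate < 0 || duplicate_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must be in [0,1]", call. = FALSE)
  }
  if (duplicate_rate == 0 || nrow(corpus) == 0L) {
    return(list(corpus = corpus, truth = truth))
  }
  window <- attr(corpus, "date_window")
  new_rows <- withr::with_seed(seed, {
    src <- which(stats::runif(nrow(corpus)) < duplicate_rate)
    lapply(src, function(i) {
      split <- split_sentences(corpus$body[[i]])
      sents <- split$text
      if (mutation_rate > 0 && length(sents) > 0L) {
        mutate <- stats::runif(length(sents)) < mutation_rate
        sents[mutate] <- vapply(sents[mutate], paraphrase_sentence,
                                character(1), USE.NAMES = FALSE)
        sents <- sents[sample.int(length(sents))]
      }
      pub <- min(corpus$published[[i]] + sample(1:6, 1L), window[2L])
      tibble::tibble(article_id = paste0(corpus$article_id[[i]], "-syn"),
                     title = corpus$title[[i]],
                     body = paste(sents, collapse = " "),
                     published = pub,
                     source = paste0(corpus$source[[i]], "-wire"),
                     country_tags = corpus$country_tags[i],
                     language = corpus$language[[i]],
                     .src = corpus$article_id[[i]])
    })
  })
  if (length(new_rows) == 0L) {
    return(list(corpus = corpus, truth = truth))
  }
  copies <- dplyr::bind_rows(new_rows)
  corpus2 <- news_corpus(dplyr::bind_rows(
    tibble::as_tibble(corpus),
    copies[setdiff(names(copies), ".src")]), date_window = window)
  truth_by_id <- truth[match(copies$.src, truth$article_id), , drop = FALSE]
  truth_copies <- truth_by_id
  truth_copies$article_id <- copies$article_id
  truth_copies$month <- month_bucket(copies$published)
  truth_copies$duplicate_of <- copies$.src
  list(corpus = corpus2, truth = dplyr::bind_rows(truth, truth_copies))
}

#' Write / read ground truth as JSON Lines keyed by article id
#'
#' @param truth ground-truth tibble from [generate_corpus()].
#' @param path output path.
#' @return `path` (write) or the truth tibble (read), invisibly for
#'   write.
#' @export
write_ground_truth <- function(truth, path) {
  lines <- vapply(seq_len(nrow(truth)), function(i) {
    jsonlite::toJSON(list(
      article_id = truth$article_id[[i]],
      background = truth$background[[i]],
      topics = I(truth$topics[[i]]),
      primary_topic = truth$primary_topic[[i]],
      subevent = truth$subevent[[i]],
      factor_code = truth$factor_code[[i]],
      response_code = truth$response_code[[i]],
      country = truth$country[[i]],
      month = truth$month[[i]],
      affected_count = truth$affected_count[[i]],
      affected_kind = truth$affected_kind[[i]],
      duplicate_of = truth$duplicate_of[[i]]),
      auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    tibble::tibble(
      article_id = rec$article_id, background = rec$background,
      topics = list(as.character(unlist(rec$topics))),
      primary_topic = rec$primary_topic %||% NA_character_,
      subevent = rec$subevent %||% NA_character_,
      factor_code = rec$factor_code %||% NA_character_,
      response_code = rec$response_code %||% NA_character_,
      country = rec$country, month = rec$month,
      affected_count = rec$affected_count %||% NA_real_,
      affected_kind = rec$affected_kind %||% NA_character_,
      duplicate_of = rec$duplicate_of %||% NA_character_)
  })
  dplyr::bind_rows(rows)
}
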