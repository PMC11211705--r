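test_that("distribution tables reproduce printed-style percentages", {
  # infection/death frequencies
  infd <- distribution_table(c(infections = 307, deaths = 135, both = 128))
  expect_equal(infd$pct, c(53.9, 23.7, 22.5))
  expect_identical(attr(infd, "N"), 570L)
  # industrial action frequencies
  ia <- distribution_table(c(demo = 128, walkout = 16, strike = 107))
  expect_equal(ia$pct, c(51.0, 6.4, 42.6))
  # 2-decimal precision variant used in running text
  mh <- distribution_table(c(anxiety = 166, burnout = 209, depression = 65,
                             exhaustion = 332, sleep = 36, stress = 238,
                             suicide = 24, trauma = 92), digits = 2)
  expect_equal(mh$pct[mh$code == "exhaustion"], 28.57)
  expect_equal(mh$pct[mh$code == "stress"], 20.48)
  expect_equal(mh$pct[mh$code == "burnout"], 17.99)
  expect_equal(mh$pct[mh$code == "anxiety"], 14.29)
})

test_that("distribution table edge cases and conservation", {
  one <- distribution_table(c(only = 1))
  expect_equal(one$pct, 100.0)
  empty <- distribution_table(integer(0))
  expect_identical(attr(empty, "N"), 0L)
  expect_identical(nrow(empty), 0L)
  zero <- distribution_table(c(a = 0L, b = 0L))
  expect_identical(attr(zero, "N"), 0L)
  withr::with_seed(11, {
    for (rep in 1:20) {
      counts <- stats::setNames(sample.int(400, 6),
                                paste0("c", 1:6))
      tab <- distribution_table(counts)
      expect_identical(sum(tab$n), as.integer(attr(tab, "N")))
      expect_gte(sum(tab$pct), 99.7)
      expect_lte(sum(tab$pct), 100.3)
    }
  })
})

test_that("auto-coding recovers planted subevents, factors and responses", {
  run <- coding_run()
  truth <- run$gen$truth
  codes <- run$codes
  # primary-topic subevent codes match truth exactly
  lab <- truth[!truth$background & !is.na(truth$subevent), ]
  for (i in seq_len(nrow(lab))) {
    got <- codes$code[codes$article_id == lab$article_id[[i]] &
                        codes$theme == "area_of_impact" &
                        codes$topic_id == lab$primary_topic[[i]]]
    if (lab$primary_topic[[i]] == "vaccination" &&
        lab$subevent[[i]] == "vac_unspecified") {
      expect_identical(got, "vac_unspecified")
    } else {
      expect_true(lab$subevent[[i]] %in% got)
    }
  }
  # factor and response codes match truth
  fac <- truth[!truth$background & !is.na(truth$factor_code), ]
  for (i in seq_len(nrow(fac))) {
    got <- unique(codes$code[codes$article_id == fac$article_id[[i]] &
                               codes$theme == "contributing_factor"])
    expect_identical(got, fac$factor_code[[i]])
  }
  # unmatched summaries produce no rows rather than empty codes
  bg_summ <- tibble::tibble(article_id = "bg", mode = "topic:vaccination",
                            title = "plain", indices = list(0L),
                            scores = list(1), text = "Nothing to see here.",
                            n_sentences = 1L)
  got_bg <- apply_codebook(bg_summ, read_codebook())
  expect_identical(got_bg$code, "vac_unspecified")  # residual only
})

test_that("manual code files override auto codes and are validated", {
  cb <- read_codebook()
  summ <- tibble::tibble(article_id = c("x", "y"),
                         mode = "topic:mental_health", title = "",
                         indices = list(0L), scores = list(1),
                         text = c("Reports of burnout rose.",
                                  "Stress levels climbed."),
                         n_sentences = 1L)
  auto <- apply_codebook(summ, cb)
  expect_identical(auto$code[auto$article_id == "x"], "mh_burnout")
  manual <- tibble::tibble(article_id = "x", code = "mh_suicide")
  over <- apply_codebook(summ, cb, manual_codes = manual)
  expect_identical(over$code[over$article_id == "x"], "mh_suicide")
  expect_identical(over$code[over$article_id == "y"], "mh_stress")
  expect_error(apply_codebook(summ, cb, manual_codes = tibble::tibble(
    article_id = "x", code = "not_a_code")), "unknown code")
})

test_that("affected sums aggregate per kind and year with exclusions", {
  rec <- tibble::tibble(
    article_id = c("a", "b", "c", "d"),
    topic_id = "industrial_action", theme = "area_of_impact",
    code = "ia_strike", country = "IN",
    month = c("2020-01", "2020-11", "2021-02", "2020-05"),
    affected_count = c(3500000, 110735, 43000, NA),
    affected_kind = c("striking", "striking", "striking", NA))
  out <- affected_sums(rec)
  strike_2020 <- out$table$total[out$table$year == "2020"]
  expect_equal(strike_2020, 3610735)
  expect_equal(out$table$total[out$table$year == "2021"], 43000)
  expect_identical(out$excluded, 1L)
  none <- affected_sums(rec[4, ])
  expect_identical(nrow(none$table), 0L)
  expect_identical(none$excluded, 1L)
  bad <- rec
  bad$affected_count[1] <- -5
  expect_error(affected_sums(bad), "negative")
  # planted synthetic totals equal brute-force sums over distinct articles
  gen <- default_gen()
  truth <- gen$truth
  rec2 <- tibble::tibble(article_id = truth$article_id,
                         topic_id = truth$primary_topic, theme = "area_of_impact",
                         code = truth$subevent, country = truth$country,
                         month = truth$month,
                         affected_count = truth$affected_count,
                         affected_kind = truth$affected_kind)
  out2 <- affected_sums(rec2)
  for (r in seq_len(nrow(out2$table))) {
    k <- out2$table$affected_kind[[r]]
    y <- out2$table$year[[r]]
    manual <- sum(truth$affected_count[!is.na(truth$affected_kind) &
                                         truth$affected_kind == k &
                                         substr(truth$month, 1, 4) == y])
    expect_equal(out2$table$total[[r]], manual)
  }
})

test_that("monthly series conserve counts and fill zero months", {
  months <- month_seq(c("2020-01-01", "2020-06-30"))
  rec <- tibble::tibble(article_id = c("a", "a", "b", "c"),
                        topic_id = c("t1", "t1", "t1", "t2"),
                        theme = "area_of_impact", code = c("k1", "k2", "k1", "k3"),
                        country = "IN",
                        month = c("2020-02", "2020-02", "2020-02", "2020-05"),
                        affected_count = NA_real_,
                        affected_kind = NA_character_)
  ser <- monthly_series(rec, months = months)
  expect_identical(nrow(ser), length(months) * 2L)
  # article `a` carries two codes but counts once
  expect_identical(ser$n[ser$month == "2020-02" & ser$topic_id == "t1"], 2L)
  expect_identical(sum(ser$n[ser$topic_id == "t1"]), 2L)
  expect_identical(sum(ser$n == 0L), 10L)
  empty <- monthly_series(rec[0, ], topic = "t1", months = months)
  expect_identical(sum(empty$n), 0L)
  expect_identical(nrow(empty), length(months))
})

test_that("country coverage counts distinct resolved countries", {
  rec <- tibble::tibble(article_id = c("a", "b", "c", "d"),
                        topic_id = "t1", theme = "area_of_impact",
                        code = "k", country = c("IN", "IN", "US", "unresolved"),
                        month = "2020-01", affected_count = NA_real_,
                        affected_kind = NA_character_)
  expect_identical(country_coverage(rec), 2L)
  expect_identical(country_coverage(rec[rec$country == "unresolved", ]), 0L)
  gen <- generate_corpus(generation_spec(n_articles = 50, seed = 47))
  truth <- gen$truth
  rec2 <- tibble::tibble(article_id = truth$article_id,
                         topic_id = truth$primary_topic,
                         theme = "area_of_impact", code = truth$subevent,
                         country = truth$country, month = truth$month,
                         affected_count = NA_real_, affected_kind = NA_character_)
  expect_identical(country_coverage(rec2),
                   length(unique(truth$country)))
})

test_that("co-occurrence cells equal brute-force pairwise counts", {
  disjoint <- tibble::tibble(
    article_id = c("a", "b"), topic_id = c("t1", NA),
    theme = c("area_of_impact", "contributing_factor"),
    code = c(NA, "f1"), country = "IN", month = "2020-01",
    affected_count = NA_real_, affected_kind = NA_character_)
  z <- cooccurrence_matrix(disjoint, axis_a = "f1", axis_b = "t1")
  expect_identical(sum(z$matrix), 0L)
  one <- tibble::tibble(
    article_id = "a", topic_id = c("t1", "t2", "t1", "t2"),
    theme = "x", code = c("c1", "c1", "c2", "c2"), country = "IN",
    month = "2020-01", affected_count = NA_real_,
    affected_kind = NA_character_)
  m1 <- cooccurrence_matrix(one, axis_a = c("c1", "c2"),
                            axis_b = c("t1", "t2"))
  expect_true(all(m1$matrix == 1L))
  expect_true(all(m1$row_marginals == 1L))
  # random assignment vs O(n * |a| * |b|) oracle
  withr::with_seed(13, {
    rec <- tibble::tibble(
      article_id = sample(sprintf("a%02d", 1:25), 120, replace = TRUE),
      topic_id = sample(paste0("t", 1:4), 120, replace = TRUE),
      theme = "x", code = sample(paste0("c", 1:5), 120, replace = TRUE),
      country = "IN", month = "2020-01", affected_count = NA_real_,
      affected_kind = NA_character_)
  })
  mm <- cooccurrence_matrix(rec)
  for (a in rownames(mm$matrix)) {
    for (b in colnames(mm$matrix)) {
      ids_a <- unique(rec$article_id[rec$code == a])
      ids_b <- unique(rec$article_id[rec$topic_id == b])
      expect_identical(mm$matrix[a, b], length(intersect(ids_a, ids_b)))
      expect_lte(mm$matrix[a, b], min(mm$row_marginals[[a]],
                                      mm$col_marginals[[b]]))
    }
  }
})

test_that("stacked shares normalize to one per non-empty month", {
  rec <- tibble::tibble(article_id = c("a", "b", "c", "d"),
                        topic_id = "t", theme = "contributing_factor",
                        code = c("f1", "f1", "f1", "f2"), country = "IN",
                        month = c("2020-01", "2020-01", "2020-01", "2020-01"),
                        affected_count = NA_real_,
                        affected_kind = NA_character_)
  sh <- stacked_share_series(rec, months = c("2020-01", "2020-02"))
  jan <- sh[sh$month == "2020-01", ]
  expect_equal(sort(jan$share), c(0.25, 0.75))
  feb <- sh[sh$month == "2020-02", ]
  expect_true(all(feb$empty))
  expect_true(all(feb$share == 0))
  single <- stacked_share_series(rec[rec$code == "f1", ],
                                 months = "2020-01")
  expect_equal(single$share, 1.0)
  # synthetic data: every non-empty month sums to 1 within 1e-12
  run <- coding_run()
  rec2 <- assemble_records(run$codes, run$gen$corpus,
                           annotations = run$gen$truth)
  sh2 <- stacked_share_series(rec2[rec2$theme == "contributing_factor", ])
  sums <- tapply(sh2$share, sh2$month, sum)
  emp <- tapply(sh2$empty, sh2$month, all)
  expect_true(all(abs(sums[!emp] - 1) < 1e-12))
})
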