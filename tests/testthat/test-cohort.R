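day <- 1 / 365.25

test_that("eczema algorithm requires a diagnosis plus two therapy days", {
  ev <- function(classes, days) {
    data.frame(person_id = "p1", event_class = classes,
               event_age = 30 + days * day, stringsAsFactors = FALSE)
  }
  # diagnosis + therapies on days 100 and 250
  expect_true(apply_eczema_algorithm(
    ev(c("eczema_diagnosis", "eczema_therapy", "eczema_therapy"),
       c(0, 100, 250)))[["p1"]])
  # two therapies on the same day count once
  expect_false(apply_eczema_algorithm(
    ev(c("eczema_diagnosis", "eczema_therapy", "eczema_therapy"),
       c(0, 100, 100.4)))[["p1"]])
  # therapies alone never qualify
  expect_false(apply_eczema_algorithm(
    ev(rep("eczema_therapy", 5), c(1, 10, 20, 30, 40)))[["p1"]])
  # persons absent from the events are FALSE
  expect_false(apply_eczema_algorithm(ev("eczema_diagnosis", 0),
                                      person_ids = c("p1", "p2"))[["p2"]])
})

test_that("asthma algorithm is any-morbidity-code-ever", {
  ev <- data.frame(person_id = c("p1", "p2", "p2", "p2", "p3"),
                   event_class = c("asthma_morbidity", rep("asthma_morbidity", 3),
                                   "morbidity"),
                   event_age = c(30, 31, 32, 33, 40), stringsAsFactors = FALSE)
  got <- apply_asthma_algorithm(ev, person_ids = c("p1", "p2", "p3"))
  expect_identical(unname(got), c(TRUE, TRUE, FALSE))
})

test_that("exposure algorithms are monotone in the event set", {
  set.seed(42)
  classes <- c("morbidity", "eczema_diagnosis", "eczema_therapy", "asthma_morbidity")
  for (rep_i in 1:20) {
    n1 <- sample(1:6, 1)
    base_ev <- data.frame(person_id = "p1",
                          event_class = sample(classes, n1, replace = TRUE),
                          event_age = 20 + sample(0:5000, n1) * day,
                          stringsAsFactors = FALSE)
    extra <- data.frame(person_id = "p1",
                        event_class = sample(classes, 3, replace = TRUE),
                        event_age = 20 + sample(0:5000, 3) * day,
                        stringsAsFactors = FALSE)
    grown <- rbind(base_ev, extra)
    for (alg in list(apply_eczema_algorithm, apply_asthma_algorithm)) {
      before <- alg(base_ev, "p1")[["p1"]]
      after <- alg(grown, "p1")[["p1"]]
      expect_true(!before || after)
    }
  }
})

test_that("matching honours practice, sex and the 5-year age window", {
  pool <- data.frame(person_id = sprintf("c%02d", 1:6),
                     practice_id = c("g1", "g1", "g1", "g2", "g1", "g1"),
                     sex = c("female", "female", "male", "female", "female", "female"),
                     entry_age = c(40, 44.9, 40, 40, 46.1, 35.5),
                     stringsAsFactors = FALSE)
  exposed <- data.frame(person_id = "e1", practice_id = "g1", sex = "female",
                        entry_age = 40, stringsAsFactors = FALSE)
  m <- match_controls(exposed, pool, seed = 1)
  # c3 wrong sex, c4 wrong practice, c5 is 6.1 years older
  expect_true(all(m$control_id %in% c("c01", "c02", "c06")))
  expect_identical(nrow(m), 5L)
  # every emitted control satisfies all three constraints
  pm <- match(m$control_id, pool$person_id)
  expect_true(all(pool$practice_id[pm] == "g1"))
  expect_true(all(pool$sex[pm] == "female"))
  expect_true(all(abs(pool$entry_age[pm] - 40) <= 5))
})

test_that("matching handles degenerate pools", {
  exposed <- data.frame(person_id = c("e1", "e2"), practice_id = "g1",
                        sex = "female", entry_age = c(40, 80),
                        stringsAsFactors = FALSE)
  pool <- data.frame(person_id = "c1", practice_id = "g1", sex = "female",
                     entry_age = 41, stringsAsFactors = FALSE)
  expect_message(m <- match_controls(exposed, pool, seed = 1), "no eligible")
  # single eligible control is drawn all five times, with replacement
  expect_identical(m$control_id, rep("c1", 5))
  expect_identical(attr(m, "unmatched"), "e2")
})

test_that("first chapter records take the earliest event and its followup", {
  persons <- make_persons(2, entry_age = 20, end_age = 50)
  ev <- data.frame(person_id = c("p0001", "p0001", "p0001", "p0001"),
                   chapter = c("A", "A", "B", "B"),
                   event_class = "morbidity",
                   event_age = c(45, 30, 33, 33),
                   stringsAsFactors = FALSE)
  fr <- first_chapter_records(ev, persons)
  expect_identical(nrow(fr), 2L)
  a <- fr[fr$chapter == "A", ]
  expect_equal(a$first_age, 30)
  expect_equal(a$followup_from_first, 20)
  expect_equal(fr[fr$chapter == "B", ]$first_age, 33)  # ties collapse
  # person with no events contributes no rows
  expect_false("p0002" %in% fr$person_id)
})

test_that("first chapter records reject out-of-window events", {
  persons <- make_persons(1, entry_age = 30, end_age = 40)
  ev <- data.frame(person_id = "p0001", chapter = "A",
                   event_class = "morbidity", event_age = 45,
                   stringsAsFactors = FALSE)
  expect_error(first_chapter_records(ev, persons), "outside")
})

test_that("cohort percentages follow the table rounding rule", {
  expect_identical(cohort_percent(312098, 434422), 72)
  expect_identical(cohort_percent(115685, 434422, 1), 26.6)
  expect_identical(cohort_percent(0, 100), 0)
  expect_true(is.na(cohort_percent(0, 0)))
})

test_that("cohort summary recomputes exactly from its own counts", {
  pop <- generate_population(sim_config(n_practices = 4, persons_per_practice = 120,
                                        seed = 31))
  persons <- pop$persons
  persons$eczema_flag <- unname(apply_eczema_algorithm(pop$events, persons$person_id))
  persons$asthma_flag <- unname(apply_asthma_algorithm(pop$events, persons$person_id))
  fr <- first_chapter_records(pop$events, persons)
  sm <- summarize_cohort(persons, fr)
  for (cond in c("eczema", "asthma")) {
    for (grp in c("exposed", "control")) {
      sub <- sm[sm$condition == cond & sm$group == grp, ]
      total <- sub$count[sub$statistic == "total"]
      ch_rows <- sub[startsWith(sub$statistic, "chapter_"), ]
      expect_equal(ch_rows$percent, cohort_percent(ch_rows$count, total))
      ov <- sub[sub$statistic == "in_both_cohorts", ]
      expect_equal(ov$percent, cohort_percent(ov$count, total, 1))
    }
  }
  # algorithm-derived flags match the generator's ground truth
  expect_identical(persons$eczema_flag, persons$eczema_true)
  expect_identical(persons$asthma_flag, persons$asthma_true)
})

test_that("with null exposure effects, prevalence is balanced between groups", {
  cfg <- sim_config(n_practices = 6, persons_per_practice = 500,
                    exposure_effect = stats::setNames(rep(0, 19), read_chapters()),
                    seed = 77)
  pop <- generate_population(cfg)
  persons <- pop$persons
  persons$eczema_flag <- unname(apply_eczema_algorithm(pop$events, persons$person_id))
  fr <- first_chapter_records(pop$events, persons)
  has_A <- persons$person_id %in% fr$person_id[fr$chapter == "A"]
  p1 <- mean(has_A[persons$eczema_flag]); n1 <- sum(persons$eczema_flag)
  p0 <- mean(has_A[!persons$eczema_flag]); n0 <- sum(!persons$eczema_flag)
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  expect_lt(abs(p1 - p0), 3 * se + 1e-9)
})
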