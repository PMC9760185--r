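test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_practices = 4, persons_per_practice = 50, seed = 11)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$events, b$events)
  c2 <- generate_population(sim_config(n_practices = 4, persons_per_practice = 50,
                                       seed = 12))
  expect_false(identical(a$events, c2$events))
})

test_that("impossible chapters emit no morbidity events", {
  base <- stats::setNames(rep(-Inf, 19), read_chapters())
  cfg <- sim_config(n_practices = 2, persons_per_practice = 40,
                    chapter_base_logodds = base,
                    eczema_prevalence = 0, asthma_prevalence = 0, seed = 3)
  pop <- generate_population(cfg)
  expect_identical(sum(pop$events$event_class == "morbidity"), 0L)
})

test_that("marginal chapter prevalence matches the logistic model", {
  # copula margins are exact; check a common and a rare chapter at sigma 0
  cfg <- sim_config(n_practices = 10, persons_per_practice = 800,
                    practice_sd = 0, dependence = 0.4,
                    chapter_age_slope = stats::setNames(rep(0, 19), read_chapters()),
                    chapter_sex_effect = stats::setNames(rep(0, 19), read_chapters()),
                    eczema_prevalence = 0, asthma_prevalence = 0, seed = 21)
  pop <- generate_population(cfg)
  n <- nrow(pop$persons)
  for (cc in c("A", "Q")) {
    p_true <- plogis(cfg$chapter_base_logodds[[cc]])
    p_hat <- sum(pop$events$chapter == cc & pop$events$event_class == "morbidity") / n
    mc_sd <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * mc_sd)
  }
})

test_that("pregnancy-chapter events never occur for men", {
  cfg <- sim_config(n_practices = 6, persons_per_practice = 300, seed = 5)
  pop <- generate_population(cfg)
  males <- pop$persons$person_id[pop$persons$sex == "male"]
  l_events <- pop$events[pop$events$chapter == "L" &
                           pop$events$event_class == "morbidity", ]
  expect_length(intersect(l_events$person_id, males), 0)
  expect_gt(nrow(l_events), 0)
})

test_that("event ages stay inside each person's followup window", {
  pop <- generate_population(sim_config(n_practices = 4, persons_per_practice = 100,
                                        seed = 9))
  m <- match(pop$events$person_id, pop$persons$person_id)
  expect_true(all(pop$events$event_age >= pop$persons$entry_age[m] - 1e-9))
  expect_true(all(pop$events$event_age <= pop$persons$end_age[m] + 1e-9))
})

test_that("empirical Jaccard increases with the latent dependence", {
  base <- stats::setNames(rep(-Inf, 19), read_chapters())
  base[c("A", "B")] <- 0
  jac <- vapply(c(0, 0.25, 0.5, 0.75), function(rho) {
    cfg <- sim_config(n_practices = 5, persons_per_practice = 2000,
                      practice_sd = 0, dependence = rho,
                      chapter_base_logodds = base,
                      chapter_age_slope = stats::setNames(rep(0, 19), read_chapters()),
                      chapter_sex_effect = stats::setNames(rep(0, 19), read_chapters()),
                      eczema_prevalence = 0, asthma_prevalence = 0, seed = 100)
    pop <- generate_population(cfg)
    fr <- first_chapter_records(pop$events, pop$persons)
    empirical_jaccard(fr, "A", "B")
  }, numeric(1))
  expect_true(all(diff(jac) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_practices = 0), "positive")
  expect_error(sim_config(dependence = 1), "dependence")
  expect_error(sim_config(dependence = -0.1), "dependence")
  expect_error(sim_config(age_range = c(10, 80)), "age_range")
  expect_error(sim_config(chapter_base_logodds = c(A = 0)), "19 chapters")
})

test_that("configuration round-trips through YAML", {
  cfg <- sim_config(n_practices = 3, persons_per_practice = 10, seed = 2,
                    dependence = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  expect_identical(generate_population(cfg)$events,
                   generate_population(cfg2)$events)
})

test_that("direct pair simulator matches closed-form outcome means", {
  d0 <- generate_pair_glmm_dataset(glmm_truth(), n = 40000, n_practices = 10,
                                   seed = 1)
  expect_gt(mean(d0$y), 0.49)
  expect_lt(mean(d0$y), 0.51)

  d1 <- generate_pair_glmm_dataset(glmm_truth(beta0 = -2, beta_f = 0.2),
                                   n = 10000, n_practices = 10,
                                   covariate_ranges = list(f = c(5, 5), a = c(18, 80)),
                                   seed = 2)
  expect_lt(abs(mean(d1$y) - plogis(-1)), 0.01)
})

test_that("practice heterogeneity shows up at sigma_u = 1 without moving the margin", {
  d <- generate_pair_glmm_dataset(glmm_truth(sigma_u = 1), n = 10000,
                                  n_practices = 50, seed = 3)
  marginal <- integrate(function(u) plogis(u) * dnorm(u), -10, 10)$value
  expect_lt(abs(mean(d$y) - marginal), 0.02)
  practice_means <- tapply(d$y, d$p, mean)
  expect_gt(sd(practice_means), 0.15)
})

test_that("pair simulator validates its counts", {
  expect_error(generate_pair_glmm_dataset(glmm_truth(), n = 5, n_practices = 10),
               "n >= n_practices")
  expect_error(glmm_truth(sigma_u = -1), "non-negative")
})
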