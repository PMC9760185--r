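test_that("pair enumeration covers all unordered pairs in order", {
  p19 <- enumerate_pairs()
  expect_identical(nrow(p19), 171L)
  expect_true(all(p19$chapter1 < p19$chapter2))
  expect_false(any(duplicated(paste(p19$chapter1, p19$chapter2))))
  expect_identical(nrow(enumerate_pairs(c("A", "B"))), 1L)
  expect_identical(nrow(enumerate_pairs(c("D", "C", "B", "A"))), 6L)
  expect_error(enumerate_pairs(c("A", "A", "B")), "duplicate")
})

test_that("union restriction and the both-chapters outcome", {
  # 4 persons with both chapters, 3 only A, 3 only B, 5 with neither
  persons <- make_persons(15, entry_age = 20, end_age = 60)
  persons$eczema_flag <- rep(c(TRUE, FALSE, FALSE), 5)
  fr <- rbind(
    data.frame(person_id = sprintf("p%04d", 1:7), chapter = "A",
               first_age = 30, followup_from_first = 30),
    data.frame(person_id = sprintf("p%04d", c(1:4, 8:10)), chapter = "B",
               first_age = 35, followup_from_first = 25))
  d <- build_pair_dataset(fr, persons, "A", "B", "eczema")
  expect_identical(attr(d, "n_union"), 10L)
  expect_identical(attr(d, "n_both"), 4L)
  expect_identical(sum(d$y), 4L)
  expect_equal(empirical_jaccard(fr, "A", "B"), 0.4)
})

test_that("pair covariates come from the earlier first record", {
  persons <- make_persons(1, entry_age = 20, end_age = 50)
  fr <- data.frame(person_id = "p0001", chapter = c("A", "B"),
                   first_age = c(40, 43), followup_from_first = c(10, 7))
  persons$eczema_flag <- FALSE
  d <- build_pair_dataset(fr, persons, "A", "B", "eczema")
  expect_equal(d$a, 40)
  expect_equal(d$f, 10)
  expect_identical(d$y, 1L)
})

test_that("pair datasets are symmetric in chapter order", {
  pop <- generate_population(sim_config(n_practices = 3, persons_per_practice = 80,
                                        seed = 14))
  persons <- pop$persons
  persons$eczema_flag <- unname(apply_eczema_algorithm(pop$events, persons$person_id))
  fr <- first_chapter_records(pop$events, persons)
  d1 <- build_pair_dataset(fr, persons, "A", "H", "eczema")
  d2 <- build_pair_dataset(fr, persons, "H", "A", "eczema")
  expect_identical(attr(d1, "n_union"), attr(d2, "n_union"))
  expect_identical(attr(d1, "n_both"), attr(d2, "n_both"))
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("pregnancy-chapter pairs are restricted to women", {
  persons <- make_persons(4, entry_age = 20, end_age = 60)
  persons$sex <- c("female", "male", "female", "male")
  persons$eczema_flag <- FALSE
  fr <- data.frame(person_id = sprintf("p%04d", 1:4), chapter = "A",
                   first_age = 30, followup_from_first = 30)
  fr <- rbind(fr, data.frame(person_id = c("p0001", "p0003"), chapter = "L",
                             first_age = 32, followup_from_first = 28))
  d <- build_pair_dataset(fr, persons, "A", "L", "eczema")
  expect_identical(attr(d, "n_union"), 2L)
  expect_true(all(d$s == 1))
})

test_that("empirical Jaccard endpoints", {
  fr_same <- data.frame(person_id = c("p1", "p1", "p2", "p2"),
                        chapter = c("A", "B", "A", "B"))
  expect_equal(empirical_jaccard(fr_same, "A", "B"), 1)
  fr_disj <- data.frame(person_id = c("p1", "p2"), chapter = c("A", "B"))
  expect_equal(empirical_jaccard(fr_disj, "A", "B"), 0)
  expect_true(is.na(empirical_jaccard(fr_disj[0, ], "A", "B")))
})

test_that("intercept-only data recovers the binomial MLE with sigma at zero", {
  set.seed(8)
  n <- 600
  d <- data.frame(y = rbinom(n, 1, 0.4), f = 5, a = 50, s = 1, x = 0,
                  p = rep(sprintf("g%d", 1:6), each = 100))
  fit <- fit_pair_glmm(d)
  expect_identical(fit$dropped, c("f", "a", "s", "x"))
  expect_lt(abs(coef(fit)["beta0"] - qlogis(mean(d$y))), 1e-3)
  expect_identical(fit$sigma_u, 0)
})

test_that("without practice heterogeneity the fit collapses to plain logistic", {
  d <- generate_pair_glmm_dataset(glmm_truth(beta0 = -1, beta_f = 0.1,
                                             beta_a = -0.02, beta_s = 0.3,
                                             beta_x = 0.5, sigma_u = 0),
                                  n = 4000, n_practices = 20, seed = 4)
  fit <- fit_pair_glmm(d)
  ref <- glm(y ~ f + a + s + x, data = d, family = binomial())
  expect_lt(max(abs(coef(fit) - coef(ref)[c("(Intercept)", "f", "a", "s", "x")])),
            1e-3)
})

test_that("reported likelihood matches brute-force integration of the intercept", {
  d <- generate_pair_glmm_dataset(glmm_truth(beta0 = -0.5, beta_f = 0.1,
                                             beta_s = 0.4, beta_x = 0.3,
                                             sigma_u = 0.8),
                                  n = 60, n_practices = 4, seed = 6)
  fit <- fit_pair_glmm(d, min_union = 20, min_events = 3)
  oracle <- marginal_loglik(d, coef(fit), fit$sigma_u)
  expect_lt(abs(fit$loglik - oracle), 1e-3)
})

test_that("degenerate and undersized pair data are handled as specified", {
  d_const <- data.frame(y = rep(1, 100), f = runif(100), a = 50, s = 1, x = 0,
                        p = "g1")
  expect_error(fit_pair_glmm(d_const), "constant")
  d_small <- generate_pair_glmm_dataset(glmm_truth(), n = 30, n_practices = 3,
                                        seed = 2)
  fit <- fit_pair_glmm(d_small, min_union = 50)
  expect_true(fit$flagged)
  expect_false(fit$converged)
  expect_match(fit$flag_reason, "union size")
  expect_error(predict_jaccard(fit, stratum_profile()), "not fitted")
})

test_that("prediction follows the inverse-logit closed form", {
  f0 <- fake_fit()
  for (sex in c("female", "male")) {
    expect_equal(predict_jaccard(f0, stratum_profile(sex = sex, age0 = 18)), 0.5)
  }
  f1 <- fake_fit(beta0 = -2, beta_f = 0.2)
  pr <- stratum_profile(age0 = 18, followup = 5)
  expect_equal(predict_jaccard(f1, pr), plogis(-1), tolerance = 1e-12)
  # monotone in followup when beta_f > 0
  preds <- vapply(c(1, 5, 10), function(T) {
    predict_jaccard(f1, stratum_profile(age0 = 18, followup = T))
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  # non-converged fits refuse to predict unless overridden
  f2 <- fake_fit(converged = FALSE)
  expect_error(predict_jaccard(f2, pr), "converge")
  expect_equal(predict_jaccard(f2, pr, override = TRUE), 0.5)
})

test_that("coefficient bias shrinks as the sample grows", {
  truth <- glmm_truth(beta0 = -1, beta_f = 0.1, beta_a = -0.02, beta_s = 0.3,
                      beta_x = 0.5, sigma_u = 0.5)
  err <- function(n, seeds) {
    e <- sapply(seeds, function(s) {
      d <- generate_pair_glmm_dataset(truth, n = n, n_practices = 20, seed = s)
      fit <- fit_pair_glmm(d, nAGQ = 7)
      abs(coef(fit) - unlist(truth)[1:5])
    })
    mean(e)
  }
  expect_lt(err(9000, 1:4), err(800, 1:4))
})

test_that("matrix assembly is symmetric with unit-complement distances", {
  chapters <- c("A", "B", "L")
  fits <- list("A:B" = fake_fit(beta0 = 0.5, chapters = c("A", "B")),
               "A:L" = fake_fit(beta0 = -0.5, chapters = c("A", "L")),
               "B:L" = fake_fit(beta0 = -1, chapters = c("B", "L")))
  profs <- list(stratum_profile(sex = "female", age0 = 18),
                stratum_profile(sex = "male", age0 = 18))
  mats <- assemble_matrices(fits, profs, chapters)
  expect_length(mats, 2)
  fem <- mats[[1]]
  expect_equal(fem$index, t(fem$index))
  off <- !diag(3) & !fem$flags
  expect_equal(fem$distance[off], 1 - fem$index[off])
  expect_equal(diag(fem$distance), rep(0, 3), ignore_attr = TRUE)
  # male stratum: every chapter-L cell is flagged at distance 1
  mal <- mats[[2]]
  expect_true(all(mal$flags["L", c("A", "B")]))
  expect_equal(unname(mal$distance["L", c("A", "B")]), c(1, 1))
  expect_true(all(is.na(mal$index["L", c("A", "B")])))
  # a missing pair is an assembly error
  expect_error(assemble_matrices(fits[-1], profs, chapters), "no fit")
})
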