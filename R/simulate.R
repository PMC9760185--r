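#' Generate a synthetic primary-care population
#'
#' Draws persons nested in general practices together with chapter-level
#' morbidity events and the record structure required by the eczema/asthma
#' case algorithms. Chapter indicators come from a Gaussian copula on latent
#' liabilities: person-level chapter probabilities are logistic in entry age,
#' sex, exposure count and a practice random intercept, and the copula's
#' latent correlation controls pairwise co-occurrence without disturbing the
#' margins. Every occurring chapter emits one morbidity event at an age drawn
#' uniformly over the person's observation window.
#'
#' Eczema cases receive one `eczema_diagnosis` record plus at least two
#' `eczema_therapy` records on distinct days (the minimum satisfying the case
#' algorithm) with Poisson-distributed extra therapy records; asthma cases
#' receive at least one `asthma_morbidity` record with Poisson extras.
#' Chapter `L` events are never generated for men.
#'
#' @param config A [sim_config()] object.
#' @return List of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{persons}{data frame: `person_id`, `practice_id`, `sex`
#'       (`"female"`/`"male"`), `entry_age`, `end_age`, and generator truth
#'       columns `eczema_true`, `asthma_true`.}
#'     \item{events}{data frame: `person_id`, `chapter` (a chapter letter, or
#'       `"eczema"`/`"asthma"` for exposure-defining records), `event_class`
#'       (`morbidity`, `eczema_diagnosis`, `eczema_therapy`,
#'       `asthma_morbidity`), `event_age` in years.}
#'   }
#'   Identical configurations (including `seed`) give identical outputs.
#' @export
#' @examples
#' cfg <- sim_config(n_practices = 3, persons_per_practice = 30, seed = 1)
#' pop <- generate_population(cfg)
#' head(pop$events)
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  ch <- read_chapters()
  n_prac <- config$n_practices
  n <- n_prac * config$persons_per_practice

  practice_id <- sprintf("gp%03d", rep(seq_len(n_prac), each = config$persons_per_practice))
  u_prac <- stats::rnorm(n_prac, 0, config$practice_sd)
  u <- rep(u_prac, each = config$persons_per_practice)

  person_id <- sprintf("p%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  entry_age <- stats::runif(n, config$age_range[1], config$age_range[2])
  end_age <- entry_age + config$followup_years
  eczema <- stats::runif(n) < config$eczema_prevalence
  asthma <- stats::runif(n) < config$asthma_prevalence
  n_expo <- as.numeric(eczema) + as.numeric(asthma)

  # person x chapter probabilities; margins are exact under the copula
  eta <- outer(rep(1, n), config$chapter_base_logodds[ch]) +
    outer(entry_age - 50, config$chapter_age_slope[ch]) +
    outer(as.numeric(sex == "female"), config$chapter_sex_effect[ch]) +
    outer(n_expo, config$exposure_effect[ch]) + u
  p <- stats::plogis(eta)
  p[sex == "male", "L"] <- 0

  dep <- config$dependence
  if (is.matrix(dep)) {
    z <- matrix(stats::rnorm(n * 19), n, 19) %*% chol(dep)
  } else {
    g <- stats::rnorm(n)
    z <- sqrt(dep) * g + sqrt(1 - dep) * matrix(stats::rnorm(n * 19), n, 19)
  }
  colnames(z) <- ch
  occurs <- stats::pnorm(z) < p

  hit <- which(occurs, arr.ind = TRUE)
  ev_morb <- data.frame(
    person_id = person_id[hit[, 1]],
    chapter = ch[hit[, 2]],
    event_class = rep("morbidity", nrow(hit)),
    event_age = entry_age[hit[, 1]] +
      stats::runif(nrow(hit)) * (end_age[hit[, 1]] - entry_age[hit[, 1]]),
    stringsAsFactors = FALSE)

  ev_ecz <- exposure_events(which(eczema), person_id, entry_age, end_age, kind = "eczema")
  ev_ast <- exposure_events(which(asthma), person_id, entry_age, end_age, kind = "asthma")

  events <- rbind(ev_morb, ev_ecz, ev_ast)
  events <- events[order(events$person_id, events$event_class, events$event_age), ,
                   drop = FALSE]
  rownames(events) <- NULL

  persons <- data.frame(person_id, practice_id, sex, entry_age, end_age,
                        eczema_true = eczema, asthma_true = asthma,
                        stringsAsFactors = FALSE)
  structure(list(persons = persons, events = events, config = config),
            class = "synthetic_cohort")
}

# minimal records satisfying the case algorithm, plus Poisson extras
exposure_events <- function(idx, person_id, entry_age, end_age, kind) {
  if (!length(idx)) {
    return(data.frame(person_id = character(), chapter = character(),
                      event_class = character(), event_age = numeric(),
                      stringsAsFactors = FALSE))
  }
  day <- 1 / 365.25
  rows <- lapply(idx, function(i) {
    span <- end_age[i] - entry_age[i]
    if (kind == "eczema") {
      n_th <- 2 + stats::rpois(1, 1)
      th <- entry_age[i] + stats::runif(n_th) * span
      # therapy records must fall on distinct calendar days
      th <- sort(th)
      fl <- floor(th / day)
      while (anyDuplicated(fl)) {
        th[duplicated(fl)] <- th[duplicated(fl)] + day
        fl <- floor(th / day)
      }
      th <- pmin(th, end_age[i])
      dx <- entry_age[i] + stats::runif(1) * span
      data.frame(person_id = person_id[i],
                 chapter = "eczema",
                 event_class = c("eczema_diagnosis", rep("eczema_therapy", n_th)),
                 event_age = c(dx, th),
                 stringsAsFactors = FALSE)
    } else {
      n_ev <- 1 + stats::rpois(1, 1)
      data.frame(person_id = person_id[i],
                 chapter = "asthma",
                 event_class = "asthma_morbidity",
                 event_age = entry_age[i] + stats::runif(n_ev) * span,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d persons in %d practices, %d events\n",
              nrow(x$persons), length(unique(x$persons$practice_id)),
              nrow(x$events)))
  invisible(x)
}

#' Ground-truth coefficients for a pair-level regression simulator
#'
#' Holds the coefficients of the random-intercept logistic model used by
#' [generate_pair_glmm_dataset()]: intercept, per-year followup and age
#' effects, sex and exposure contrasts, and the practice-intercept SD.
#'
#' @param beta0,beta_f,beta_a,beta_s,beta_x Fixed-effect coefficients
#'   (log-odds scale; `beta_f` per followup year, `beta_a` per year of age).
#' @param sigma_u Non-negative practice-intercept SD.
#' @return Object of class `glmm_truth`.
#' @export
glmm_truth <- function(beta0 = 0, beta_f = 0, beta_a = 0, beta_s = 0,
                       beta_x = 0, sigma_u = 0) {
  if (sigma_u < 0) stop("sigma_u must be non-negative", call. = FALSE)
  structure(list(beta0 = beta0, beta_f = beta_f, beta_a = beta_a,
                 beta_s = beta_s, beta_x = beta_x, sigma_u = sigma_u),
            class = "glmm_truth")
}

#' Simulate a regression-ready pair dataset with known ground truth
#'
#' Draws rows directly from the random-intercept logistic model used for the
#' pairwise Jaccard regressions: covariates uniform over stated ranges, sex
#' and exposure fair Bernoulli, practice intercepts Normal(0, `sigma_u`^2),
#' outcomes Bernoulli with logistic mean. Used for estimator
#' parameter-recovery checks.
#'
#' @param truth A [glmm_truth()] object.
#' @param n Number of rows (persons).
#' @param n_practices Number of practices; persons are spread evenly.
#' @param covariate_ranges List with elements `f` and `a`, each a length-2
#'   range for the followup and age covariates.
#' @param seed Optional integer seed.
#' @return Data frame of class `pair_data` with columns `y`, `f`, `a`, `s`,
#'   `x`, `p` and attributes `truth`, `n_union`, `n_both`.
#' @export
generate_pair_glmm_dataset <- function(truth, n, n_practices,
                                       covariate_ranges = list(f = c(1, 20),
                                                               a = c(18, 80)),
                                       seed = NULL) {
  stopifnot(inherits(truth, "glmm_truth"))
  if (n < 1 || n_practices < 1 || n < n_practices) {
    stop("need n >= n_practices >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- rep(seq_len(n_practices), length.out = n)
  u <- stats::rnorm(n_practices, 0, truth$sigma_u)[p]
  f <- stats::runif(n, covariate_ranges$f[1], covariate_ranges$f[2])
  a <- stats::runif(n, covariate_ranges$a[1], covariate_ranges$a[2])
  s <- stats::rbinom(n, 1, 0.5)
  x <- stats::rbinom(n, 1, 0.5)
  eta <- truth$beta0 + truth$beta_f * f + truth$beta_a * a +
    truth$beta_s * s + truth$beta_x * x + u
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  out <- data.frame(y = y, f = f, a = a, s = s, x = x,
                    p = sprintf("gp%03d", p), stringsAsFactors = FALSE)
  structure(out, truth = truth, n_union = n, n_both = sum(y),
            chapter1 = NA_character_, chapter2 = NA_character_,
            class = c("pair_data", "data.frame"))
}
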