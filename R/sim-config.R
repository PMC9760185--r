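#' Default per-chapter baseline log-odds of ever recording a chapter
#'
#' Baselines are on the log-odds scale at the reference profile (entry age 50,
#' male, unexposed, average practice) and are chosen so that marginal
#' prevalences resemble lifetime chapter recording in UK primary care:
#' near-universal respiratory, nervous-system and musculoskeletal recording,
#' rare perinatal and congenital chapters. Chapter `L` is referenced to women
#' (its probability for men is structurally zero).
#'
#' @return Named numeric vector over the 19 chapters.
#' @export
default_chapter_base_logodds <- function() {
  prev <- c(A = 0.50, B = 0.28, C = 0.29, D = 0.095, E = 0.38, F = 0.61,
            G = 0.38, H = 0.67, J = 0.47, K = 0.50, L = 0.33, M = 0.63,
            N = 0.66, P = 0.05, Q = 0.017, R = 0.53, S = 0.56, T = 0.23,
            U = 0.052)
  stats::qlogis(prev)
}

#' Synthetic-cohort generator configuration
#'
#' Bundles every knob of the synthetic electronic-health-record generator:
#' practice structure, per-chapter prevalence model, cross-chapter dependence,
#' exposure prevalence and effects, and the observation window.
#'
#' The per-chapter linear predictor for person \eqn{i} in practice \eqn{p} is
#' \deqn{\eta_{ij} = \beta_{0j} + \beta_{aj}(age_i - 50) + \beta_{sj} 1[female_i]
#'   + \beta_{xj} n^{exposures}_i + u_p,\quad u_p \sim N(0, \sigma_u^2)}
#' and chapter indicators are drawn through a Gaussian copula with
#' equicorrelation `dependence` (or a full 19x19 latent correlation matrix),
#' so marginal prevalences equal `plogis(eta)` exactly while pairwise
#' co-occurrence is tunable. Chapter `L` has probability zero for men.
#'
#' @param n_practices Number of general practices.
#' @param persons_per_practice Persons registered per practice.
#' @param practice_sd SD of the practice random intercept (log-odds scale).
#' @param chapter_base_logodds Named numeric vector (19 chapters): baseline
#'   log-odds at the reference profile.
#' @param chapter_age_slope Named numeric vector: log-odds change per year of
#'   entry age (centred at 50).
#' @param chapter_sex_effect Named numeric vector: female-vs-male log-odds
#'   contrast (ignored for `L`, which is female-only by construction).
#' @param exposure_effect Named numeric vector: log-odds shift per exposure
#'   (eczema, asthma) the person carries.
#' @param dependence Either a scalar latent equicorrelation in `[0, 1)` shared
#'   by all chapter pairs, or a 19x19 positive-definite latent correlation
#'   matrix with unit diagonal.
#' @param age_range Length-2 numeric: entry ages are uniform on this interval
#'   (adults only; must lie within `[18, 100]`).
#' @param followup_years Observation window length in years; end-of-followup
#'   age is entry age plus this.
#' @param eczema_prevalence,asthma_prevalence Probability that a person is an
#'   eczema / asthma case (drawn independently).
#' @param prop_female Probability a person is female.
#' @param seed Optional integer seed; generation is deterministic given the
#'   configuration including the seed.
#' @return Object of class `sim_config` (a validated list).
#' @seealso [generate_population()]
#' @export
sim_config <- function(n_practices = 25,
                       persons_per_practice = 120,
                       practice_sd = 0.3,
                       chapter_base_logodds = default_chapter_base_logodds(),
                       chapter_age_slope = stats::setNames(
                         ifelse(read_chapters() == "L", -0.05, 0.02), read_chapters()),
                       chapter_sex_effect = stats::setNames(
                         ifelse(read_chapters() == "L", 0, 0.1), read_chapters()),
                       exposure_effect = stats::setNames(
                         rep(0.4, 19), read_chapters()),
                       dependence = 0.3,
                       age_range = c(18, 80),
                       followup_years = 20,
                       eczema_prevalence = 0.15,
                       asthma_prevalence = 0.15,
                       prop_female = 0.55,
                       seed = NULL) {
  cfg <- list(n_practices = n_practices,
              persons_per_practice = persons_per_practice,
              practice_sd = practice_sd,
              chapter_base_logodds = chapter_base_logodds,
              chapter_age_slope = chapter_age_slope,
              chapter_sex_effect = chapter_sex_effect,
              exposure_effect = exposure_effect,
              dependence = dependence,
              age_range = age_range,
              followup_years = followup_years,
              eczema_prevalence = eczema_prevalence,
              asthma_prevalence = asthma_prevalence,
              prop_female = prop_female,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_practices) || cfg$n_practices < 1 ||
      cfg$n_practices != round(cfg$n_practices)) {
    stop("n_practices must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cfg$persons_per_practice) || cfg$persons_per_practice < 1 ||
      cfg$persons_per_practice != round(cfg$persons_per_practice)) {
    stop("persons_per_practice must be a positive integer", call. = FALSE)
  }
  if (cfg$practice_sd < 0) stop("practice_sd must be non-negative", call. = FALSE)
  ch <- read_chapters()
  for (nm in c("chapter_base_logodds", "chapter_age_slope",
               "chapter_sex_effect", "exposure_effect")) {
    v <- cfg[[nm]]
    if (length(v) != 19 || !setequal(names(v), ch)) {
      stop(nm, " must be a named numeric vector over the 19 chapters", call. = FALSE)
    }
  }
  dep <- cfg$dependence
  if (is.matrix(dep)) {
    if (!isTRUE(all.equal(dep, t(dep))) || nrow(dep) != 19 ||
        any(diag(dep) != 1)) {
      stop("a matrix dependence must be a symmetric 19x19 correlation matrix with unit diagonal",
           call. = FALSE)
    }
    ev <- eigen(dep, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("dependence matrix is not positive semi-definite", call. = FALSE)
  } else if (length(dep) != 1 || dep < 0 || dep >= 1) {
    stop("dependence must be a scalar in [0, 1) or a 19x19 correlation matrix", call. = FALSE)
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] < 18 ||
      cfg$age_range[2] > 100 || cfg$age_range[1] > cfg$age_range[2]) {
    stop("age_range must lie within [18, 100] with min <= max", call. = FALSE)
  }
  if (cfg$followup_years <= 0) stop("followup_years must be positive", call. = FALSE)
  for (nm in c("eczema_prevalence", "asthma_prevalence", "prop_female")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic EHR configuration\n")
  cat(sprintf("  %d practices x %d persons (practice SD %.2f)\n",
              x$n_practices, x$persons_per_practice, x$practice_sd))
  cat(sprintf("  entry age U[%g, %g], followup %g y\n",
              x$age_range[1], x$age_range[2], x$followup_years))
  dep <- if (is.matrix(x$dependence)) "matrix" else sprintf("%.2f", x$dependence)
  cat(sprintf("  latent dependence %s; eczema %.0f%%, asthma %.0f%%\n",
              dep, 100 * x$eczema_prevalence, 100 * x$asthma_prevalence))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' @param cfg A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  if (is.matrix(out$dependence)) out$dependence <- as.vector(out$dependence)
  for (nm in c("chapter_base_logodds", "chapter_age_slope",
               "chapter_sex_effect", "exposure_effect")) {
    out[[nm]] <- as.list(out[[nm]])   # keep chapter names: maps, not sequences
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw$dependence) == 361) {
    raw$dependence <- matrix(unlist(raw$dependence), 19, 19,
                             dimnames = list(read_chapters(), read_chapters()))
  }
  for (nm in c("chapter_base_logodds", "chapter_age_slope",
               "chapter_sex_effect", "exposure_effect")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$age_range <- as.numeric(unlist(raw$age_range))
  do.call(sim_config, raw)
}
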