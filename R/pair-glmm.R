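#' Fit the random-intercept logistic model for one chapter pair
#'
#' Maximum-likelihood fit of
#' \deqn{logit P(y=1) = \beta_0 + \beta_f f + \beta_a a + \beta_s s + \beta_x x + u_p,
#'   \quad u_p \sim N(0, \sigma_u^2)}
#' on a union-restricted pair dataset, where `y` indicates records in both
#' chapters, `f` is followup from the first chapter record, `a` age at that
#' record, `s` sex, `x` exposure and `u_p` a practice random intercept. The
#' marginal likelihood integrates the practice intercept by adaptive
#' Gauss-Hermite quadrature (default 15 nodes, via \pkg{lme4}). Continuous
#' covariates are standardized internally for optimization and estimates are
#' back-transformed to the natural per-year scale.
#'
#' Covariates that are constant in the dataset (e.g. sex for pairs involving
#' the women-only chapter `L`) are dropped and recorded in `$dropped`.
#' Datasets below the minimum union size or with too few persons in either
#' outcome class are not fitted: a flagged, unconverged stub is returned so
#' that downstream matrices can exclude the pair explicitly. Practice-SD
#' estimates below `1e-4` are reported as exactly 0 (boundary fits are
#' expected when practices are homogeneous).
#'
#' @param data A `pair_data` data frame (see [build_pair_dataset()] or
#'   [generate_pair_glmm_dataset()]) with columns `y`, `f`, `a`, `s`, `x`, `p`.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes.
#' @param min_union Minimum union size required to attempt a fit.
#' @param min_events Minimum persons required in each outcome class.
#' @param keep_model Keep the underlying fitted model object in `$model`.
#' @return Object of class `pair_glmm`: coefficients `beta0`, `beta_f`,
#'   `beta_a`, `beta_s`, `beta_x` (`NA` for dropped terms), `sigma_u`,
#'   `loglik`, `converged`, `gradient_norm`, `n_union`, `n_both`, `flagged`,
#'   `flag_reason`, `dropped`, `chapters`.
#' @seealso [predict_jaccard()]
#' @export
fit_pair_glmm <- function(data, nAGQ = 15, min_union = 50, min_events = 10,
                          keep_model = FALSE) {
  stopifnot(all(c("y", "f", "a", "s", "x", "p") %in% names(data)))
  n_union <- nrow(data)
  n_both <- sum(data$y)
  chapters <- c(attr(data, "chapter1"), attr(data, "chapter2"))
  if (n_union > 0 && (n_both == 0 || n_both == n_union)) {
    stop("degenerate pair dataset: outcome is constant (all y equal)", call. = FALSE)
  }
  stub <- function(reason) flagged_pair_fit(chapters, n_union, n_both, reason)
  if (n_union < min_union) return(stub(sprintf("union size %d below minimum %d", n_union, min_union)))
  if (n_both < min_events || (n_union - n_both) < min_events) {
    return(stub(sprintf("outcome class with fewer than %d persons", min_events)))
  }

  covs <- c("f", "a", "s", "x")
  dropped <- covs[vapply(covs, function(v) length(unique(data[[v]])) < 2, logical(1))]
  used <- setdiff(covs, dropped)

  # standardize continuous covariates for the optimizer; back-transform after
  dd <- data.frame(y = data$y, p = factor(data$p))
  center <- c(f = 0, a = 0); scale_ <- c(f = 1, a = 1)
  for (v in used) {
    z <- data[[v]]
    if (v %in% c("f", "a")) {
      center[v] <- mean(z); scale_[v] <- stats::sd(z)
      if (scale_[v] == 0) scale_[v] <- 1
      z <- (z - center[v]) / scale_[v]
    }
    dd[[v]] <- z
  }

  multi_practice <- nlevels(dd$p) >= 2
  fixed <- paste(c("1", used), collapse = " + ")
  msgs <- character()
  if (multi_practice) {
    form <- stats::as.formula(paste("y ~", fixed, "+ (1 | p)"))
    fit <- withCallingHandlers(
      lme4::glmer(form, data = dd, family = stats::binomial(), nAGQ = nAGQ),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    fe <- lme4::fixef(fit)
    V_std <- as.matrix(stats::vcov(fit))
    sigma_u <- sqrt(as.numeric(lme4::VarCorr(fit)$p))
    deriv <- fit@optinfo$derivs
    gradient_norm <- if (!is.null(deriv)) max(abs(deriv$gradient)) else NA_real_
    opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
    bad_msg <- any(grepl("failed to converge|unidentifiable|Hessian",
                         c(msgs, unlist(fit@optinfo$conv$lme4$messages)),
                         ignore.case = TRUE))
    converged <- opt_ok && !bad_msg
    loglik <- as.numeric(stats::logLik(fit))
  } else {
    form <- stats::as.formula(paste("y ~", fixed))
    fit <- stats::glm(form, data = dd, family = stats::binomial())
    fe <- stats::coef(fit)
    V_std <- stats::vcov(fit)
    sigma_u <- 0
    gradient_norm <- 0
    converged <- fit$converged
    loglik <- as.numeric(stats::logLik(fit))
    msgs <- c(msgs, "single practice level: plain logistic fit, sigma_u fixed at 0")
  }

  beta <- c(beta0 = NA_real_, beta_f = NA_real_, beta_a = NA_real_,
            beta_s = NA_real_, beta_x = NA_real_)
  b0 <- unname(fe["(Intercept)"])
  for (v in used) {
    bv <- unname(fe[v])
    if (v %in% c("f", "a")) {
      bv <- bv / scale_[v]
      b0 <- b0 - bv * center[v]
    }
    beta[paste0("beta_", v)] <- bv
  }
  beta["beta0"] <- b0
  if (!is.na(sigma_u) && sigma_u < 1e-4) sigma_u <- 0

  # back-transform the fixed-effect covariance through the same linear map
  terms_std <- c("(Intercept)", used)
  A <- diag(length(terms_std))
  dimnames(A) <- list(terms_std, terms_std)
  for (v in intersect(used, c("f", "a"))) {
    A[v, v] <- 1 / scale_[v]
    A["(Intercept)", v] <- -center[v] / scale_[v]
  }
  vcov_nat <- A %*% V_std[terms_std, terms_std, drop = FALSE] %*% t(A)
  nat_names <- c("beta0", if (length(used)) paste0("beta_", used))
  dimnames(vcov_nat) <- list(nat_names, nat_names)

  structure(list(coefficients = beta, sigma_u = sigma_u, loglik = loglik,
                 converged = converged, gradient_norm = gradient_norm,
                 n_union = n_union, n_both = n_both,
                 flagged = FALSE, flag_reason = NA_character_,
                 dropped = dropped, chapters = chapters,
                 vcov = vcov_nat, notes = msgs,
                 model = if (keep_model) fit else NULL),
            class = "pair_glmm")
}

# unfitted placeholder carrying the exclusion reason downstream
flagged_pair_fit <- function(chapters, n_union, n_both, reason) {
  structure(list(coefficients = c(beta0 = NA_real_, beta_f = NA_real_,
                                  beta_a = NA_real_, beta_s = NA_real_,
                                  beta_x = NA_real_),
                 sigma_u = NA_real_, loglik = NA_real_, converged = FALSE,
                 gradient_norm = NA_real_, n_union = n_union, n_both = n_both,
                 flagged = TRUE, flag_reason = reason,
                 dropped = character(), chapters = chapters, model = NULL),
            class = "pair_glmm")
}

#' @export
coef.pair_glmm <- function(object, ...) object$coefficients

#' @export
logLik.pair_glmm <- function(object, ...) {
  structure(object$loglik, df = sum(!is.na(object$coefficients)) + 1,
            nobs = object$n_union, class = "logLik")
}

#' @export
print.pair_glmm <- function(x, ...) {
  lab <- if (all(is.na(x$chapters))) "simulated pair" else paste(x$chapters, collapse = ":")
  cat(sprintf("Pair model %s (union %d, both %d)\n", lab, x$n_union, x$n_both))
  if (x$flagged) {
    cat("  not fitted:", x$flag_reason, "\n")
    return(invisible(x))
  }
  b <- x$coefficients
  cat("  coefficients:\n")
  print(round(b, 4))
  cat(sprintf("  sigma_u = %.4f; logLik = %.2f; converged = %s\n",
              x$sigma_u, x$loglik, x$converged))
  if (length(x$dropped)) cat("  dropped (constant):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pair_glmm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Standardized prediction profile
#'
#' The setting at which the fitted pair models are evaluated: age at first
#' chapter record (18 or 50 years in the primary analysis), sex, exposure
#' status and followup length (5 years primary; 1 and 10 as sensitivity), at
#' an average practice (zero practice effect) always.
#'
#' @param condition Exposure condition the profile belongs to.
#' @param exposed `"exposed"` or `"control"`.
#' @param sex `"female"` or `"male"`.
#' @param age0 Age at first chapter record, years.
#' @param followup Followup length from the first chapter record, years.
#' @return Object of class `stratum_profile`.
#' @export
stratum_profile <- function(condition = c("eczema", "asthma"),
                            exposed = c("exposed", "control"),
                            sex = c("female", "male"),
                            age0 = 18, followup = 5) {
  structure(list(condition = match.arg(condition),
                 exposed = match.arg(exposed),
                 sex = match.arg(sex),
                 age0 = age0, followup = followup),
            class = "stratum_profile")
}

#' @export
print.stratum_profile <- function(x, ...) {
  cat(stratum_label(x), "\n")
  invisible(x)
}

#' Compact label for a stratum profile
#' @param profile A [stratum_profile()].
#' @return Single string, e.g. `"eczema_exposed_female_age18_fu5"`.
#' @export
stratum_label <- function(profile) {
  sprintf("%s_%s_%s_age%g_fu%g", profile$condition, profile$exposed,
          profile$sex, profile$age0, profile$followup)
}

#' Predict the Jaccard index at a standardized profile
#'
#' Inverse-logit of the fitted linear predictor at the profile's followup,
#' age, sex and exposure, with the practice effect fixed at zero (an
#' "average practice"). Dropped covariates contribute nothing: for pairs
#' involving chapter `L` the intercept already refers to the women-only
#' population and predictions are only meaningful for female profiles.
#'
#' @param fit A converged [fit_pair_glmm()] object.
#' @param profile A [stratum_profile()] (or list with `age0`, `sex`,
#'   `exposed`, `followup`).
#' @param override Permit prediction from an unconverged (but fitted) model.
#' @param se Also return a delta-method standard error (diagnostic only; the
#'   analysis reports point predictions) as attribute `"se"`.
#' @return Predicted Jaccard index in `(0, 1)`.
#' @export
predict_jaccard <- function(fit, profile, override = FALSE, se = FALSE) {
  stopifnot(inherits(fit, "pair_glmm"))
  if (fit$flagged) stop("pair was not fitted: ", fit$flag_reason, call. = FALSE)
  if (!fit$converged && !override) {
    stop("model did not converge; use override = TRUE to predict anyway", call. = FALSE)
  }
  b <- fit$coefficients
  z <- c(beta0 = 1,
         beta_f = profile$followup,
         beta_a = profile$age0,
         beta_s = as.numeric(profile$sex == "female"),
         beta_x = as.numeric(profile$exposed == "exposed"))
  used <- names(b)[!is.na(b)]
  eta <- sum(b[used] * z[used])
  p <- unname(stats::plogis(eta))
  if (se) {
    if (is.null(fit$vcov)) stop("fit carries no covariance matrix", call. = FALSE)
    se_eta <- sqrt(drop(t(z[used]) %*% fit$vcov[used, used] %*% z[used]))
    attr(p, "se") <- stats::dlogis(eta) * se_eta
  }
  p
}

#' @export
predict.pair_glmm <- function(object, profile = stratum_profile(), ...) {
  predict_jaccard(object, profile, ...)
}
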