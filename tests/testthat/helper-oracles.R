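# Independent oracles and small fixture builders used across the suite.

# Direct agglomeration oracles. Unlike the package implementation these never
# use a Lance-Williams update: complete linkage recomputes each inter-cluster
# maximum from the raw matrix, and Ward evaluates its merge cost from the raw
# squared distances through the formal centroid identities
#   mean cross d^2 = |c_A - c_B|^2 + V_A + V_B,   V_A = sum_{a,a'} d^2 / (2 n_A^2)
#   cost(A, B) = 2 n_A n_B / (n_A + n_B) * |c_A - c_B|^2.
brute_linkage <- function(d, method = c("complete", "ward")) {
  method <- match.arg(method)
  n <- nrow(d)
  S <- d^2
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cost <- function(A, B) {
    if (method == "complete") return(max(d[A, B]))
    nA <- length(A); nB <- length(B)
    mAB <- mean(S[A, B, drop = FALSE])
    VA <- sum(S[A, A]) / (2 * nA^2)
    VB <- sum(S[B, B]) / (2 * nB^2)
    2 * nA * nB / (nA + nB) * (mAB - VA - VB)
  }
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_c <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        cc <- cost(clusters[[i]], clusters[[j]])
        if (cc < best_c) { best_c <- cc; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    height[step] <- best_c
    v <- c(ids[i], ids[j])
    merge[step, ] <- as.integer(v[order(v >= 0, abs(v))])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merge, height = height)
}

agglomerate_for_test <- function(d, method) {
  tr <- if (method == "complete") complete_linkage(d) else ward_linkage(d)
  list(merge = tr$merge, height = tr$height)
}

random_distance_matrix <- function(n, labels = LETTERS[seq_len(n)]) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- runif(n * (n - 1) / 2, 0.05, 1)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  d
}

# Brute-force marginal log-likelihood of the random-intercept logistic model:
# numerical integration of the practice intercept, independent of lme4.
marginal_loglik <- function(data, beta, sigma_u) {
  eta0 <- beta["beta0"] + beta["beta_f"] * data$f + beta["beta_a"] * data$a +
    beta["beta_s"] * data$s + beta["beta_x"] * data$x
  by_prac <- split(seq_len(nrow(data)), data$p)
  sum(vapply(by_prac, function(idx) {
    if (sigma_u == 0) {
      p <- plogis(eta0[idx])
      return(sum(data$y[idx] * log(p) + (1 - data$y[idx]) * log1p(-p)))
    }
    f <- function(u) {
      vapply(u, function(ui) {
        p <- plogis(eta0[idx] + ui)
        exp(sum(data$y[idx] * log(p) + (1 - data$y[idx]) * log1p(-p))) *
          dnorm(ui, 0, sigma_u)
      }, numeric(1))
    }
    log(integrate(f, -8 * sigma_u, 8 * sigma_u, rel.tol = 1e-10)$value)
  }, numeric(1)))
}

# A pair_glmm test double with known coefficients, for prediction formulas.
fake_fit <- function(beta0 = 0, beta_f = 0, beta_a = 0, beta_s = 0,
                     beta_x = 0, sigma_u = 0, chapters = c("A", "B"),
                     converged = TRUE) {
  structure(list(coefficients = c(beta0 = beta0, beta_f = beta_f,
                                  beta_a = beta_a, beta_s = beta_s,
                                  beta_x = beta_x),
                 sigma_u = sigma_u, loglik = NA_real_, converged = converged,
                 gradient_norm = 0, n_union = 100L, n_both = 50L,
                 flagged = FALSE, flag_reason = NA_character_,
                 dropped = character(), chapters = chapters,
                 vcov = NULL, model = NULL),
            class = "pair_glmm")
}

make_jmatrix <- function(index, stratum = stratum_profile(), flags = NULL) {
  diag(index) <- NA_real_
  if (is.null(flags)) {
    flags <- matrix(FALSE, nrow(index), ncol(index),
                    dimnames = dimnames(index))
  }
  distance <- 1 - index
  distance[flags] <- 1
  diag(distance) <- 0
  structure(list(index = index, distance = distance, flags = flags,
                 stratum = stratum),
            class = "jaccard_matrix")
}

make_persons <- function(n, practice = "gp001", sex = "female",
                         entry_age = 40, end_age = 60) {
  data.frame(person_id = sprintf("p%04d", seq_len(n)),
             practice_id = rep_len(practice, n),
             sex = rep_len(sex, n),
             entry_age = rep_len(entry_age, n),
             end_age = rep_len(end_age, n),
             stringsAsFactors = FALSE)
}

# A small, quick synthetic configuration reused by pipeline tests.
tiny_run_config <- function(seed = 7, out_dir = NULL, ...) {
  run_config(sim = sim_config(n_practices = 5, persons_per_practice = 60,
                              followup_years = 15),
             chapters = c("A", "F", "H", "M"),
             conditions = "eczema",
             min_union = 30, min_events = 5,
             seed = seed, out_dir = out_dir, ...)
}
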