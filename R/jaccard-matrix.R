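#' Assemble per-stratum Jaccard index and distance matrices
#'
#' Evaluates every fitted pair model at each standardized profile and fills
#' symmetric chapter-by-chapter matrices of predicted Jaccard indices and the
#' corresponding Jaccard distances (1 minus index). Cells whose pair was
#' flagged (too small, degenerate, or unconverged) are `NA` in the index
#' matrix, carry distance 1 (maximal dissimilarity) and are marked in the
#' flag matrix; the same applies to every chapter-`L` cell in male strata,
#' where pregnancy records cannot occur. The diagonal is undefined for the
#' index and 0 for the distance.
#'
#' @param fits Named list of [fit_pair_glmm()] objects, one per unordered
#'   chapter pair, named `"A:B"` style (see [enumerate_pairs()]). A missing
#'   pair is an error.
#' @param profiles List of [stratum_profile()] objects.
#' @param chapters Chapter set defining matrix order.
#' @return Named list (by [stratum_label()]) of `jaccard_matrix` objects,
#'   each with elements `index`, `distance`, `flags`, `stratum`.
#' @export
assemble_matrices <- function(fits, profiles, chapters = read_chapters()) {
  pairs <- enumerate_pairs(chapters)
  keys <- pair_key(pairs$chapter1, pairs$chapter2)
  missing <- setdiff(keys, names(fits))
  if (length(missing)) {
    stop("no fit (flagged or otherwise) supplied for pair(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (inherits(profiles, "stratum_profile")) profiles <- list(profiles)
  out <- lapply(profiles, function(pr) {
    n <- length(chapters)
    index <- matrix(NA_real_, n, n, dimnames = list(chapters, chapters))
    flags <- matrix(FALSE, n, n, dimnames = list(chapters, chapters))
    for (k in seq_len(nrow(pairs))) {
      c1 <- pairs$chapter1[k]; c2 <- pairs$chapter2[k]
      fit <- fits[[keys[k]]]
      male_L <- pr$sex == "male" && ("L" %in% c(c1, c2))
      if (male_L || fit$flagged || !fit$converged) {
        flags[c1, c2] <- flags[c2, c1] <- TRUE
      } else {
        v <- predict_jaccard(fit, pr)
        index[c1, c2] <- index[c2, c1] <- v
      }
    }
    distance <- 1 - index
    distance[flags] <- 1
    diag(distance) <- 0
    structure(list(index = index, distance = distance, flags = flags,
                   stratum = pr),
              class = "jaccard_matrix")
  })
  names(out) <- vapply(profiles, stratum_label, character(1))
  out
}

#' @export
print.jaccard_matrix <- function(x, ...) {
  cat("Jaccard matrix —", stratum_label(x$stratum), "\n")
  ut <- x$index[upper.tri(x$index)]
  cat(sprintf("  %d chapters; %d informative pairs (flagged: %d); index range [%.3f, %.3f]\n",
              nrow(x$index), sum(!is.na(ut)), sum(x$flags[upper.tri(x$flags)]),
              suppressWarnings(min(ut, na.rm = TRUE)),
              suppressWarnings(max(ut, na.rm = TRUE))))
  invisible(x)
}

#' Write a Jaccard matrix (or its distance) as square CSV
#'
#' @param x A `jaccard_matrix`.
#' @param path Output file.
#' @param which `"index"` or `"distance"`.
#' @return `path`, invisibly.
#' @export
write_jaccard_matrix <- function(x, path, which = c("index", "distance")) {
  which <- match.arg(which)
  m <- x[[which]]
  df <- data.frame(chapter = rownames(m),
                   formatC(m, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
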