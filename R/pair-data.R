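#' Build the union-restricted dataset for one chapter pair
#'
#' Restricts to persons with a first record in at least one of the two
#' chapters (the union restriction: persons with records in neither chapter
#' are excluded so that the model estimates the Jaccard index, the
#' probability of both given at least one). The outcome `y` is 1 when the
#' person has first records in both chapters. Covariates are taken at the
#' *earlier* of the person's (one or two) first records: `a` is the age at
#' that record and `f` the followup from it to end of followup — the only
#' definition available for single-chapter members, applied uniformly.
#'
#' For pairs involving chapter `L` the dataset is restricted to women (sex is
#' constant there and is dropped from the model).
#'
#' @param firstrecords Output of [first_chapter_records()].
#' @param persons Person data frame with `sex`, `practice_id`, `end_age` and
#'   the exposure flag named by `condition` (`eczema_flag`/`asthma_flag`).
#' @param c1,c2 Distinct chapter codes.
#' @param condition Which exposure flag provides the `x` covariate.
#' @return Data frame of class `pair_data` with columns `y`, `f`, `a`, `s`
#'   (1 = female), `x` (1 = exposed), `p` (practice) and attributes
#'   `chapter1`, `chapter2`, `n_union`, `n_both`, `empty`.
#' @export
build_pair_dataset <- function(firstrecords, persons, c1, c2,
                               condition = c("eczema", "asthma")) {
  condition <- match.arg(condition)
  if (identical(c1, c2)) stop("the two chapters must differ", call. = FALSE)
  assert_chapters(c(c1, c2))
  flag_col <- paste0(condition, "_flag")
  if (is.null(persons[[flag_col]])) {
    stop("persons lacks column ", flag_col, call. = FALSE)
  }
  f1 <- firstrecords[firstrecords$chapter == c1, c("person_id", "first_age")]
  f2 <- firstrecords[firstrecords$chapter == c2, c("person_id", "first_age")]
  union_ids <- union(f1$person_id, f2$person_id)
  pm <- match(union_ids, persons$person_id)
  keep <- !is.na(pm)
  union_ids <- union_ids[keep]; pm <- pm[keep]
  if ("L" %in% c(c1, c2)) {
    fem <- persons$sex[pm] == "female"
    union_ids <- union_ids[fem]; pm <- pm[fem]
  }
  a1 <- f1$first_age[match(union_ids, f1$person_id)]
  a2 <- f2$first_age[match(union_ids, f2$person_id)]
  first_age <- pmin(a1, a2, na.rm = TRUE)
  y <- as.integer(!is.na(a1) & !is.na(a2))
  out <- data.frame(
    y = y,
    f = persons$end_age[pm] - first_age,
    a = first_age,
    s = as.integer(persons$sex[pm] == "female"),
    x = as.integer(persons[[flag_col]][pm]),
    p = persons$practice_id[pm],
    stringsAsFactors = FALSE)
  ord <- order(union_ids)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            chapter1 = min(c1, c2), chapter2 = max(c1, c2),
            n_union = nrow(out), n_both = sum(out$y),
            empty = nrow(out) == 0L,
            class = c("pair_data", "data.frame"))
}

#' @export
print.pair_data <- function(x, ...) {
  cat(sprintf("Pair dataset %s:%s — union %d, both %d (raw Jaccard %.3f)\n",
              attr(x, "chapter1"), attr(x, "chapter2"),
              attr(x, "n_union"), attr(x, "n_both"),
              if (attr(x, "n_union") > 0) attr(x, "n_both") / attr(x, "n_union") else NA))
  invisible(x)
}

#' Raw (unadjusted) Jaccard index between two chapters
#'
#' The empirical analogue of the modelled quantity:
#' `|both| / |at least one|` over persons' first chapter records.
#'
#' @inheritParams build_pair_dataset
#' @return A number in `[0, 1]`, or `NA` when no person has either chapter.
#' @export
#' @examples
#' fr <- data.frame(person_id = c("p1","p1","p2","p3"),
#'                  chapter = c("A","B","A","B"))
#' empirical_jaccard(fr, "A", "B")  # 1 both / 3 union
empirical_jaccard <- function(firstrecords, c1, c2) {
  if (identical(c1, c2)) stop("the two chapters must differ", call. = FALSE)
  s1 <- unique(firstrecords$person_id[firstrecords$chapter == c1])
  s2 <- unique(firstrecords$person_id[firstrecords$chapter == c2])
  n_union <- length(union(s1, s2))
  if (n_union == 0) return(NA_real_)
  length(intersect(s1, s2)) / n_union
}
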