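#' Alphabetic Read chapters used in the analysis
#'
#' The 19 alphabetic chapters of the Read morbidity coding system, `A` to `U`
#' excluding `I` and `O` (and all numeric chapters, which hold history and
#' examination findings rather than morbidity). Chapter `L`
#' (pregnancy/childbirth/puerperium) can only be recorded for women.
#'
#' @return Character vector of the 19 chapter letters, in alphabetical order.
#' @export
#' @examples
#' read_chapters()
read_chapters <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K",
    "L", "M", "N", "P", "Q", "R", "S", "T", "U")
}

#' Human-readable chapter descriptions
#'
#' @return Named character vector mapping chapter letter to body-system label.
#' @export
chapter_labels <- function() {
  c(A = "Infectious/parasitic diseases",
    B = "Neoplasms",
    C = "Endocrine/metabolic",
    D = "Blood diseases",
    E = "Mental disorders",
    F = "Nervous system/senses",
    G = "Circulatory system",
    H = "Respiratory system",
    J = "Digestive system",
    K = "Genito-urinary system",
    L = "Pregnancy/childbirth/puerperium",
    M = "Skin/subcutaneous",
    N = "Musculoskeletal",
    P = "Congenital anomalies",
    Q = "Perinatal conditions",
    R = "Ill-defined conditions",
    S = "Injury/poisoning",
    T = "Causes of injury/poisoning",
    U = "External causes")
}

is_chapter <- function(x) x %in% read_chapters()

assert_chapters <- function(x, what = "chapter") {
  bad <- setdiff(unique(x), read_chapters())
  if (length(bad)) {
    stop(sprintf("invalid %s code(s): %s (valid codes are the alphabetic Read chapters %s)",
                 what, paste(bad, collapse = ", "),
                 paste(read_chapters(), collapse = "")), call. = FALSE)
  }
  invisible(x)
}

#' Enumerate unordered chapter pairs
#'
#' All `C(n, 2)` unordered pairs of distinct chapters, in lexicographic order.
#' With the full 19-chapter set this yields the 171 pairwise regression models
#' of the primary analysis.
#'
#' @param chapters Character vector of distinct chapter codes
#'   (default [read_chapters()]).
#' @return Data frame with columns `chapter1`, `chapter2` (`chapter1 <
#'   chapter2` lexicographically), one row per pair.
#' @export
#' @examples
#' nrow(enumerate_pairs())            # 171
#' enumerate_pairs(c("A", "B", "H"))
enumerate_pairs <- function(chapters = read_chapters()) {
  if (anyDuplicated(chapters)) {
    stop("duplicate chapter codes: ", paste(chapters[duplicated(chapters)], collapse = ", "),
         call. = FALSE)
  }
  if (length(chapters) < 2) stop("need at least two chapters", call. = FALSE)
  chapters <- sort(chapters)
  idx <- utils::combn(length(chapters), 2)
  data.frame(chapter1 = chapters[idx[1, ]],
             chapter2 = chapters[idx[2, ]],
             stringsAsFactors = FALSE)
}

pair_key <- function(c1, c2) {
  paste(pmin(c1, c2), pmax(c1, c2), sep = ":")
}
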