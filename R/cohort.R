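#' Eczema and asthma case algorithms
#'
#' `apply_eczema_algorithm()` flags a person as an eczema case when their
#' records hold at least one eczema diagnostic code and at least two eczema
#' therapy records on separate calendar days (event ages are floored to whole
#' days; two therapies on the same day count once). `apply_asthma_algorithm()`
#' flags a person who has ever had an asthma morbidity code. Both mirror case
#' definitions validated for UK primary-care records, and both are monotone:
#' adding records never un-flags a person.
#'
#' @param events Event data frame with `person_id`, `event_class`, `event_age`.
#' @param person_ids Optional character vector of persons to report on;
#'   defaults to the persons appearing in `events`. Persons with no events
#'   are `FALSE`.
#' @return Named logical vector over `person_ids`.
#' @export
#' @examples
#' ev <- data.frame(person_id = "p1",
#'                  event_class = c("eczema_diagnosis", "eczema_therapy",
#'                                  "eczema_therapy"),
#'                  event_age = c(30, 30 + 100/365.25, 30 + 250/365.25))
#' apply_eczema_algorithm(ev)
apply_eczema_algorithm <- function(events, person_ids = NULL) {
  if (is.null(person_ids)) person_ids <- unique(events$person_id)
  out <- stats::setNames(logical(length(person_ids)), person_ids)
  if (!nrow(events)) return(out)
  dx <- unique(events$person_id[events$event_class == "eczema_diagnosis"])
  th <- events[events$event_class == "eczema_therapy", , drop = FALSE]
  if (nrow(th)) {
    th$day <- floor(th$event_age * 365.25)
    day_counts <- tapply(th$day, th$person_id, function(d) length(unique(d)))
    ok_th <- names(day_counts)[day_counts >= 2]
  } else {
    ok_th <- character()
  }
  hit <- intersect(intersect(dx, ok_th), person_ids)
  out[hit] <- TRUE
  out
}

#' @rdname apply_eczema_algorithm
#' @export
apply_asthma_algorithm <- function(events, person_ids = NULL) {
  if (is.null(person_ids)) person_ids <- unique(events$person_id)
  out <- stats::setNames(logical(length(person_ids)), person_ids)
  hit <- intersect(unique(events$person_id[events$event_class == "asthma_morbidity"]),
                   person_ids)
  out[hit] <- TRUE
  out
}

#' Match exposed persons to controls
#'
#' For each exposed person, samples up to `ratio` controls uniformly at
#' random *with replacement* from pool members sharing their practice and sex
#' with entry age within `age_window` years. A control may serve several
#' exposed persons. Exposed persons with no eligible control get an empty
#' match set and are reported in the `unmatched` attribute (and via a
#' message).
#'
#' Matching is recorded for cohort description only: the pairwise regressions
#' deliberately break matching and adjust for the matching factors (age, sex,
#' practice) directly, because the union restriction drops matched members
#' asymmetrically.
#'
#' @param exposed,pool Person data frames (`person_id`, `practice_id`, `sex`,
#'   `entry_age`). `pool` should exclude persons meeting the exposure
#'   definition.
#' @param ratio Maximum controls per exposed person.
#' @param age_window Maximum absolute entry-age difference in years.
#' @param seed Optional integer seed.
#' @return Data frame (`exposed_id`, `control_id`, `draw`) with one row per
#'   sampled control; attribute `unmatched` lists exposed persons with no
#'   eligible control.
#' @export
match_controls <- function(exposed, pool, ratio = 5, age_window = 5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ratio >= 1, age_window >= 0)
  key <- function(df) paste(df$practice_id, df$sex, sep = "|")
  pool_by <- split(seq_len(nrow(pool)), key(pool))
  ek <- key(exposed)
  rows <- vector("list", nrow(exposed))
  unmatched <- character()
  for (i in seq_len(nrow(exposed))) {
    cand <- pool_by[[ek[i]]]
    if (!is.null(cand)) {
      cand <- cand[abs(pool$entry_age[cand] - exposed$entry_age[i]) <= age_window]
    }
    if (is.null(cand) || !length(cand)) {
      unmatched <- c(unmatched, exposed$person_id[i])
      next
    }
    pick <- cand[sample.int(length(cand), ratio, replace = TRUE)]
    rows[[i]] <- data.frame(exposed_id = exposed$person_id[i],
                            control_id = pool$person_id[pick],
                            draw = seq_len(ratio),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(exposed_id = character(), control_id = character(),
                      draw = integer(), stringsAsFactors = FALSE)
  }
  if (length(unmatched)) {
    message(length(unmatched), " exposed person(s) had no eligible control")
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' First record per person and chapter
#'
#' Reduces the morbidity events to one row per (person, chapter): the age at
#' the earliest record in that chapter, and the followup remaining from that
#' record to the person's end of followup. Only events of class `morbidity`
#' with a valid chapter letter are considered.
#'
#' @param events Event data frame.
#' @param persons Person data frame (`person_id`, `end_age`, `entry_age`).
#' @return Data frame `person_id`, `chapter`, `first_age`,
#'   `followup_from_first` (always non-negative).
#' @export
first_chapter_records <- function(events, persons) {
  ev <- events[events$event_class == "morbidity", , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(person_id = character(), chapter = character(),
                      first_age = numeric(), followup_from_first = numeric(),
                      stringsAsFactors = FALSE))
  }
  assert_chapters(ev$chapter, "event chapter")
  m <- match(ev$person_id, persons$person_id)
  if (anyNA(m)) {
    stop("events reference unknown person_id(s): ",
         paste(unique(ev$person_id[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  bad <- which(ev$event_age < persons$entry_age[m] - 1e-9 |
                 ev$event_age > persons$end_age[m] + 1e-9)
  if (length(bad)) {
    stop(sprintf("event_age outside the person's followup window in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  agg <- stats::aggregate(event_age ~ person_id + chapter, data = ev, FUN = min)
  names(agg)[names(agg) == "event_age"] <- "first_age"
  agg$followup_from_first <-
    persons$end_age[match(agg$person_id, persons$person_id)] - agg$first_age
  agg <- agg[order(agg$person_id, agg$chapter), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Percentage with the cohort table's rounding rule
#'
#' Computes `100 * count / total` rounded to `digits` decimal places —
#' integer precision for chapter prevalences, one decimal for cohort
#' overlaps, as in standard cohort description tables.
#'
#' @param count,total Non-negative counts.
#' @param digits Decimal places to round to.
#' @return Numeric percentage; `NA` when `total` is zero.
#' @export
#' @examples
#' cohort_percent(312098, 434422)      # 72
#' cohort_percent(115685, 434422, 1)   # 26.6
cohort_percent <- function(count, total, digits = 0) {
  n <- max(length(count), length(total))
  count <- rep_len(count, n)
  total <- rep_len(total, n)
  ifelse(total > 0, round(100 * count / total, digits), NA_real_)
}

#' Cohort characteristics by exposure group
#'
#' Table-1-style summary: per exposure condition (eczema, asthma) and group
#' (exposed vs unexposed), the group size, count and percentage of persons
#' with at least one record in each chapter (integer percentages), the
#' overlap with the other exposure cohort (one-decimal percentages), median
#' entry age and sex counts. Requires logical columns `eczema_flag` and
#' `asthma_flag` on `persons` (see [apply_eczema_algorithm()]).
#'
#' @param persons Person data frame with exposure flags filled.
#' @param firstrecords Output of [first_chapter_records()].
#' @param conditions Conditions to summarize.
#' @return Object of class `cohort_summary`: a data frame with one row per
#'   (condition, group) x statistic.
#' @export
summarize_cohort <- function(persons, firstrecords,
                             conditions = c("eczema", "asthma")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  ch <- read_chapters()
  has_ch <- table(factor(firstrecords$person_id, levels = persons$person_id),
                  factor(firstrecords$chapter, levels = ch)) > 0
  rows <- list()
  for (cond in conditions) {
    flag <- persons[[paste0(cond, "_flag")]]
    if (is.null(flag)) stop("persons lacks column ", cond, "_flag", call. = FALSE)
    other <- persons[[paste0(setdiff(c("eczema", "asthma"), cond), "_flag")]]
    for (grp in c("exposed", "control")) {
      sel <- if (grp == "exposed") flag else !flag
      total <- sum(sel)
      add <- function(stat, count, pct) {
        rows[[length(rows) + 1]] <<- data.frame(
          condition = cond, group = grp, statistic = stat,
          count = count, percent = pct, stringsAsFactors = FALSE)
      }
      add("total", total, NA_real_)
      if (total == 0) next
      if (!is.null(other)) {
        add("in_both_cohorts", sum(sel & other),
            cohort_percent(sum(sel & other), total, 1))
      }
      add("median_entry_age", stats::median(persons$entry_age[sel]), NA_real_)
      add("female", sum(persons$sex[sel] == "female"),
          cohort_percent(sum(persons$sex[sel] == "female"), total))
      add("male", sum(persons$sex[sel] == "male"),
          cohort_percent(sum(persons$sex[sel] == "male"), total))
      for (cc in ch) {
        n_cc <- sum(has_ch[sel, cc])
        add(paste0("chapter_", cc), n_cc, cohort_percent(n_cc, total))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (counts with percentages)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
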