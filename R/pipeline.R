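#' Configuration for a full multimorbidity-clustering run
#'
#' The defaults reproduce the primary analysis configuration: prediction ages
#' 18 and 50 years, 5 years of followup, complete linkage, and the 30%
#' co-occurrence threshold for both network edges and the dendrogram cut.
#' Sensitivity settings add followups of 1 and 10 years and Ward linkage.
#'
#' @param sim A [sim_config()] describing synthetic inputs, or `NULL` when
#'   reading person/event CSV files.
#' @param persons_path,events_path Input CSV paths (used when `sim` is NULL).
#' @param conditions Exposure conditions to analyse.
#' @param ages0 Ages at first chapter record for the standardized profiles.
#' @param followups Followup lengths (years) for the standardized profiles.
#' @param linkages Linkage methods to run (`"complete"` always defines the
#'   headline clusters; add `"ward"` for the sensitivity comparison).
#' @param network_threshold Jaccard-index threshold for network edges.
#' @param cut_probability Co-occurrence probability defining the dendrogram
#'   cut (clusters join below distance `1 - cut_probability`).
#' @param chapters Chapter subset to analyse (default all 19).
#' @param nAGQ,min_union,min_events Fit options passed to [fit_pair_glmm()].
#' @param match_ratio,age_window Control-matching options.
#' @param seed Integer seed governing every random draw of the run.
#' @param out_dir Optional output directory; when set, all tables, trees and
#'   a JSON manifest are written there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       persons_path = NULL, events_path = NULL,
                       conditions = c("eczema", "asthma"),
                       ages0 = c(18, 50),
                       followups = 5,
                       linkages = "complete",
                       network_threshold = 0.30,
                       cut_probability = 0.30,
                       chapters = read_chapters(),
                       nAGQ = 15, min_union = 50, min_events = 10,
                       match_ratio = 5, age_window = 5,
                       seed = 1L,
                       out_dir = NULL) {
  conditions <- match.arg(conditions, c("eczema", "asthma"), several.ok = TRUE)
  linkages <- match.arg(linkages, c("complete", "ward"), several.ok = TRUE)
  if (!length(ages0) || !length(followups)) {
    stop("ages0 and followups must be non-empty", call. = FALSE)
  }
  if (network_threshold < 0 || network_threshold > 1 ||
      cut_probability < 0 || cut_probability > 1) {
    stop("thresholds must be in [0, 1]", call. = FALSE)
  }
  assert_chapters(chapters)
  if (is.null(sim) && (is.null(persons_path) || is.null(events_path))) {
    stop("provide either a sim_config or persons/events paths", call. = FALSE)
  }
  structure(list(sim = sim, persons_path = persons_path,
                 events_path = events_path, conditions = conditions,
                 ages0 = ages0, followups = followups, linkages = linkages,
                 network_threshold = network_threshold,
                 cut_probability = cut_probability, chapters = chapters,
                 nAGQ = nAGQ, min_union = min_union, min_events = min_events,
                 match_ratio = match_ratio, age_window = age_window,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Enumerate standardized prediction strata
#'
#' Cartesian product of condition x exposure status x sex x age at first
#' record x followup. The default configuration (2 conditions, 2 statuses,
#' 2 sexes, ages 18/50, followup 5) yields the 16 strata of the primary
#' undirected-network analysis; extra followups multiply the prediction
#' strata but not the fitted models.
#'
#' @param config A [run_config()].
#' @return List of [stratum_profile()] objects.
#' @export
enumerate_strata <- function(config) {
  grid <- expand.grid(followup = config$followups,
                      age0 = config$ages0,
                      sex = c("female", "male"),
                      exposed = c("exposed", "control"),
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  # stable, readable order: condition, status, sex, age, followup
  grid <- grid[order(match(grid$condition, config$conditions),
                     grid$exposed, grid$sex, grid$age0, grid$followup), ]
  lapply(seq_len(nrow(grid)), function(i) {
    stratum_profile(condition = grid$condition[i], exposed = grid$exposed[i],
                    sex = grid$sex[i], age0 = grid$age0[i],
                    followup = grid$followup[i])
  })
}

#' Schema validation of person and event tables
#'
#' Row-level checks of the CSV contracts: required columns, sex values,
#' age ordering (end of followup after entry, adults only), valid chapter
#' letters on morbidity events, event ages inside the person's followup
#' window, known person identifiers, and the structural rule that chapter
#' `L` (pregnancy) events occur only for women.
#'
#' @param persons,events Data frames (see [read_persons()], [read_events()]).
#' @return Object of class `validation_report`: data frame `table`, `row`,
#'   `problem`; zero rows when the inputs are well-formed.
#' @export
validate_inputs <- function(persons, events) {
  problems <- list()
  note <- function(table, row, problem) {
    problems[[length(problems) + 1]] <<- data.frame(
      table = table, row = row, problem = problem, stringsAsFactors = FALSE)
  }
  bad_sex <- which(!persons$sex %in% c("female", "male"))
  for (i in bad_sex) note("persons", i, paste0("invalid sex value: ", persons$sex[i]))
  bad_age <- which(persons$end_age < persons$entry_age | persons$entry_age < 18)
  for (i in bad_age) note("persons", i, "requires end_age >= entry_age >= 18")
  dup <- which(duplicated(persons$person_id))
  for (i in dup) note("persons", i, paste0("duplicate person_id: ", persons$person_id[i]))

  valid_class <- c("morbidity", "eczema_diagnosis", "eczema_therapy", "asthma_morbidity")
  bad_cl <- which(!events$event_class %in% valid_class)
  for (i in bad_cl) note("events", i, paste0("invalid event_class: ", events$event_class[i]))
  morb <- events$event_class == "morbidity"
  bad_ch <- which(morb & !is_chapter(events$chapter))
  for (i in bad_ch) note("events", i, paste0("invalid Read chapter: ", events$chapter[i]))
  m <- match(events$person_id, persons$person_id)
  bad_pid <- which(is.na(m))
  for (i in bad_pid) note("events", i, paste0("unknown person_id: ", events$person_id[i]))
  known <- !is.na(m)
  out_win <- which(known &
                     (events$event_age < persons$entry_age[m] - 1e-9 |
                        events$event_age > persons$end_age[m] + 1e-9))
  for (i in out_win) note("events", i, "event_age outside followup window")
  male_L <- which(known & morb & events$chapter == "L" &
                    persons$sex[m] == "male")
  for (i in male_L) note("events", i, "chapter L (pregnancy) event for a male person")

  out <- if (length(problems)) do.call(rbind, problems) else
    data.frame(table = character(), row = integer(), problem = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Input validation: no problems found\n")
  } else {
    cat("Input validation:", nrow(x), "problem(s)\n")
    print.data.frame(utils::head(x, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Fit all pairwise models for one exposure condition
#'
#' Builds the union-restricted dataset and fits the random-intercept logistic
#' model for every chapter pair. Pairs whose dataset is empty, too small, or
#' has a constant outcome are returned as flagged stubs rather than aborting
#' the run.
#'
#' @param firstrecords,persons See [build_pair_dataset()].
#' @param condition `"eczema"` or `"asthma"`.
#' @param chapters Chapter set.
#' @param nAGQ,min_union,min_events Passed to [fit_pair_glmm()].
#' @return Named list (`"A:B"` keys) of `pair_glmm` objects.
#' @export
fit_condition_pairs <- function(firstrecords, persons, condition,
                                chapters = read_chapters(),
                                nAGQ = 15, min_union = 50, min_events = 10) {
  pairs <- enumerate_pairs(chapters)
  fits <- vector("list", nrow(pairs))
  names(fits) <- pair_key(pairs$chapter1, pairs$chapter2)
  for (k in seq_len(nrow(pairs))) {
    c1 <- pairs$chapter1[k]; c2 <- pairs$chapter2[k]
    dat <- build_pair_dataset(firstrecords, persons, c1, c2, condition)
    fits[[k]] <- tryCatch(
      fit_pair_glmm(dat, nAGQ = nAGQ, min_union = min_union,
                    min_events = min_events),
      error = function(e) flagged_pair_fit(c(c1, c2), attr(dat, "n_union"),
                                           attr(dat, "n_both"),
                                           conditionMessage(e)))
  }
  fits
}

#' Run the full multimorbidity clustering analysis
#'
#' End-to-end orchestration: generate (or read) the person/event tables,
#' apply the eczema and asthma case algorithms, match controls (recorded for
#' cohort description; the regressions model the matching factors directly),
#' derive first chapter records, fit all pairwise random-intercept logistic
#' models per condition, predict Jaccard matrices at every standardized
#' stratum, and derive thresholded networks, dendrograms and 30%-cut cluster
#' memberships. When Ward linkage is requested the run also reports the Rand
#' agreement between complete- and Ward-linkage partitions per stratum.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return Object of class `morbclust_run` with elements `config`, `persons`,
#'   `events`, `firstrecords`, `validation`, `summary`, `matches`, `fits`,
#'   `matrices`, `networks`, `trees`, `clusters`, `sensitivity`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  if (!is.null(config$sim)) {
    sim <- config$sim
    if (is.null(sim$seed)) sim$seed <- config$seed
    pop <- generate_population(sim)
    persons <- pop$persons
    events <- pop$events
  } else {
    persons <- read_persons(config$persons_path)
    events <- read_events(config$events_path)
  }
  validation <- validate_inputs(persons, events)
  if (nrow(validation)) {
    stop("input validation failed with ", nrow(validation),
         " problem(s); see validate_inputs()", call. = FALSE)
  }

  persons$eczema_flag <- unname(apply_eczema_algorithm(events, persons$person_id))
  persons$asthma_flag <- unname(apply_asthma_algorithm(events, persons$person_id))

  set.seed(config$seed + 1000L)
  matches <- lapply(stats::setNames(nm = config$conditions), function(cond) {
    flag <- persons[[paste0(cond, "_flag")]]
    suppressMessages(match_controls(persons[flag, ], persons[!flag, ],
                                    ratio = config$match_ratio,
                                    age_window = config$age_window))
  })

  firstrecords <- first_chapter_records(events, persons)
  summary <- summarize_cohort(persons, firstrecords, config$conditions)

  fits <- lapply(stats::setNames(nm = config$conditions), function(cond) {
    fit_condition_pairs(firstrecords, persons, cond,
                        chapters = config$chapters, nAGQ = config$nAGQ,
                        min_union = config$min_union,
                        min_events = config$min_events)
  })

  strata <- enumerate_strata(config)
  matrices <- list()
  for (cond in config$conditions) {
    prs <- Filter(function(p) p$condition == cond, strata)
    matrices <- c(matrices,
                  assemble_matrices(fits[[cond]], prs, config$chapters))
  }

  networks <- lapply(matrices, build_network,
                     threshold = config$network_threshold)
  cut_height <- 1 - config$cut_probability
  trees <- lapply(matrices, function(jm) {
    tr <- list(complete = complete_linkage(jm$distance))
    if ("ward" %in% config$linkages) tr$ward <- ward_linkage(jm$distance)
    tr
  })
  clusters <- lapply(trees, function(tr) cut_tree(tr$complete, cut_height))
  sensitivity <- if ("ward" %in% config$linkages) {
    vapply(names(trees), function(nm) {
      cc <- clusters[[nm]]
      ww <- cut_tree_k(trees[[nm]]$ward, length(unique(cc)))
      rand_index(cc, ww)
    }, numeric(1))
  } else NULL

  run <- structure(list(config = config, persons = persons, events = events,
                        firstrecords = firstrecords, validation = validation,
                        summary = summary, matches = matches, fits = fits,
                        matrices = matrices, networks = networks,
                        trees = trees, clusters = clusters,
                        sensitivity = sensitivity, manifest = NULL),
                   class = "morbclust_run")
  if (!is.null(config$out_dir)) {
    run$manifest <- write_run_outputs(run, config$out_dir)
  }
  run
}

# cut into exactly k clusters by replaying the first n - k merges
cut_tree_k <- function(tree, k) {
  n <- length(tree$labels)
  stopifnot(k >= 1, k <= n)
  if (k == n) {
    return(structure(stats::setNames(seq_len(n), tree$labels), cut_height = 0))
  }
  h <- sort(tree$height)[n - k]
  steps <- order(tree$height)[seq_len(n - k)]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    mem <- c(if (tree$merge[step, 1] < 0) -tree$merge[step, 1] else node_members[[tree$merge[step, 1]]],
             if (tree$merge[step, 2] < 0) -tree$merge[step, 2] else node_members[[tree$merge[step, 2]]])
    node_members[[step]] <- mem
    if (step %in% steps) {
      r <- find(mem[1])
      for (m in mem[-1]) parent[find(m)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, roots[!duplicated(roots)])
  structure(stats::setNames(cl, tree$labels), cut_height = h)
}

#' @export
print.morbclust_run <- function(x, ...) {
  cat("Multimorbidity clustering run\n")
  cat(sprintf("  %d persons, %d events; conditions: %s\n",
              nrow(x$persons), nrow(x$events),
              paste(x$config$conditions, collapse = ", ")))
  n_fit <- sum(vapply(x$fits, function(fl)
    sum(!vapply(fl, `[[`, logical(1), "flagged")), numeric(1)))
  n_all <- sum(lengths(x$fits))
  cat(sprintf("  pair models: %d fitted / %d (%d flagged)\n",
              n_fit, n_all, n_all - n_fit))
  cat(sprintf("  strata: %d; edges per network: %s\n", length(x$networks),
              paste(vapply(x$networks, count_edges, integer(1)), collapse = ", ")))
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  paths <- character()
  save_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
    p
  }
  sm <- run$summary
  sm$percent <- ifelse(is.na(sm$percent), "", formatC(sm$percent, format = "fg"))
  sm$count <- formatC(sm$count, format = "fg")
  save_csv(sm, "cohort_summary.csv")
  for (cond in cfg$conditions) {
    save_csv(run$matches[[cond]], sprintf("matches_%s.csv", cond))
    save_csv(fit_table(run$fits[[cond]]), sprintf("fits_%s.csv", cond))
  }
  for (nm in names(run$matrices)) {
    p <- file.path(out_dir, sprintf("jaccard_index_%s.csv", nm))
    write_jaccard_matrix(run$matrices[[nm]], p, "index"); paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("jaccard_distance_%s.csv", nm))
    write_jaccard_matrix(run$matrices[[nm]], p, "distance"); paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("edges_%s.csv", nm))
    export_edge_list(run$networks[[nm]], p); paths <- c(paths, p)
    for (lk in names(run$trees[[nm]])) {
      p <- file.path(out_dir, sprintf("dendrogram_%s_%s.nwk", nm, lk))
      write_newick(run$trees[[nm]][[lk]], p); paths <- c(paths, p)
      p <- file.path(out_dir, sprintf("merges_%s_%s.csv", nm, lk))
      write_merge_table(run$trees[[nm]][[lk]], p); paths <- c(paths, p)
    }
    cl <- run$clusters[[nm]]
    save_csv(data.frame(stratum = nm, chapter = names(cl),
                        cluster = unname(cl), stringsAsFactors = FALSE),
             sprintf("clusters_%s.csv", nm))
  }
  manifest <- list(
    package = "morbclust",
    version = as.character(utils::packageVersion("morbclust")),
    seed = cfg$seed,
    conditions = cfg$conditions,
    ages0 = cfg$ages0,
    followups = cfg$followups,
    linkages = cfg$linkages,
    network_threshold = cfg$network_threshold,
    cut_probability = cfg$cut_probability,
    chapters = paste(cfg$chapters, collapse = ""),
    n_persons = nrow(run$persons),
    n_events = nrow(run$events),
    checksums = as.list(tools::md5sum(sort(paths))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

# per-pair fit summaries as a flat, fixed-format table
fit_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(chapter1 = f$chapters[1], chapter2 = f$chapters[2],
               n_union = f$n_union, n_both = f$n_both,
               beta0 = f$coefficients["beta0"],
               beta_f = f$coefficients["beta_f"],
               beta_a = f$coefficients["beta_a"],
               beta_s = f$coefficients["beta_s"],
               beta_x = f$coefficients["beta_x"],
               sigma_u = f$sigma_u, loglik = f$loglik,
               converged = f$converged, flagged = f$flagged,
               flag_reason = ifelse(is.na(f$flag_reason), "",
                                    gsub(",", ";", f$flag_reason, fixed = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- c("beta0", "beta_f", "beta_a", "beta_s", "beta_x", "sigma_u", "loglik")
  for (v in num) out[[v]] <- ifelse(is.na(out[[v]]), "",
                                    formatC(out[[v]], format = "f", digits = 6))
  out
}
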