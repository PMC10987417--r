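#' Assemble a concussion cohort
#'
#' Joins athlete metadata with daily SCAT5 evaluations into a validated
#' cohort object. One row of `athletes` per concussion episode; each
#' episode's trajectory must start within 48 h of injury (first evaluation
#' at day 0--2) with strictly increasing days.
#'
#' @param athletes Metadata data frame: `athlete_id`, `sex`, `sport`,
#'   `mechanism`, optional `sport_group`, `rtp_day`.
#' @param evals Wide evaluation table: `athlete_id`, `day_post_injury`,
#'   22 symptom columns.
#' @return An object of class `src_cohort` with elements `athletes` and
#'   `evals`.
#' @export
src_cohort <- function(athletes, evals) {
  stopifnot(is.data.frame(athletes), is.data.frame(evals))
  need <- c("athlete_id", "sex", "mechanism")
  miss <- setdiff(need, names(athletes))
  if (length(miss) > 0L) stop("athletes table missing: ", paste(miss, collapse = ", "),
                              call. = FALSE)
  if (!all(athletes$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (anyNA(athletes$mechanism) ||
      !all(athletes$mechanism %in% c("sport", "non_sport", "uncertain"))) {
    bad <- athletes$athlete_id[is.na(athletes$mechanism) |
                               !athletes$mechanism %in% c("sport", "non_sport", "uncertain")]
    stop("invalid/missing mechanism for athlete(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (!"rtp_day" %in% names(athletes)) athletes$rtp_day <- NA_integer_
  as_checklist_matrix(evals[, scat5_symptoms])
  orphan <- setdiff(evals$athlete_id, athletes$athlete_id)
  if (length(orphan) > 0L) {
    stop("evaluations for unknown athlete(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  evals <- evals[order(evals$athlete_id, evals$day_post_injury), , drop = FALSE]
  first_day <- tapply(evals$day_post_injury, evals$athlete_id, min)
  late <- names(first_day)[first_day > 2]
  if (length(late) > 0L) {
    stop("first evaluation later than 48 h post-injury for athlete(s): ",
         paste(utils::head(late, 5L), collapse = ", "), call. = FALSE)
  }
  dup <- anyDuplicated(paste(evals$athlete_id, evals$day_post_injury))
  if (dup) stop("duplicate (athlete, day) evaluations", call. = FALSE)
  rownames(athletes) <- rownames(evals) <- NULL
  structure(list(athletes = athletes, evals = evals), class = "src_cohort")
}

#' @export
print.src_cohort <- function(x, ...) {
  cat("Concussion cohort: ", nrow(x$athletes), " episodes, ",
      nrow(x$evals), " daily evaluations\n", sep = "")
  cat("  sex: ", sum(x$athletes$sex == "female"), " female / ",
      sum(x$athletes$sex == "male"), " male\n", sep = "")
  cat("  mechanism:", paste(names(table(x$athletes$mechanism)),
                            table(x$athletes$mechanism), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a cohort to sport-related concussions
#'
#' Retains only episodes whose injury mechanism is `sport`; non-sport and
#' uncertain-origin concussions differ systematically in severity and
#' recovery and are excluded from analysis. Order is preserved and the
#' exclusion counts are attached as attribute `"excluded"`.
#'
#' @param cohort An [src_cohort()].
#' @return Filtered `src_cohort`; `attr(, "excluded")` is a named count
#'   vector by removal reason.
#' @export
apply_inclusion_filter <- function(cohort) {
  stopifnot(inherits(cohort, "src_cohort"))
  mech <- cohort$athletes$mechanism
  keep <- mech == "sport"
  excluded <- c(non_sport = sum(mech == "non_sport"),
                uncertain = sum(mech == "uncertain"))
  athletes <- cohort$athletes[keep, , drop = FALSE]
  evals <- cohort$evals[cohort$evals$athlete_id %in% athletes$athlete_id, ,
                        drop = FALSE]
  out <- src_cohort(athletes, evals)
  attr(out, "excluded") <- excluded
  out
}

#' Default sport-to-group mapping
#'
#' Loads the grouping table shipped with the package, which collapses 27
#' collegiate sports into 11 groups sized for mixed-model clusters.
#'
#' @return List with `table` (named character vector sport -> group) and
#'   `default_group`.
#' @export
default_sport_mapping <- function() {
  path <- system.file("extdata", "sport_groups.yaml",
                      package = "concussionprofiles", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  tab <- unlist(lapply(names(cfg$groups), function(g) {
    stats::setNames(rep(g, length(cfg$groups[[g]])), cfg$groups[[g]])
  }))
  list(table = tab, default_group = cfg$default_group %||% "other")
}

#' Collapse free-text sport names to sport groups
#'
#' @param sport Character vector of sport names.
#' @param mapping Mapping list as from [default_sport_mapping()].
#' @return Character vector of group labels. Unmapped sports go to the
#'   default bucket with a warning.
#' @export
collapse_sport <- function(sport, mapping = default_sport_mapping()) {
  grp <- unname(mapping$table[sport])
  unmapped <- is.na(grp)
  if (any(unmapped)) {
    warning("unmapped sport(s) sent to '", mapping$default_group, "': ",
            paste(unique(sport[unmapped]), collapse = ", "), call. = FALSE)
    grp[unmapped] <- mapping$default_group
  }
  grp
}

#' Time-to-recovery per episode
#'
#' Recovery is the day of the final daily evaluation, provided the athlete
#' is asymptomatic (total severity 0 under the default rule) at that
#' evaluation — i.e. the athlete reached asymptomatic status and completed
#' their final form. Episodes whose observed trajectory ends symptomatic
#' (including rebounds not followed by a clean final evaluation) are
#' right-censored and return `NA`.
#'
#' @param cohort An [src_cohort()].
#' @param asymptomatic_max Total severity at or below which an evaluation
#'   counts as asymptomatic (default 0).
#' @return Data frame `athlete_id`, `recovery_day` (integer or `NA`).
#' @export
time_to_recovery <- function(cohort, asymptomatic_max = 0L) {
  stopifnot(inherits(cohort, "src_cohort"))
  ev <- cohort$evals
  if (nrow(ev) == 0L) stop("cohort has no evaluations", call. = FALSE)
  sev <- as.integer(rowSums(ev[, scat5_symptoms]))
  last <- !duplicated(ev$athlete_id, fromLast = TRUE)
  rec <- ifelse(sev[last] <= asymptomatic_max, ev$day_post_injury[last], NA_integer_)
  out <- data.frame(athlete_id = ev$athlete_id[last], recovery_day = as.integer(rec))
  out[match(cohort$athletes$athlete_id, out$athlete_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Time to return-to-play per episode
#'
#' Passes through the recorded clearance day, validating that it is not
#' earlier than the derived recovery day; violations are kept but flagged
#' with a warning (clinical-record inconsistency, not silently fixed).
#'
#' @param cohort An [src_cohort()].
#' @return Data frame `athlete_id`, `rtp_day`.
#' @export
time_to_rtp <- function(cohort) {
  stopifnot(inherits(cohort, "src_cohort"))
  rec <- time_to_recovery(cohort)
  rtp <- cohort$athletes$rtp_day
  bad <- !is.na(rtp) & !is.na(rec$recovery_day) & rtp < rec$recovery_day
  if (any(bad)) {
    warning(sum(bad), " episode(s) have return-to-play before recovery: ",
            paste(utils::head(cohort$athletes$athlete_id[bad], 5L), collapse = ", "),
            call. = FALSE)
  }
  data.frame(athlete_id = cohort$athletes$athlete_id, rtp_day = as.integer(rtp))
}

#' One-decimal percentage with an explicit denominator
#' @param n Count.
#' @param total Denominator.
#' @return `round(100 * n / total, 1)`.
#' @export
profile_percent <- function(n, total) round(100 * n / total, 1)

#' Descriptive profile table from counts
#'
#' Builds the descriptive table (per-profile N, percent of cohort, and the
#' female/male split as percent of that profile's count) from raw counts.
#' Used by [summarize_cohort()] and directly when only published counts
#' are available.
#'
#' @param counts Data frame: `profile`, `n`, `n_female` (with
#'   `n_male = n - n_female`).
#' @param n_total Cohort size used as the percentage denominator.
#' @return Data frame with `pct`, `pct_female`, `pct_male` added, each to
#'   one decimal.
#' @export
summarize_counts <- function(counts, n_total) {
  stopifnot(all(c("profile", "n", "n_female") %in% names(counts)))
  counts$n_male <- counts$n - counts$n_female
  counts$pct <- profile_percent(counts$n, n_total)
  counts$pct_female <- profile_percent(counts$n_female, counts$n)
  counts$pct_male <- profile_percent(counts$n_male, counts$n)
  counts
}

#' Descriptive cohort summary (sex split and initial clinical profiles)
#'
#' Classifies each episode on its initial (first) evaluation and tabulates
#' per-profile counts and percentages overall and by sex, plus a
#' goodness-of-fit chi-square of the sex ratio against 1:1.
#'
#' @param cohort An [src_cohort()].
#' @param registry A [profile_registry()].
#' @return List of class `cohort_summary`: `n_total`, `n_by_sex`,
#'   `profile_table` (as [summarize_counts()]), `sex_chisq`
#'   (`statistic`, `p_value`).
#' @export
summarize_cohort <- function(cohort, registry = default_registry()) {
  stopifnot(inherits(cohort, "src_cohort"))
  if (nrow(cohort$athletes) == 0L) stop("empty cohort", call. = FALSE)
  init <- initial_table(cohort, registry)
  profs <- names(registry$profiles)
  counts <- data.frame(
    profile = profs,
    n = vapply(profs, function(p) sum(init[[p]]), integer(1)),
    n_female = vapply(profs, function(p) sum(init[[p]] & init$sex == "female"),
                      integer(1))
  )
  tab <- summarize_counts(counts, nrow(init))
  nf <- sum(init$sex == "female"); nm <- sum(init$sex == "male")
  chi <- stats::chisq.test(c(nf, nm), p = c(0.5, 0.5))
  structure(
    list(n_total = nrow(init),
         n_by_sex = c(female = nf, male = nm),
         pct_by_sex = c(female = profile_percent(nf, nf + nm),
                        male = profile_percent(nm, nf + nm)),
         profile_table = tab,
         sex_chisq = c(statistic = unname(chi$statistic),
                       p_value = unname(chi$p.value))),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort: n =", x$n_total, "\n")
  cat(sprintf("  Female %d (%.1f)  Male %d (%.1f)   chi-square vs 1:1 = %.2f, p = %.2f\n",
              x$n_by_sex["female"], x$pct_by_sex["female"],
              x$n_by_sex["male"], x$pct_by_sex["male"],
              x$sex_chisq["statistic"], x$sex_chisq["p_value"]))
  cat("Initial clinical profiles, N (%) / female (%) / male (%):\n")
  t <- x$profile_table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-18s %4d (%.1f)   %4d (%.1f)   %4d (%.1f)\n",
                t$profile[i], t$n[i], t$pct[i],
                t$n_female[i], t$pct_female[i], t$n_male[i], t$pct_male[i]))
  }
  invisible(x)
}

#' Initial-evaluation analysis table
#'
#' One row per episode: sex, sport group, the initial (first evaluation)
#' severity score, profile flags, profile count, and the derived recovery
#' and return-to-play outcomes. This is the table the cross-sectional
#' analyses consume; later evaluations never leak into it.
#'
#' @param cohort An [src_cohort()].
#' @param registry A [profile_registry()].
#' @return Data frame, one row per episode.
#' @export
initial_table <- function(cohort, registry = default_registry()) {
  stopifnot(inherits(cohort, "src_cohort"))
  ev <- cohort$evals
  first <- ev[!duplicated(ev$athlete_id), , drop = FALSE]
  first <- first[match(cohort$athletes$athlete_id, first$athlete_id), , drop = FALSE]
  cls <- classify_profiles(first[, scat5_symptoms], registry)
  rec <- time_to_recovery(cohort)
  out <- data.frame(
    athlete_id = cohort$athletes$athlete_id,
    sex = cohort$athletes$sex,
    sport_group = if ("sport_group" %in% names(cohort$athletes))
      cohort$athletes$sport_group else NA_character_,
    day_initial = first$day_post_injury,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, cls)
  out$recovery_day <- rec$recovery_day
  out$rtp_day <- as.integer(cohort$athletes$rtp_day)
  rownames(out) <- NULL
  out
}

#' Repeated-measures table for temporal-trend models
#'
#' One row per daily evaluation: day post-injury, total severity score and
#' number of clinical profiles present that day, with athlete and sport
#' group identifiers for the nested random intercepts.
#'
#' @param cohort An [src_cohort()].
#' @param registry A [profile_registry()].
#' @return Data frame, one row per evaluation.
#' @export
longitudinal_table <- function(cohort, registry = default_registry()) {
  stopifnot(inherits(cohort, "src_cohort"))
  ev <- cohort$evals
  cls <- classify_profiles(ev[, scat5_symptoms], registry)
  idx <- match(ev$athlete_id, cohort$athletes$athlete_id)
  data.frame(
    athlete_id = ev$athlete_id,
    sex = cohort$athletes$sex[idx],
    sport_group = if ("sport_group" %in% names(cohort$athletes))
      cohort$athletes$sport_group[idx] else NA_character_,
    day = ev$day_post_injury,
    severity = cls$severity_score,
    n_profiles = cls$n_profiles,
    stringsAsFactors = FALSE
  )
}
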