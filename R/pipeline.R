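#' Temporal trends in severity and profile count
#'
#' Fits zero-inflated negative-binomial mixed models to the repeated
#' daily measures of total symptom severity and of the number of clinical
#' profiles, with a natural-spline effect of day post-injury and random
#' intercepts for sport group and athlete-within-sport-group. Reports the
#' percent decline of the population-level predicted mean from day 0 to
#' day 14, the variance explained, and the same quantities for the
#' linear-time (df = 1) comparison models.
#'
#' @param cohort An [src_cohort()], typically already inclusion-filtered.
#' @param registry A [profile_registry()].
#' @param df Spline degrees of freedom for the day effect (default 3).
#' @param responses Which daily responses to model (default both).
#' @param compare_linear Also fit the linear-time (df = 1) comparison
#'   models (default TRUE).
#' @return List of class `temporal_trends`: fits, predicted day curves,
#'   `decline` (percent, severity and profiles, day 0 to 14), variance
#'   explained for the nonlinear and linear fits.
#' @export
temporal_trends <- function(cohort, registry = default_registry(), df = 3L,
                            responses = c("severity", "n_profiles"),
                            compare_linear = TRUE) {
  responses <- match.arg(responses, several.ok = TRUE)
  lt <- longitudinal_table(cohort, registry)
  if (mean(table(lt$athlete_id) >= 2) < 0.2) {
    stop("insufficient longitudinal data: most athletes have a single evaluation",
         call. = FALSE)
  }
  random <- c("sport_group", "sport_group:athlete_id")
  fits <- list(); r2 <- list(); curves <- list(); decline <- c()
  grid <- data.frame(day = 0:min(max(lt$day), 80))
  for (resp in responses) {
    spec <- model_spec(resp, "zinb", spline = list(var = "day", df = df),
                       random = random)
    fit <- fit_glmm(spec, lt)
    cur <- predict_conditional(fit, grid)
    mu0 <- cur$estimate[cur$day == 0]
    mu14 <- cur$estimate[cur$day == 14]
    decline[resp] <- 100 * (1 - mu14 / mu0)
    fits[[resp]] <- fit
    r2[[resp]] <- variance_explained(fit)
    curves[[resp]] <- cur
    if (compare_linear) {
      spec_lin <- model_spec(resp, "zinb", spline = list(var = "day", df = 1L),
                             random = random)
      fit_lin <- fit_glmm(spec_lin, lt)
      fits[[paste0(resp, "_linear")]] <- fit_lin
      r2[[paste0(resp, "_linear")]] <- variance_explained(fit_lin)
    }
  }
  structure(list(fits = fits, curves = curves, decline = decline,
                 variance_explained = r2),
            class = "temporal_trends")
}

#' @export
print.temporal_trends <- function(x, ...) {
  cat("Temporal trends (day 0 -> 14 predicted decline):\n")
  for (resp in names(x$decline)) {
    lin <- x$variance_explained[[paste0(resp, "_linear")]]
    cat(sprintf("  %-11s %.1f%%   (R2 cond %.2f nonlinear%s)\n",
                paste0(resp, ":"), x$decline[resp],
                x$variance_explained[[resp]]$conditional,
                if (!is.null(lin)) sprintf(" vs %.2f linear", lin$conditional) else ""))
  }
  invisible(x)
}

check_two_sexes <- function(init) {
  if (length(unique(init$sex)) < 2L) {
    stop("sex effects are inestimable: cohort contains a single sex", call. = FALSE)
  }
}

#' Q1: probability of presenting each clinical profile, by sex
#'
#' One Bernoulli mixed model per profile (profile present at the initial
#' evaluation ~ sex, random sport-group intercept), with per-sex
#' predicted probabilities, the sex contrast, its p-value and Cohen's d.
#'
#' @param init Initial-evaluation table from [initial_table()].
#' @param registry A [profile_registry()].
#' @return Data frame, one row per profile.
#' @export
q1_profile_probability <- function(init, registry = default_registry()) {
  check_two_sexes(init)
  rows <- lapply(names(registry$profiles), function(p) {
    y <- as.integer(init[[p]])
    if (length(unique(y)) < 2L) {
      warning("profile '", p, "' has zero or full prevalence: skipped", call. = FALSE)
      return(NULL)
    }
    d <- init; d$.y <- y
    fit <- fit_glmm(model_spec(".y", "bernoulli", terms = "sex",
                               random = "sport_group"), d)
    ct <- factor_contrast(fit, "sex")
    pr <- predict_conditional(fit, data.frame(sex = c("female", "male")))
    data.frame(profile = p,
               prob_female = pr$estimate[1], lower_female = pr$lower[1],
               upper_female = pr$upper[1],
               prob_male = pr$estimate[2], lower_male = pr$lower[2],
               upper_male = pr$upper[2],
               diff = ct$diff, p_value = ct$p_value, d = ct$d,
               magnitude = ct$magnitude)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared machinery for the per-profile sex-effect models (q2: initial
# severity; q3: recovery days). NB2 family for right-skewed overdispersed
# outcomes, random sport-group intercept, one model per profile subset.
per_profile_sex_model <- function(init, registry, response) {
  check_two_sexes(init)
  rows <- lapply(names(registry$profiles), function(p) {
    sub <- init[init[[p]] & !is.na(init[[response]]), , drop = FALSE]
    if (nrow(sub) < 10L || length(unique(sub$sex)) < 2L) {
      warning("profile '", p, "' has too few usable episodes: skipped", call. = FALSE)
      return(NULL)
    }
    fit <- fit_glmm(model_spec(response, "nb2", terms = "sex",
                               random = "sport_group"), sub)
    ct <- factor_contrast(fit, "sex")
    pr <- predict_conditional(fit, data.frame(sex = c("female", "male")))
    data.frame(profile = p, n = nrow(sub),
               mean_female = pr$estimate[1], lower_female = pr$lower[1],
               upper_female = pr$upper[1],
               mean_male = pr$estimate[2], lower_male = pr$lower[2],
               upper_male = pr$upper[2],
               diff = ct$diff, p_value = ct$p_value, d = ct$d,
               magnitude = ct$magnitude)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Q2: initial injury severity within each profile, by sex
#' @inheritParams q1_profile_probability
#' @return Data frame, one row per profile with usable data.
#' @export
q2_severity_within_profile <- function(init, registry = default_registry()) {
  per_profile_sex_model(init, registry, "severity_score")
}

#' Q3: time-to-recovery within each profile, by sex
#'
#' Right-censored (never asymptomatic in the follow-up window) episodes
#' are excluded; the excluded count is attached as attribute
#' `"n_censored"`.
#' @inheritParams q1_profile_probability
#' @return Data frame, one row per profile with usable data.
#' @export
q3_recovery_within_profile <- function(init, registry = default_registry()) {
  n_cens <- sum(is.na(init$recovery_day))
  if (n_cens == nrow(init)) stop("all recoveries censored", call. = FALSE)
  out <- per_profile_sex_model(init, registry, "recovery_day")
  attr(out, "n_censored") <- n_cens
  out
}

#' Q4: number of clinical profiles predicted by initial severity
#'
#' Binomial (6 trials) mixed model of the initial profile count on a
#' natural spline of initial severity interacted with sex, random
#' sport-group intercept. Returns the predicted severity -> count curve
#' per sex, the joint Wald test of the spline-by-sex interaction,
#' variance explained, and a band table mapping severity ranges to
#' rounded predicted counts (the saturating, logistic-growth-like shape
#' means low severities map to 0--1 profiles and high severities to all
#' 6).
#'
#' @inheritParams q1_profile_probability
#' @param df Spline degrees of freedom for severity (default 3).
#' @return List of class `q4_result`: `fit`, `curve`, `sex_interaction`,
#'   `variance_explained`, `bands`.
#' @export
q4_profiles_from_severity <- function(init, registry = default_registry(), df = 3L) {
  check_two_sexes(init)
  if (length(unique(init$severity_score)) < 2L) {
    stop("constant severity: spline inestimable", call. = FALSE)
  }
  fit <- fit_glmm(model_spec("n_profiles", "binomial_k", size = 6L,
                             spline = list(var = "severity_score", df = df),
                             spline_by = "sex", random = "sport_group"),
                  init)
  grid <- expand.grid(severity_score = 0:max(init$severity_score),
                      sex = c("female", "male"), stringsAsFactors = FALSE)
  curve <- predict_conditional(fit, grid)
  sexint <- wald_joint(fit, ":sex|sex.*:")
  # sex-averaged curve for the band table
  avg <- stats::aggregate(estimate ~ severity_score, data = curve, FUN = mean)
  avg <- avg[order(avg$severity_score), ]
  rounded <- round(avg$estimate)
  edge_low <- avg$severity_score[match(TRUE, rounded >= 2)]
  edge_high <- avg$severity_score[match(TRUE, rounded >= 6)]
  bands <- data.frame(
    band = c("0-1 profiles", "2-5 profiles", "6 profiles"),
    severity_from = c(0, edge_low, edge_high),
    severity_to = c(edge_low - 1, edge_high - 1, max(init$severity_score))
  )
  structure(list(fit = fit, curve = curve, sex_interaction = sexint,
                 variance_explained = variance_explained(fit), bands = bands),
            class = "q4_result")
}

#' @export
print.q4_result <- function(x, ...) {
  cat("Initial severity -> number of clinical profiles\n")
  cat(sprintf("  spline-by-sex interaction: chisq = %.2f (df %d), p = %.3g\n",
              x$sex_interaction$chisq, x$sex_interaction$df,
              x$sex_interaction$p_value))
  cat(sprintf("  variance explained (conditional R2): %.2f\n",
              x$variance_explained$conditional))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Q5: recovery and return-to-play predicted by profile count
#'
#' NB2 mixed models of recovery days and of return-to-play days on a
#' natural spline of the initial profile count interacted with sex
#' (random sport-group intercept), evaluated at integer profile counts
#' 0--6: predicted curves, per-count sex contrasts (estimate, CI, p,
#' Cohen's d), and per-sex marginal means averaged over the observed
#' profile-count distribution.
#'
#' @inheritParams q4_profiles_from_severity
#' @param df Spline degrees of freedom for profile count (default 2; the
#'   predictor takes only seven distinct values).
#' @return List of class `q5_result` with elements `recovery` and `rtp`,
#'   each holding `fit`, `curve`, `contrasts`, `marginal_means`.
#' @export
q5_outcomes_from_profile_count <- function(init, df = 2L) {
  check_two_sexes(init)
  if (any(init$n_profiles < 0 | init$n_profiles > 6)) {
    stop("profile counts must be in 0-6", call. = FALSE)
  }
  out <- list()
  for (resp in c("recovery_day", "rtp_day")) {
    sub <- init[!is.na(init[[resp]]), , drop = FALSE]
    fit <- fit_glmm(model_spec(resp, "nb2",
                               spline = list(var = "n_profiles", df = df),
                               spline_by = "sex", random = "sport_group"),
                    sub)
    counts <- sort(unique(sub$n_profiles))
    grid <- expand.grid(n_profiles = counts, sex = c("female", "male"),
                        stringsAsFactors = FALSE)
    curve <- predict_conditional(fit, grid)
    ct <- factor_contrast(fit, "sex", data.frame(n_profiles = counts))
    if (length(setdiff(0:6, counts)) > 0L) {
      warning("no observations at profile count(s) ",
              paste(setdiff(0:6, counts), collapse = ", "),
              ": contrasts skipped there", call. = FALSE)
    }
    # marginal means: average predictions over the observed count mix
    wts <- table(factor(sub$n_profiles, levels = counts))
    mm <- vapply(c("female", "male"), function(s) {
      est <- curve$estimate[curve$sex == s]
      sum(est * as.numeric(wts)) / sum(wts)
    }, numeric(1))
    mm_lo <- vapply(c("female", "male"), function(s) {
      sum(curve$lower[curve$sex == s] * as.numeric(wts)) / sum(wts)
    }, numeric(1))
    mm_hi <- vapply(c("female", "male"), function(s) {
      sum(curve$upper[curve$sex == s] * as.numeric(wts)) / sum(wts)
    }, numeric(1))
    key <- sub("_day$", "", resp)
    out[[key]] <- list(fit = fit, curve = curve, contrasts = ct,
                       marginal_means = data.frame(
                         sex = c("female", "male"), estimate = mm,
                         lower = mm_lo, upper = mm_hi),
                       variance_explained = variance_explained(fit),
                       n_used = nrow(sub))
  }
  structure(out, class = "q5_result")
}

#' @export
print.q5_result <- function(x, ...) {
  for (k in names(x)) {
    mm <- x[[k]]$marginal_means
    cat(sprintf("%s ~ spline(n_profiles) * sex: marginal means %s %.1f [%.1f, %.1f], %s %.1f [%.1f, %.1f] days\n",
                k, mm$sex[1], mm$estimate[1], mm$lower[1], mm$upper[1],
                mm$sex[2], mm$estimate[2], mm$lower[2], mm$upper[2]))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Cohort assembly (from CSV paths or the synthetic generator),
#' inclusion filtering, initial-evaluation classification, temporal
#' trends, and the five sex/severity/recovery questions, producing a
#' structured report. Deterministic given the simulation seed.
#'
#' @param config List with either `simulate` (arguments to
#'   [simulation_config()]) or `data` (list with `symptoms`, `metadata`,
#'   optional `dialect`); optional `registry` (path), `spline_df`,
#'   `temporal` (logical, default TRUE).
#' @return List of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  registry <- if (!is.null(config$registry)) load_registry(config$registry)
              else default_registry()
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(do.call(simulation_config, config$simulate))
  } else if (!is.null(config$data)) {
    evals <- read_symptom_csv(config$data$symptoms,
                              dialect = config$data$dialect %||% "wide")
    meta <- read_metadata_csv(config$data$metadata)
    if (!"sport_group" %in% names(meta)) {
      meta$sport_group <- collapse_sport(meta$sport)
    }
    cohort <- src_cohort(meta, evals)
  } else {
    stop("config needs a 'simulate' or 'data' section", call. = FALSE)
  }
  n_before <- nrow(cohort$athletes)
  cohort <- apply_inclusion_filter(cohort)
  excluded <- attr(cohort, "excluded")
  summary <- summarize_cohort(cohort, registry)
  init <- initial_table(cohort, registry)
  df <- config$spline_df %||% 3L
  trends <- if (isTRUE(config$temporal %||% TRUE)) {
    temporal_trends(cohort, registry, df = df)
  } else NULL
  report <- list(
    n_input = n_before,
    excluded = as.list(excluded),
    n_analyzed = nrow(init),
    cohort_summary = summary,
    temporal_trends = trends,
    q1 = q1_profile_probability(init, registry),
    q2 = q2_severity_within_profile(init, registry),
    q3 = q3_recovery_within_profile(init, registry),
    q4 = q4_profiles_from_severity(init, registry, df = df),
    q5 = q5_outcomes_from_profile_count(init),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(report) <- "analysis_report"
  report
}

#' Write an analysis report to JSON
#'
#' Serializes the numeric content of an [run_pipeline()] report (tables,
#' declines, contrasts, variance explained) to a machine-readable JSON
#' file; fitted model objects themselves are not serialized.
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (inherits(x, "glmm_fit")) {
      return(list(family = x$spec$family,
                  coefficients = as.data.frame(x$coef_table),
                  varcomp = as.list(x$varcomp), theta = x$theta,
                  zi_prob = x$zi_prob, logLik = x$logLik,
                  converged = x$converged))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  out <- strip(unclass(report))
  out$cohort_summary <- strip(unclass(report$cohort_summary))
  if (!is.null(report$temporal_trends)) {
    out$temporal_trends <- strip(unclass(report$temporal_trends))
  }
  out$q4 <- strip(unclass(report$q4))
  out$q5 <- strip(unclass(report$q5))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Concussion clinical-profile analysis ==\n")
  cat("Episodes: ", x$n_input, " in, ",
      sum(unlist(x$excluded)), " excluded (",
      paste(names(x$excluded), unlist(x$excluded), collapse = ", "),
      "), ", x$n_analyzed, " analyzed\n", sep = "")
  print(x$cohort_summary)
  if (!is.null(x$temporal_trends)) print(x$temporal_trends)
  cat("Q1 sex differences in profile probability: p in [",
      round(min(x$q1$p_value), 2), ", ", round(max(x$q1$p_value), 2), "]\n", sep = "")
  print(x$q4)
  print(x$q5)
  invisible(x)
}
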