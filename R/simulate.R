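#' Configuration for the synthetic concussion cohort generator
#'
#' The generator emulates the statistical structure of a multi-site
#' collegiate concussion surveillance cohort: daily total symptom severity
#' declines exponentially in expectation from its acute (day 0) level,
#' observed severities are zero-inflated negative-binomial around that
#' mean, athletes carry random intercepts nested within sport groups, and
#' total severity is allocated across the 22 SCAT5 symptoms so that
#' profile co-occurrence rises mechanically with severity.
#'
#' @param n_athletes Number of concussion episodes (>= 1).
#' @param sex_ratio Probability an athlete is female (default 0.5; the
#'   observed cohort is close to 1:1).
#' @param n_sport_groups Number of sport groups (default 11).
#' @param sport_group_sd SD of sport-group random intercepts, log scale.
#' @param athlete_sd SD of athlete random intercepts within group, log
#'   scale. The defaults (0.4 and 0.9) are calibrated so the grouping
#'   terms account for roughly half of the variance explained by the
#'   temporal severity model, the structure the analysis assumes.
#' @param baseline_mean_severity Expected day-0 total severity for an
#'   average athlete (default 35; observed initial profile-conditional
#'   means span roughly 30--50).
#' @param decay_rate Exponential decline of expected severity per day
#'   (default 0.18/day, calibrated so the day-0 to day-14 decline is about
#'   92 percent: `1 - exp(-0.18 * 14)` is 0.920).
#' @param nb_dispersion Negative-binomial size parameter theta (NB2
#'   variance `mu + mu^2/theta`).
#' @param zi_prob Structural-zero probability of the zero-inflation
#'   mixture.
#' @param profile_weights Named per-symptom allocation weights over
#'   [scat5_symptoms]; the default [default_symptom_weights()] makes
#'   headache, cognitive and ocular symptoms common and affective
#'   symptoms rarer, mirroring the observed ordering of profile
#'   prevalences (ocular/cognitive most, anxiety/mood least frequent).
#' @param symptom_concentration Dirichlet concentration of per-athlete
#'   symptom weights around `profile_weights` (smaller = each athlete
#'   concentrates severity on fewer, athlete-specific symptoms; default
#'   0.4). Athlete-level weights are drawn once per athlete and reused
#'   across days, so an athlete's symptom mix is stable over recovery.
#' @param sex_severity_logfc Log fold-change of female vs male expected
#'   severity (default 0: no sex effect, as observed).
#' @param sex_symptom_logw Named numeric: per-symptom log weight
#'   multipliers applied for females only (default none). Used to inject
#'   sex-specific profile effects in power studies.
#' @param non_sport_frac,uncertain_frac Mechanism mixture fractions
#'   (defaults 82/579 and 18/579, the observed exclusion rates).
#' @param rtp_lag_mean,rtp_lag_dispersion Negative-binomial mean and size
#'   of the lag (days) from recovery to full return-to-play clearance.
#' @param max_followup_days Follow-up window; episodes still symptomatic
#'   at its end are right-censored (default 80 days).
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_athletes = 500L,
                              sex_ratio = 0.5,
                              n_sport_groups = 11L,
                              sport_group_sd = 0.4,
                              athlete_sd = 0.9,
                              baseline_mean_severity = 35,
                              decay_rate = 0.18,
                              nb_dispersion = 3,
                              zi_prob = 0.03,
                              profile_weights = NULL,
                              symptom_concentration = 0.4,
                              sex_severity_logfc = 0,
                              sex_symptom_logw = NULL,
                              non_sport_frac = 82 / 579,
                              uncertain_frac = 18 / 579,
                              rtp_lag_mean = 4,
                              rtp_lag_dispersion = 2,
                              max_followup_days = 80L,
                              seed = 1L) {
  if (is.null(profile_weights)) profile_weights <- default_symptom_weights()
  num <- function(v) stats::setNames(as.numeric(v), names(v))
  cfg <- list(
    n_athletes = as.integer(n_athletes), sex_ratio = num(sex_ratio),
    n_sport_groups = as.integer(n_sport_groups),
    sport_group_sd = num(sport_group_sd), athlete_sd = num(athlete_sd),
    baseline_mean_severity = num(baseline_mean_severity),
    decay_rate = num(decay_rate),
    nb_dispersion = num(nb_dispersion), zi_prob = num(zi_prob),
    profile_weights = num(unlist(profile_weights)),
    symptom_concentration = num(symptom_concentration),
    sex_severity_logfc = num(sex_severity_logfc),
    sex_symptom_logw = if (!is.null(sex_symptom_logw)) num(unlist(sex_symptom_logw)),
    non_sport_frac = num(non_sport_frac), uncertain_frac = num(uncertain_frac),
    rtp_lag_mean = num(rtp_lag_mean), rtp_lag_dispersion = num(rtp_lag_dispersion),
    max_followup_days = as.integer(max_followup_days), seed = as.integer(seed)
  )
  probs <- c(cfg$sex_ratio, cfg$zi_prob, cfg$non_sport_frac, cfg$uncertain_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (cfg$non_sport_frac + cfg$uncertain_frac > 1) {
    stop("mechanism fractions sum past 1", call. = FALSE)
  }
  nonneg <- c(cfg$sport_group_sd, cfg$athlete_sd, cfg$baseline_mean_severity,
              cfg$decay_rate, cfg$nb_dispersion, cfg$rtp_lag_mean)
  if (any(nonneg < 0)) stop("rates, SDs and means must be >= 0", call. = FALSE)
  if (cfg$n_athletes < 1) stop("n_athletes must be >= 1", call. = FALSE)
  if (cfg$symptom_concentration <= 0) {
    stop("symptom_concentration must be > 0", call. = FALSE)
  }
  if (length(cfg$profile_weights) != length(scat5_symptoms) ||
      !setequal(names(cfg$profile_weights), scat5_symptoms) ||
      any(cfg$profile_weights <= 0)) {
    stop("profile_weights must be positive and named over the 22 symptoms",
         call. = FALSE)
  }
  if (!is.null(cfg$sex_symptom_logw)) {
    bad <- setdiff(names(cfg$sex_symptom_logw), scat5_symptoms)
    if (length(bad) > 0L) stop("sex_symptom_logw names outside vocabulary: ",
                               paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Default per-symptom allocation weights
#'
#' Relative frequencies with which total severity is allocated across
#' the 22 symptoms. Headache and cognitive/ocular-adjacent symptoms are
#' the most commonly endorsed after concussion; affective symptoms the
#' least, so the induced profile prevalences are ordered
#' ocular/cognitive > fatigue/vestibular/headache-migraine >
#' anxiety/mood.
#'
#' @return Named numeric vector over [scat5_symptoms].
#' @export
default_symptom_weights <- function() {
  c(headache = 3.0, pressure_in_head = 2.0, neck_pain = 0.8,
    nausea_or_vomiting = 0.8, dizziness = 1.5, blurred_vision = 0.9,
    balance_problems = 0.8, sensitivity_to_light = 1.5,
    sensitivity_to_noise = 0.8, feeling_slowed_down = 1.5,
    feeling_like_in_a_fog = 1.5, dont_feel_right = 1.6,
    difficulty_concentrating = 2.0, difficulty_remembering = 1.0,
    fatigue_or_low_energy = 2.0, confusion = 0.7, drowsiness = 1.2,
    more_emotional = 0.5, irritability = 0.6, sadness = 0.4,
    nervous_or_anxious = 0.5, trouble_falling_asleep = 0.7)[scat5_symptoms]
}

# Allocate a total severity S across the 22 symptoms, respecting the
# per-symptom cap of 6, by weighted sampling without replacement from the
# 132 unit "slots" (6 per symptom). Guarantees rowSums == S for S <= 132.
allocate_symptoms <- function(total, weights) {
  sev <- integer(length(scat5_symptoms))
  if (total == 0L) return(sev)
  slots <- rep(seq_along(scat5_symptoms), each = 6L)
  pick <- sample(slots, size = total, replace = FALSE,
                 prob = rep(weights / 6, each = 6L))
  tab <- tabulate(pick, nbins = length(scat5_symptoms))
  as.integer(tab)
}

#' Generate a synthetic concussion cohort
#'
#' For each athlete: sex is Bernoulli(`sex_ratio`); sport group is uniform
#' over groups; group and athlete intercepts are normal on the log scale.
#' Expected total severity decays exponentially,
#' `mu(t) = baseline * exp(b_group + b_athlete) * exp(-decay_rate * t)`,
#' and observed totals are zero-inflated NB2 draws capped at 132. Each
#' day's total is spread over the 22 symptoms by a capacity-respecting
#' weighted draw, so higher totals endorse more symptoms and hence more
#' co-occurring profiles. Evaluations are emitted daily from day 0 until
#' the first asymptomatic (zero-severity) day, which is the final
#' evaluation and defines recovery; athletes still symptomatic at
#' `max_followup_days` are censored. Return-to-play is recovery plus a
#' right-skewed clearance lag.
#'
#' @param config A [simulation_config()].
#' @return An [src_cohort()] with `sport_group` populated; the generating
#'   parameters are retrievable with [truth_record()].
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_athletes
  ids <- sprintf("ath%04d", seq_len(n))
  sex <- ifelse(stats::rbinom(n, 1L, config$sex_ratio) == 1L, "female", "male")
  grp <- sample.int(config$n_sport_groups, n, replace = TRUE)
  b_grp <- stats::rnorm(config$n_sport_groups, 0, config$sport_group_sd)
  b_ath <- stats::rnorm(n, 0, config$athlete_sd)
  mech <- sample(c("sport", "non_sport", "uncertain"), n, replace = TRUE,
                 prob = c(1 - config$non_sport_frac - config$uncertain_frac,
                          config$non_sport_frac, config$uncertain_frac))

  w_male <- config$profile_weights[scat5_symptoms]
  w_female <- w_male
  if (!is.null(config$sex_symptom_logw)) {
    w_female[names(config$sex_symptom_logw)] <-
      w_female[names(config$sex_symptom_logw)] * exp(config$sex_symptom_logw)
  }
  # per-athlete symptom mix: Dirichlet around the sex-specific base
  # weights; lower concentration = severity piles onto fewer symptoms
  draw_weights <- function(base) {
    alpha <- config$symptom_concentration * length(base) * base / sum(base)
    g <- stats::rgamma(length(base), shape = alpha, rate = 1)
    if (sum(g) == 0) g <- base
    stats::setNames(g / sum(g), names(base))
  }

  eval_list <- vector("list", n)
  rtp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    eta0 <- log(config$baseline_mean_severity) + b_grp[grp[i]] + b_ath[i] +
      if (sex[i] == "female") config$sex_severity_logfc else 0
    w <- draw_weights(if (sex[i] == "female") w_female else w_male)
    days <- integer(0); sevs <- list(); recovery <- NA_integer_
    for (t in 0:config$max_followup_days) {
      mu <- exp(eta0 - config$decay_rate * t)
      y <- if (stats::runif(1) < config$zi_prob) 0L
           else stats::rnbinom(1L, size = config$nb_dispersion, mu = mu)
      y <- min(y, scat5_max_severity)
      days <- c(days, t)
      sevs[[length(sevs) + 1L]] <- allocate_symptoms(y, w)
      if (y == 0L) { recovery <- t; break }
    }
    m <- do.call(rbind, sevs)
    colnames(m) <- scat5_symptoms
    eval_list[[i]] <- data.frame(athlete_id = ids[i], day_post_injury = days, m,
                                 stringsAsFactors = FALSE)
    if (!is.na(recovery)) {
      lag <- stats::rnbinom(1L, size = config$rtp_lag_dispersion,
                            mu = config$rtp_lag_mean)
      rtp[i] <- recovery + as.integer(lag)
    }
  }
  athletes <- data.frame(
    athlete_id = ids, sex = sex,
    sport = paste0("sport", grp),
    sport_group = paste0("group", sprintf("%02d", grp)),
    mechanism = mech, rtp_day = rtp,
    stringsAsFactors = FALSE
  )
  cohort <- src_cohort(athletes, do.call(rbind, eval_list))
  attr(cohort, "truth") <- config
  cohort
}

#' Generating parameters of a synthetic cohort
#'
#' Returns the exact [simulation_config()] used to generate a cohort, for
#' parameter-recovery testing. The record serializes to JSON and reloads
#' bit-exactly via [write_truth_record()] / [read_truth_record()].
#'
#' @param x A cohort from [generate_cohort()], or a `simulation_config`.
#' @return The `simulation_config`.
#' @export
truth_record <- function(x) {
  if (inherits(x, "simulation_config")) return(x)
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("no generative record attached: not a synthetic cohort",
                           call. = FALSE)
  truth
}

#' @rdname truth_record
#' @param record A `simulation_config`.
#' @param path File path for the serialized record.
#' @export
write_truth_record <- function(record, path) {
  stopifnot(inherits(record, "simulation_config"))
  # named atomic vectors serialize as JSON arrays (names dropped), so box
  # them into lists; auto_unbox then writes them as name/value objects
  rec <- lapply(unclass(record), function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname truth_record
#' @export
read_truth_record <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_config, raw[!vapply(raw, is.null, logical(1))])
}
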