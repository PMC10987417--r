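#' Canonical SCAT5 symptom vocabulary
#'
#' The 22 symptoms of the SCAT5 symptom checklist, each rated on a 0
#' (absent) to 6 (severe) Likert scale. All checklist containers in this
#' package use exactly these names; unknown names are rejected.
#'
#' @format Character vector of length 22.
#' @export
scat5_symptoms <- c(
  "headache", "pressure_in_head", "neck_pain", "nausea_or_vomiting",
  "dizziness", "blurred_vision", "balance_problems",
  "sensitivity_to_light", "sensitivity_to_noise",
  "feeling_slowed_down", "feeling_like_in_a_fog", "dont_feel_right",
  "difficulty_concentrating", "difficulty_remembering",
  "fatigue_or_low_energy", "confusion", "drowsiness",
  "more_emotional", "irritability", "sadness", "nervous_or_anxious",
  "trouble_falling_asleep"
)

#' Maximum attainable injury severity score (22 symptoms x severity 6)
#' @export
scat5_max_severity <- 132L

# Coerce a checklist input (named vector, or data frame / matrix with one
# column per symptom) to a validated integer matrix with 22 columns in
# canonical order. Severities must be integer-valued in [0, 6]; non-integer
# values are rejected, never rounded (SCAT5 is a Likert instrument).
as_checklist_matrix <- function(x) {
  if (is.numeric(x) && !is.matrix(x)) {
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  }
  if (is.data.frame(x)) {
    x <- as.matrix(x[, intersect(colnames(x), scat5_symptoms), drop = FALSE])
  }
  if (!is.matrix(x) || is.null(colnames(x))) {
    stop("checklist must be a named vector or a table with one column per symptom",
         call. = FALSE)
  }
  unknown <- setdiff(colnames(x), scat5_symptoms)
  if (length(unknown) > 0L) {
    stop("unknown symptom name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(scat5_symptoms, colnames(x))
  if (length(missing) > 0L) {
    stop("missing symptom(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicated symptom column(s)", call. = FALSE)
  }
  x <- x[, scat5_symptoms, drop = FALSE]
  storage <- suppressWarnings(as.numeric(x))
  if (anyNA(storage)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop("missing severity for symptom '", scat5_symptoms[bad[1L, 2L]],
         "' (row ", bad[1L, 1L], ")", call. = FALSE)
  }
  if (any(x != round(x))) {
    bad <- which(x != round(x), arr.ind = TRUE)
    stop("non-integer severity for symptom '", scat5_symptoms[bad[1L, 2L]],
         "' (row ", bad[1L, 1L], "): severities are integer Likert ratings",
         call. = FALSE)
  }
  if (any(x < 0 | x > 6)) {
    bad <- which(x < 0 | x > 6, arr.ind = TRUE)
    stop("severity out of range [0, 6] for symptom '",
         scat5_symptoms[bad[1L, 2L]], "' (row ", bad[1L, 1L], "): value ",
         x[bad[1L, 1L], bad[1L, 2L]], call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Injury severity score of a SCAT5 checklist
#'
#' The injury severity score is the sum of all 22 symptom severities and
#' ranges from 0 (asymptomatic) to 132 (every symptom at maximum).
#'
#' @param checklist A named numeric vector over the 22 canonical symptoms,
#'   or a data frame / matrix with one column per symptom (one row per
#'   evaluation). Severities must be integers in 0--6.
#' @return Integer vector of severity scores, one per evaluation.
#' @examples
#' x <- setNames(rep(6L, 22), scat5_symptoms)
#' score_severity(x) # 132
#' @export
score_severity <- function(checklist) {
  m <- as_checklist_matrix(checklist)
  as.integer(rowSums(m))
}

#' Endorsed symptoms of a checklist
#'
#' A symptom is endorsed when rated at or above a minimum severity
#' (default 1, i.e. any non-zero rating).
#'
#' @param checklist A single checklist (named vector or one-row table).
#' @param min_severity Integer in 1--6.
#' @return Character vector of endorsed symptom names.
#' @export
endorsed_symptoms <- function(checklist, min_severity = 1L) {
  if (length(min_severity) != 1L || is.na(min_severity) ||
      min_severity != round(min_severity) || min_severity < 1 || min_severity > 6) {
    stop("min_severity must be a single integer in [1, 6]", call. = FALSE)
  }
  m <- as_checklist_matrix(checklist)
  if (nrow(m) != 1L) stop("endorsed_symptoms expects a single checklist", call. = FALSE)
  scat5_symptoms[m[1L, ] >= min_severity]
}

#' Endorsement threshold for a clinical profile
#'
#' Number of endorsed symptoms required to assign a profile defined by
#' `n_symptoms` symptoms. The default rule, `"half_floor"`, requires
#' `max(1, floor(n/2))` symptoms: for a 7-symptom profile this is 3, the
#' worked rule used to operationalize "at least half" in the profile
#' definitions. The stricter `"half_ceiling"` alternative requires
#' `ceiling(n/2)`.
#'
#' @param n_symptoms Number of symptoms defining the profile (>= 1).
#' @param rule `"half_floor"` (default) or `"half_ceiling"`.
#' @return Integer required count, always >= 1.
#' @export
profile_threshold <- function(n_symptoms, rule = c("half_floor", "half_ceiling")) {
  rule <- match.arg(rule)
  if (any(n_symptoms < 1) || any(n_symptoms != round(n_symptoms))) {
    stop("n_symptoms must be a positive integer", call. = FALSE)
  }
  k <- switch(rule,
    half_floor   = pmax(1L, as.integer(floor(n_symptoms / 2))),
    half_ceiling = as.integer(ceiling(n_symptoms / 2))
  )
  k
}

#' Construct a clinical-profile registry
#'
#' A registry holds the six profile definitions (symptom subsets), the
#' minimum severity for a symptom to count as endorsed, and the threshold
#' rule mapping subset size to the required endorsed count. Profiles are
#' not mutually exclusive and share symptoms.
#'
#' @param profiles Named list: profile name -> character vector of symptoms
#'   from [scat5_symptoms].
#' @param endorsement_min_severity Minimum severity to endorse (default 1).
#' @param threshold_rule `"half_floor"` or `"half_ceiling"`.
#' @return Object of class `profile_registry`.
#' @seealso [default_registry()], [load_registry()]
#' @export
profile_registry <- function(profiles,
                             endorsement_min_severity = 1L,
                             threshold_rule = c("half_floor", "half_ceiling")) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.list(profiles)) {
    stop("profiles must be a named list of symptom subsets", call. = FALSE)
  }
  if (length(profiles) == 0L) stop("registry has no profiles", call. = FALSE)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("profiles must be a named list of symptom subsets", call. = FALSE)
  }
  for (p in names(profiles)) {
    syms <- profiles[[p]]
    if (length(syms) == 0L) stop("profile '", p, "' has an empty symptom set", call. = FALSE)
    bad <- setdiff(syms, scat5_symptoms)
    if (length(bad) > 0L) {
      stop("profile '", p, "' uses symptom(s) outside the SCAT5 vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(syms)) stop("profile '", p, "' lists a symptom twice", call. = FALSE)
  }
  # The published definitions give cognitive, anxiety/mood and ocular
  # profiles exactly 7 symptoms each; deviations are permitted but flagged.
  for (p in intersect(c("cognitive", "anxiety_mood", "ocular"), names(profiles))) {
    if (length(profiles[[p]]) != 7L) {
      warning("profile '", p, "' has ", length(profiles[[p]]),
              " symptoms; the reference definition uses 7", call. = FALSE)
    }
  }
  if (length(endorsement_min_severity) != 1L ||
      endorsement_min_severity < 1 || endorsement_min_severity > 6 ||
      endorsement_min_severity != round(endorsement_min_severity)) {
    stop("endorsement_min_severity must be a single integer in [1, 6]", call. = FALSE)
  }
  structure(
    list(profiles = lapply(profiles, as.character),
         endorsement_min_severity = as.integer(endorsement_min_severity),
         threshold_rule = threshold_rule),
    class = "profile_registry"
  )
}

#' @export
print.profile_registry <- function(x, ...) {
  cat("Clinical-profile registry (", length(x$profiles), " profiles)\n", sep = "")
  cat("  endorsement minimum severity:", x$endorsement_min_severity, "\n")
  cat("  threshold rule:", x$threshold_rule, "\n")
  for (p in names(x$profiles)) {
    n <- length(x$profiles[[p]])
    cat(sprintf("  %-18s %d symptoms (threshold %d)\n", p, n,
                profile_threshold(n, x$threshold_rule)))
  }
  invisible(x)
}

#' Default clinical-profile registry
#'
#' Loads the registry shipped with the package
#' (`inst/extdata/profile_registry.yaml`), which encodes the six clinical
#' profiles of the AMSSM concussion-subtype framework as subsets of the 22
#' SCAT5 symptoms. The cognitive, anxiety/mood and ocular subsets have 7
#' symptoms each; a 7-symptom profile requires 3 endorsed symptoms under
#' the default rule. The mapping lives in a config file, not in code, so
#' alternative operationalizations can be dropped in.
#'
#' @return A [profile_registry()].
#' @export
default_registry <- function() {
  path <- system.file("extdata", "profile_registry.yaml",
                      package = "concussionprofiles", mustWork = TRUE)
  load_registry(path)
}

#' Classify clinical profiles from SCAT5 checklists
#'
#' A profile is assigned when the number of endorsed symptoms within its
#' defining subset reaches the registry threshold. Profiles are not
#' mutually exclusive; severity beyond the endorsement cut does not affect
#' membership.
#'
#' @param checklist One or more checklists (named vector, or a table with
#'   one column per symptom and one row per evaluation).
#' @param registry A [profile_registry()]; default [default_registry()].
#' @return Data frame with one logical column per profile, plus
#'   `n_profiles` (0--6) and `severity_score` (0--132), one row per
#'   evaluation.
#' @export
classify_profiles <- function(checklist, registry = default_registry()) {
  stopifnot(inherits(registry, "profile_registry"))
  m <- as_checklist_matrix(checklist)
  endorsed <- m >= registry$endorsement_min_severity
  out <- as.data.frame(lapply(registry$profiles, function(syms) {
    k <- profile_threshold(length(syms), registry$threshold_rule)
    rowSums(endorsed[, syms, drop = FALSE]) >= k
  }))
  out$n_profiles <- as.integer(rowSums(out))
  out$severity_score <- as.integer(rowSums(m))
  out
}
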