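#' Load a clinical-profile registry from a YAML config
#'
#' The config has three keys: `profiles` (profile name -> symptom list),
#' `endorsement_min_severity` and `threshold_rule`. Validation is strict:
#' symptoms outside the SCAT5 vocabulary are errors, and profiles whose
#' reference definition has 7 symptoms (cognitive, anxiety/mood, ocular)
#' trigger a warning when sized differently.
#'
#' @param path Path to a YAML registry file.
#' @return A [profile_registry()].
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("profiles", "endorsement_min_severity", "threshold_rule"))
  if (length(unknown) > 0L) {
    stop("unknown registry key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$profiles)) stop("registry file has no 'profiles' section", call. = FALSE)
  profile_registry(
    profiles = cfg$profiles,
    endorsement_min_severity = cfg$endorsement_min_severity %||% 1L,
    threshold_rule = cfg$threshold_rule %||% "half_floor"
  )
}

#' Write a registry back to YAML
#' @param registry A [profile_registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "profile_registry"))
  yaml::write_yaml(
    list(endorsement_min_severity = registry$endorsement_min_severity,
         threshold_rule = registry$threshold_rule,
         profiles = registry$profiles),
    path
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read daily SCAT5 evaluations from CSV
#'
#' Two dialects are supported. `wide`: columns `athlete_id`,
#' `day_post_injury`, then one column per canonical symptom. `long`:
#' columns `athlete_id`, `day_post_injury`, `symptom`, `severity` with one
#' row per (athlete, day, symptom); each (athlete, day) must have all 22
#' symptoms exactly once. Validation is strict: unknown symptom names,
#' severities outside 0--6 and duplicate keys are errors carrying row
#' numbers, never silently coerced.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @return Wide data frame: `athlete_id`, `day_post_injury`, 22 symptom
#'   columns, validated.
#' @export
read_symptom_csv <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("symptom file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("athlete_id", "day_post_injury", "symptom", "severity")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0L) stop("long dialect needs column(s): ",
                                paste(miss, collapse = ", "), call. = FALSE)
    bad <- which(!raw$symptom %in% scat5_symptoms)
    if (length(bad) > 0L) {
      stop("unknown symptom '", raw$symptom[bad[1L]], "' at row ", bad[1L],
           call. = FALSE)
    }
    key <- paste(raw$athlete_id, raw$day_post_injury, raw$symptom)
    if (anyDuplicated(key)) {
      stop("duplicate (athlete, day, symptom) at row ", which(duplicated(key))[1L],
           call. = FALSE)
    }
    wide <- stats::reshape(
      raw[, need], direction = "wide",
      idvar = c("athlete_id", "day_post_injury"),
      timevar = "symptom", v.names = "severity"
    )
    names(wide) <- sub("^severity\\.", "", names(wide))
    rownames(wide) <- NULL
    raw <- wide
  }
  need <- c("athlete_id", "day_post_injury")
  miss <- setdiff(c(need, scat5_symptoms), names(raw))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "),
                              call. = FALSE)
  if (anyDuplicated(paste(raw$athlete_id, raw$day_post_injury))) {
    stop("duplicate (athlete, day) evaluation rows", call. = FALSE)
  }
  if (any(raw$day_post_injury < 0)) stop("negative day_post_injury", call. = FALSE)
  as_checklist_matrix(raw[, scat5_symptoms])  # validation with row numbers
  raw <- raw[order(raw$athlete_id, raw$day_post_injury), c(need, scat5_symptoms)]
  rownames(raw) <- NULL
  raw
}

#' Write daily SCAT5 evaluations to CSV
#'
#' Inverse of [read_symptom_csv()]; `wide` and `long` outputs round-trip
#' losslessly through the reader.
#'
#' @param evals Wide evaluation table as returned by [read_symptom_csv()]
#'   or [generate_cohort()].
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_symptom_csv <- function(evals, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("athlete_id", "day_post_injury", scat5_symptoms) %in% names(evals)))
  if (dialect == "long") {
    long <- stats::reshape(
      as.data.frame(evals[, c("athlete_id", "day_post_injury", scat5_symptoms)]),
      direction = "long", idvar = c("athlete_id", "day_post_injury"),
      varying = scat5_symptoms, v.names = "severity",
      timevar = "symptom", times = scat5_symptoms
    )
    long <- long[order(long$athlete_id, long$day_post_injury, long$symptom), ]
    utils::write.csv(long[, c("athlete_id", "day_post_injury", "symptom", "severity")],
                     path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(evals[, c("athlete_id", "day_post_injury", scat5_symptoms)],
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read athlete metadata from CSV
#'
#' Columns: `athlete_id`, `sex` (`female`/`male`), `sport`, `mechanism`
#' (`sport`/`non_sport`/`uncertain`), `rtp_day` (integer days or empty).
#'
#' @param path CSV file path.
#' @return Validated metadata data frame.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("athlete_id", "sex", "sport", "mechanism")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0L) stop("metadata missing column(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  if (!"rtp_day" %in% names(md)) md$rtp_day <- NA_integer_
  bad <- which(!md$sex %in% c("female", "male"))
  if (length(bad) > 0L) stop("invalid sex '", md$sex[bad[1L]], "' at row ", bad[1L],
                             call. = FALSE)
  bad <- which(!md$mechanism %in% c("sport", "non_sport", "uncertain"))
  if (length(bad) > 0L) stop("invalid mechanism '", md$mechanism[bad[1L]],
                             "' at row ", bad[1L], call. = FALSE)
  if (anyDuplicated(md$athlete_id)) stop("duplicate athlete_id in metadata",
                                         call. = FALSE)
  md
}

#' Write athlete metadata to CSV
#' @param athletes Metadata data frame (see [read_metadata_csv()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(athletes, path) {
  cols <- intersect(c("athlete_id", "sex", "sport", "sport_group", "mechanism",
                      "rtp_day"), names(athletes))
  utils::write.csv(athletes[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
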