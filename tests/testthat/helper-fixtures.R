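# Shared fixture builders. All fixtures are built in code at test time.

# A single checklist as a named integer vector; unspecified symptoms are 0.
make_checklist <- function(...) {
  sev <- setNames(rep(0L, length(scat5_symptoms)), scat5_symptoms)
  args <- list(...)
  if (length(args) > 0L) sev[names(args)] <- as.integer(unlist(args))
  sev
}

# Random valid checklists (rows), sparse like real symptom reports.
random_checklists <- function(n, seed = 1L) {
  set.seed(seed)
  m <- matrix(0L, n, length(scat5_symptoms),
              dimnames = list(NULL, scat5_symptoms))
  for (i in seq_len(n)) {
    k <- sample(0:22, 1L)
    if (k > 0L) m[i, sample(22L, k)] <- sample(0:6, k, replace = TRUE)
  }
  m
}

# Naive reference classifier: explicit loop over profiles and set
# intersections, independent of the vectorized matrix implementation.
brute_force_classify <- function(m, registry) {
  t(apply(m, 1L, function(row) {
    endorsed <- scat5_symptoms[row >= registry$endorsement_min_severity]
    vapply(registry$profiles, function(syms) {
      need <- profile_threshold(length(syms), registry$threshold_rule)
      length(intersect(endorsed, syms)) >= need
    }, logical(1))
  }))
}

# Minimal hand-built cohort: trajectories given as list(athlete_id =
# list(days = c(...), sev = c(...))) with total severity placed on the
# headache item (capped 6 per symptom, spread across items as needed).
make_cohort <- function(traj, sex = NULL, mechanism = NULL, rtp = NULL,
                        sport_group = NULL) {
  ids <- names(traj)
  rows <- do.call(rbind, lapply(ids, function(id) {
    d <- traj[[id]]
    m <- t(vapply(d$sev, function(s) {
      v <- setNames(rep(0L, 22L), scat5_symptoms)
      i <- 1L
      while (s > 0L && i <= 22L) {
        v[i] <- min(6L, s); s <- s - v[i]; i <- i + 1L
      }
      v
    }, integer(22L)))
    data.frame(athlete_id = id, day_post_injury = d$days, m,
               check.names = FALSE)
  }))
  athletes <- data.frame(
    athlete_id = ids,
    sex = sex %||% rep(c("female", "male"), length.out = length(ids)),
    sport = "soccer",
    sport_group = sport_group %||% rep(c("g1", "g2"), length.out = length(ids)),
    mechanism = mechanism %||% rep("sport", length(ids)),
    rtp_day = rtp %||% rep(NA_integer_, length(ids))
  )
  src_cohort(athletes, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic cohort shared by the pipeline tests (built once).
pipeline_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(simulation_config(n_athletes = 150L, seed = 7L))
      cache <<- apply_inclusion_filter(cohort)
    }
    cache
  }
})
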