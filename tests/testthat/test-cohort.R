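test_that("inclusion filter keeps only sport-mechanism episodes and is idempotent", {
  traj <- setNames(rep(list(list(days = 0L, sev = 5L)), 10L),
                   paste0("a", 1:10))
  mech <- c(rep("sport", 6), rep("non_sport", 3), "uncertain")
  coh <- make_cohort(traj, mechanism = mech)
  f1 <- apply_inclusion_filter(coh)
  expect_identical(nrow(f1$athletes), 6L)
  expect_identical(attr(f1, "excluded"), c(non_sport = 3L, uncertain = 1L))
  expect_identical(f1$athletes$athlete_id, paste0("a", 1:6))  # order preserved
  f2 <- apply_inclusion_filter(f1)
  expect_identical(f2$athletes, f1$athletes)
  expect_identical(attr(f2, "excluded"), c(non_sport = 0L, uncertain = 0L))
  # all-sport cohort passes through unchanged
  all_sport <- make_cohort(traj)
  expect_identical(apply_inclusion_filter(all_sport)$athletes, all_sport$athletes)
})

test_that("sport collapsing maps 27 sports to 11 groups with a default bucket", {
  mp <- default_sport_mapping()
  expect_identical(length(mp$table), 27L)
  expect_identical(length(unique(mp$table)), 11L)
  expect_identical(collapse_sport(c("swimming", "diving"), mp),
                   c("water_sports", "water_sports"))
  expect_warning(grp <- collapse_sport("quidditch", mp), "quidditch")
  expect_identical(grp, mp$default_group)
  ident <- list(table = c(golf = "golf"), default_group = "other")
  expect_identical(collapse_sport("golf", ident), "golf")
})

test_that("recovery is the final evaluation day when asymptomatic, else censored", {
  coh <- make_cohort(list(
    a1 = list(days = c(0L, 5L, 12L), sev = c(30L, 10L, 0L)),
    a2 = list(days = c(0L, 6L, 9L, 15L), sev = c(20L, 0L, 4L, 0L)),
    a3 = list(days = c(0L, 4L), sev = c(25L, 8L))
  ))
  rec <- time_to_recovery(coh)
  expect_identical(rec$recovery_day[rec$athlete_id == "a1"], 12L)
  expect_identical(rec$recovery_day[rec$athlete_id == "a2"], 15L)  # rebound, then clean final
  expect_true(is.na(rec$recovery_day[rec$athlete_id == "a3"]))
})

test_that("appending trailing symptomatic evaluations never shortens recovery", {
  base <- list(a1 = list(days = c(0L, 3L, 8L), sev = c(15L, 5L, 0L)))
  r0 <- time_to_recovery(make_cohort(base))$recovery_day
  ext <- list(a1 = list(days = c(0L, 3L, 8L, 11L, 14L),
                        sev = c(15L, 5L, 0L, 3L, 0L)))
  r1 <- time_to_recovery(make_cohort(ext))$recovery_day
  expect_true(r1 >= r0)
})

test_that("return-to-play passes through and flags ordering violations", {
  traj <- list(a1 = list(days = c(0L, 12L), sev = c(10L, 0L)),
               a2 = list(days = c(0L, 12L), sev = c(10L, 0L)),
               a3 = list(days = 0L, sev = 9L))
  coh <- make_cohort(traj, rtp = c(17L, 10L, NA))
  expect_warning(rtp <- time_to_rtp(coh), "before recovery")
  expect_identical(rtp$rtp_day, c(17L, 10L, NA))
})

test_that("summary percentages use the documented denominators to one decimal", {
  counts <- data.frame(profile = c("cognitive", "anxiety_mood"),
                       n = c(383L, 206L), n_female = c(175L, 99L))
  tab <- summarize_counts(counts, 579L)
  expect_identical(tab$pct, c(66.1, 35.6))
  expect_identical(tab$pct_female, c(45.7, 48.1))
  expect_identical(tab$pct_male, c(54.3, 51.9))
  expect_identical(profile_percent(275, 579), 47.5)
})

test_that("female and male shares of each profile sum to 100 within rounding", {
  coh <- pipeline_cohort()
  s <- summarize_cohort(coh)
  expect_true(all(abs(s$profile_table$pct_female + s$profile_table$pct_male - 100)
                  <= 0.1 + 1e-9))
  expect_identical(s$profile_table$n_female + s$profile_table$n_male,
                   s$profile_table$n)
  expect_identical(unname(sum(s$n_by_sex)), s$n_total)
})

test_that("a perfectly balanced cohort has zero sex-ratio chi-square", {
  traj <- setNames(rep(list(list(days = 0L, sev = 4L)), 100L),
                   sprintf("a%03d", 1:100))
  coh <- make_cohort(traj, sex = rep(c("female", "male"), 50L))
  s <- summarize_cohort(coh)
  expect_equal(unname(s$sex_chisq["statistic"]), 0)
  expect_equal(unname(s$sex_chisq["p_value"]), 1)
})

test_that("cohort validation rejects late first evaluations and bad metadata", {
  expect_error(make_cohort(list(a1 = list(days = 3L, sev = 5L))), "48 h")
  athletes <- data.frame(athlete_id = "a1", sex = "female", sport = "soccer",
                         sport_group = "g1", mechanism = "crash",
                         rtp_day = NA_integer_)
  evals <- data.frame(athlete_id = "a1", day_post_injury = 0L,
                      t(make_checklist()), check.names = FALSE)
  expect_error(src_cohort(athletes, evals), "mechanism")
  expect_error(summarize_cohort(make_cohort(list())))
})

test_that("initial table uses only the first evaluation", {
  coh <- make_cohort(list(a1 = list(days = c(0L, 2L), sev = c(40L, 3L))))
  init <- initial_table(coh)
  expect_identical(init$severity_score, 40L)
  expect_identical(init$day_initial, 0L)
})
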